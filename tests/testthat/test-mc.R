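test_that("photon-weight budget closes exactly for layered media", {
  w <- water_iops(1, tiny_grid())
  r <- simulate_rrs(w, quick_scenario(), seed = 1)
  expect_equal(budget_sum(r), rep(1, 3), tolerance = 1e-6)
  o <- oil_iops("CL", tiny_grid(), ppm = 1)
  r2 <- simulate_rrs(w, quick_scenario(), oil = o, seed = 2)
  expect_equal(budget_sum(r2), rep(1, 3), tolerance = 1e-6)
  expect_true(all(r2$rrs >= 0))
})

test_that("a pure absorber returns exactly zero reflectance", {
  med <- homogeneous_medium(a = 0.5, b = 0, pf = pf_isotropic())
  r <- simulate_rrs(med, quick_scenario(), seed = 3)
  expect_identical(r$rrs, 0)
  # everything is either absorbed in the column or lost at the surface
  expect_equal(r$budget_absorbed + r$budget_surface_lost, 1, tolerance = 1e-12)
  expect_identical(r$budget_water_leaving, 0)
})

test_that("identical scenario and seed give bit-identical results", {
  w <- water_iops(0.1, spectral_grid(c(440, 555)))
  r1 <- simulate_rrs(w, quick_scenario(), seed = 99)
  r2 <- simulate_rrs(w, quick_scenario(), seed = 99)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("below-surface reflectance matches the single-scattering estimate", {
  # homogeneous ocean, flat surface, direct beam only, isotropic scattering:
  # R(0-) ~ f * b_b / (a + b_b) with f = 0.33
  med <- homogeneous_medium(a = 0.1, b = 0.05, pf = pf_isotropic())
  sc <- scenario(n_photons = 2e5, wind_speed = 0,
                 sky_diffuse_fraction = function(l) 0)
  r <- simulate_rrs(med, sc, seed = 4)
  bb <- 0.5 * 0.05
  est <- 0.33 * bb / (0.1 + bb)
  expect_lt(abs(r$r0minus - est) / est, 0.35)
})

test_that("Monte Carlo noise scales as one over the square root of photons", {
  # wide receiver cone: the batch-based stderr estimate needs a healthy hit
  # count at the smallest photon budget to be itself reliable
  w <- water_iops(1, spectral_grid(555))
  ns <- c(1e5, 1e6, 1e7)
  se <- vapply(ns, function(n) {
    simulate_rrs(w, scenario(n_photons = n, n_batches = 100,
                             receiver_half_angle = 30), seed = 5)$stderr
  }, numeric(1))
  fit <- stats::lm(log10(se) ~ log10(ns))
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 0.05)
})

test_that("bottom parameters do not influence reflectance of a 1000 m column", {
  w <- water_iops(1, spectral_grid(550))
  r_dark <- simulate_rrs(w, quick_scenario(5e4, bottom_diffuse = 0,
                                           bottom_mirror = 0), seed = 6)
  r_bright <- simulate_rrs(w, quick_scenario(5e4), seed = 6)
  expect_lte(abs(r_dark$rrs - r_bright$rrs),
             max(r_dark$stderr, .Machine$double.eps))
})

test_that("a weakly absorbing, scattering oil raises red-band reflectance", {
  g <- spectral_grid(c(670, 680))
  w <- water_iops(0.1, g)
  o <- oil_iops("CL", g, ppm = 1)
  sc <- quick_scenario(2e5, receiver_half_angle = 30)
  nat <- simulate_rrs(w, sc, seed = 7)
  pol <- simulate_rrs(w, sc, oil = o, seed = 8)
  expect_true(all(pol$rrs > nat$rrs))
})

test_that("oil mixing builds the layered medium additively", {
  g <- tiny_grid()
  w <- water_iops(1, g)
  o <- oil_iops("BD", g, ppm = 1)
  sc <- scenario(oil_ppm = 2)
  med <- mix_iops(w, o, sc)
  expect_length(med$layers, 2)
  expect_equal(med$layers[[1]]$z_bottom, sc$mixed_layer_depth)
  expect_equal(med$layers[[1]]$a, w$a_tot + 2 * o$a_oil)
  expect_equal(med$layers[[1]]$b, w$b_tot + 2 * o$b_oil)
  expect_equal(med$layers[[2]]$a, w$a_tot)
  # without oil, or at zero concentration, the column is a single layer
  expect_length(mix_iops(w, NULL, sc)$layers, 1)
  med0 <- mix_iops(w, o, scenario(oil_ppm = 0))
  expect_equal(med0$layers, mix_iops(w, NULL, sc)$layers)
  expect_error(mix_iops(w, oil_iops("BD", spectral_grid(c(440, 555)), ppm = 1), sc),
               "grids")
})
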