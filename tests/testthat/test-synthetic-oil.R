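test_that("template complex indices respect their structural constraints", {
  g <- default_grid()
  for (kind in c("BD", "CL", "FL")) {
    idx <- make_oil_index(kind, g)
    expect_true(all(idx$n >= 1.45 & idx$n <= 1.53))
    expect_true(all(idx$k >= 0))
  }
  # crude-like oil: strong blue absorption, ~100x the lubricant amplitude
  fl <- make_oil_index("FL", g)
  cl <- make_oil_index("CL", g)
  expect_gt(fl$k[fl$wavelength == 440] / fl$k[fl$wavelength == 670], 5)
  ratio <- max(fl$k) / max(cl$k)
  expect_gt(ratio, 50)
  expect_lt(ratio, 200)
  # CL and FL imaginary indices decrease strictly with wavelength
  expect_true(all(diff(cl$k) < 0))
  expect_true(all(diff(fl$k) < 0))
})

test_that("the biodiesel-like imaginary index has exactly three local maxima", {
  k <- make_oil_index("BD", default_grid())$k
  n <- length(k)
  n_max <- sum(k[2:(n - 1)] > k[1:(n - 2)] & k[2:(n - 1)] > k[3:n])
  expect_identical(n_max, 3L)
})

test_that("size distributions integrate to the stated concentration with the right mode", {
  psd_cl <- make_psd("CL", total_ppm = 1)
  expect_equal(oildroprt:::psd_total_ppm(psd_cl), 1, tolerance = 1e-6)
  expect_true(all(psd_cl$diameter_um > 0.2 & psd_cl$diameter_um < 200))
  argmax <- function(p) p$diameter_um[which.max(p$density_ppm_per_um)]
  expect_gte(argmax(psd_cl), 6); expect_lte(argmax(psd_cl), 8)
  expect_gte(argmax(make_psd("BD")), 4); expect_lte(argmax(make_psd("BD")), 6)
  expect_gte(argmax(make_psd("FL")), 4); expect_lte(argmax(make_psd("FL")), 6)
  # negligible droplet volume above ~80 um (under 1% of the total)
  sel <- psd_cl$diameter_um > 80
  w <- oildroprt:::trapezoid_weights(psd_cl$diameter_um)
  expect_lt(sum((psd_cl$density_ppm_per_um * w)[sel]), 0.01)
  # linear rescaling of the total concentration
  psd2 <- make_psd("CL", total_ppm = 2)
  expect_equal(psd2$density_ppm_per_um, 2 * psd_cl$density_ppm_per_um)
  expect_error(make_psd("CL", total_ppm = 0), "> 0")
})

test_that("jittered templates are deterministic and preserve the invariants", {
  tpl <- oil_template("FL")
  j1 <- jitter_template(tpl, seed = 5)
  j2 <- jitter_template(tpl, seed = 5)
  expect_identical(j1, j2)
  expect_false(identical(j1$k_model$amplitude, tpl$k_model$amplitude))
  g <- default_grid()
  for (kind in c("BD", "CL", "FL")) {
    for (seed in 1:100) {
      jt <- jitter_template(oil_template(kind), seed = seed)
      idx <- make_oil_index(template = jt, wavelengths = g)
      expect_true(all(idx$n >= 1.45 & idx$n <= 1.53))
      expect_true(all(idx$k >= 0))
      psd <- make_psd(template = jt, total_ppm = 1)
      expect_equal(oildroprt:::psd_total_ppm(psd), 1, tolerance = 1e-6)
      if (kind == "FL") {
        expect_gt(idx$k[idx$wavelength == 440] / idx$k[idx$wavelength == 670], 5)
      }
    }
  }
  # jitter must not disturb the global RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(jitter_template(tpl, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})
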