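test_that("single-sphere efficiencies satisfy their identities", {
  # non-absorbing sphere: extinction equals scattering
  r <- mie_single(5, complex(real = 1.1))
  expect_identical(r$q_abs, 0)
  expect_identical(r$q_ext, r$q_sca)
  # absorbing sphere: q_ext = q_sca + q_abs holds by construction and all
  # efficiencies are positive
  r2 <- mie_single(10, complex(real = 1.1, imaginary = 0.01))
  expect_equal(r2$q_ext, r2$q_sca + r2$q_abs, tolerance = 1e-12)
  expect_true(all(c(r2$q_ext, r2$q_sca, r2$q_abs) > 0))
  expect_error(mie_single(-1, 1.1), "> 0")
})

test_that("small-sphere limit matches the Rayleigh closed form", {
  m <- complex(real = 1.1)
  r <- mie_single(1e-3, m)
  rayleigh <- (8 / 3) * (1e-3)^4 * Mod((m^2 - 1) / (m^2 + 2))^2
  expect_equal(r$q_sca, rayleigh, tolerance = 0.01)
})

test_that("efficiencies agree with the independent continued-fraction oracle", {
  for (x in c(0.1, 1, 10, 50)) {
    for (m in c(complex(real = 1.05), complex(real = 1.13, imaginary = 0.001),
                complex(real = 1.15, imaginary = 0.01))) {
      got <- mie_single(x, m)
      ref <- oracle_mie_q(x, m)
      expect_equal(got$q_sca, ref$q_sca, tolerance = 1e-6)
      if (Im(m) > 0) {
        expect_equal(got$q_ext, ref$q_ext, tolerance = 1e-6)
      }
    }
  }
})

test_that("polydisperse integration reduces to a single sphere for one bin", {
  g <- spectral_grid(550)
  idx <- tibble::tibble(wavelength = 550, n = 1.48, k = 1e-4)
  D <- 5 # um
  psd <- tibble::tibble(diameter_um = D, density_ppm_per_um = 1)
  o <- polydisperse_iops(idx, psd, g)
  nm <- seawater_refractive_index(550)
  x <- pi * D * 1e3 * nm / 550
  r <- mie_single(x, complex(real = 1.48, imaginary = 1e-4) / nm)
  num <- 1e-6 / (pi / 6 * (D * 1e-6)^3) # droplets per m^3 at 1 ppm
  area <- pi / 4 * (D * 1e-6)^2
  expect_equal(o$b_oil, num * area * r$q_sca, tolerance = 1e-12)
  expect_equal(o$a_oil, num * area * r$q_abs, tolerance = 1e-12)
})

test_that("polydisperse coefficients are linear in concentration", {
  g <- spectral_grid(c(440, 670))
  idx <- make_oil_index("CL", g)
  psd1 <- make_psd("CL", total_ppm = 1, diameters = 10^seq(log10(0.5), log10(40), length.out = 25))
  psd2 <- dplyr::mutate(psd1, density_ppm_per_um = density_ppm_per_um * 2)
  o1 <- polydisperse_iops(idx, psd1, g)
  o2 <- polydisperse_iops(idx, psd2, g)
  expect_equal(o2$a_oil, 2 * o1$a_oil, tolerance = 1e-12)
  expect_equal(o2$b_oil, 2 * o1$b_oil, tolerance = 1e-12)
  expect_equal(attr(o2, "pf")[[1]]$value, attr(o1, "pf")[[1]]$value,
               tolerance = 1e-10)
  # scale_oil_iops provides the same linearity without recomputation
  o5 <- scale_oil_iops(o1, 5)
  expect_equal(o5$b_oil, 5 * o1$b_oil)
  expect_equal(attr(o5, "ppm"), 5)
})

test_that("polydisperse result is stable under quadrature refinement", {
  g <- spectral_grid(550)
  idx <- make_oil_index("CL", g)
  coarse <- make_psd("CL", diameters = 10^seq(log10(0.25), log10(60), length.out = 40))
  fine <- make_psd("CL", diameters = 10^seq(log10(0.25), log10(60), length.out = 400))
  oc <- polydisperse_iops(idx, coarse, g)
  of <- polydisperse_iops(idx, fine, g)
  expect_equal(oc$b_oil, of$b_oil, tolerance = 0.01)
  expect_equal(oc$a_oil, of$a_oil, tolerance = 0.01)
})

test_that("polydisperse phase functions are normalized and show the droplet side peak", {
  g <- spectral_grid(555)
  o <- oil_iops("CL", g, ppm = 1)
  pf <- attr(o, "pf")[[1]]
  expect_equal(pf_integral(pf), 1, tolerance = 1e-3)
  # characteristic dispersed-oil peak near 90-100 degrees (droplet rainbow)
  peak <- oil_phase_peak_check(pf)
  expect_false(is.na(peak))
  expect_gt(peak, 80)
  expect_lt(peak, 110)
})

test_that("the crude-like oil absorbs far more in the blue than in the red", {
  g <- spectral_grid(c(440, 670))
  o <- oil_iops("FL", g, ppm = 1)
  expect_gt(o$a_oil[1] / o$a_oil[2], 5)
})
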