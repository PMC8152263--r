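test_that("pure-water absorption interpolates the embedded table", {
  # table nodes are returned unchanged
  expect_equal(pure_water_absorption(440), 0.00635)
  expect_equal(pure_water_absorption(550), 0.0565)
  # red absorption exceeds blue absorption in clear water
  expect_gt(pure_water_absorption(700), pure_water_absorption(440))
  # midpoint between nodes is the mean of the node values
  expect_equal(pure_water_absorption(445),
               (pure_water_absorption(440) + pure_water_absorption(450)) / 2)
  expect_true(all(pure_water_absorption(default_grid()) >= 0))
})

test_that("pure-seawater scattering follows its power law", {
  p <- water_params()
  expect_equal(pure_water_scattering(p$lambda_ref_b), p$b_water_ref)
  expect_gt(pure_water_scattering(400), pure_water_scattering(700))
  expect_equal(pure_water_scattering(400) / pure_water_scattering(700),
               (700 / 400)^p$gamma)
})

test_that("particulate absorption is a power law in chlorophyll", {
  g <- default_grid()
  expect_equal(particle_absorption(g, 0), rep(0, 27))
  tab <- oildroprt:::load_table("chl_specific_absorption")
  expect_equal(particle_absorption(tab$wavelength_nm, 1), tab$A)
  E440 <- tab$E[tab$wavelength_nm == 440]
  expect_equal(particle_absorption(440, 10) / particle_absorption(440, 0.1),
               100^E440)
  expect_error(particle_absorption(g, -1), ">= 0")
})

test_that("CDOM absorption anchors to particulate absorption at 440 nm", {
  p <- water_params()
  expect_equal(cdom_absorption(440, 1),
               p$cdom_fraction * particle_absorption(440, 1))
  expect_equal(cdom_absorption(tiny_grid(), 0), rep(0, 3))
  expect_equal(cdom_absorption(540, 2) / cdom_absorption(440, 2),
               exp(-0.014 * 100))
})

test_that("particulate scattering follows the Loisel-Morel law", {
  expect_equal(particle_scattering(550, 0), 0)
  expect_equal(particle_scattering(550, 1), 0.416)
  expect_equal(particle_scattering(550, 10) / particle_scattering(550, 0.1),
               100^0.766)
  # clear water scatters blue-enhanced; chl >= 2 is spectrally flat
  expect_gt(particle_scattering(440, 0.1), particle_scattering(670, 0.1))
  expect_equal(particle_scattering(440, 5), particle_scattering(670, 5))
})

test_that("components increase monotonically with chlorophyll at every band", {
  g <- default_grid()
  chls <- c(0.1, 1, 10)
  for (f in list(particle_absorption, particle_scattering,
                 function(g, c) cdom_absorption(g, c))) {
    vals <- sapply(chls, function(ch) f(g, ch))
    expect_true(all(diff(t(vals)) > 0))
  }
})

test_that("water IOPs are additive and non-negative", {
  for (chl in c(0.1, 1, 10)) {
    w <- water_iops(chl, tiny_grid())
    expect_identical(w$a_tot, w$a_water + w$a_particle + w$a_cdom)
    expect_identical(w$b_tot, w$b_water + w$b_particle)
    expect_true(all(as.matrix(w[-1]) >= 0))
  }
  b01 <- water_iops(0.1, tiny_grid())$b_tot
  b1 <- water_iops(1, tiny_grid())$b_tot
  b10 <- water_iops(10, tiny_grid())$b_tot
  expect_true(all(b10 > b1 & b1 > b01))
  expect_error(water_iops(0), "> 0")
})

test_that("water phase function is a normalized chl-weighted mixture", {
  for (chl in c(0.1, 1, 10)) {
    for (lam in c(440, 555, 670)) {
      pf <- water_phase_function(chl, lam)
      expect_equal(pf_integral(pf), 1, tolerance = 1e-3)
    }
  }
  # chl -> 0: the particle weight vanishes and the mixture tends to the
  # pure-seawater shape (compared away from the particulate forward spike,
  # whose pointwise magnitude diverges even at negligible weight)
  pf_lo <- water_phase_function(1e-10, 555)
  pr <- pf_rayleigh()
  sel <- pr$angle_deg >= 1
  expect_equal(pf_lo$value[sel], pr$value[sel], tolerance = 1e-3)
  expect_equal(pf_backscatter_fraction(pf_lo), 0.5, tolerance = 1e-3)
  # particles are forward-peaked: forward probability grows with chl
  forward <- function(chl) {
    pf <- water_phase_function(chl, 555)
    sel <- pf$angle_deg <= 20
    th <- pf$angle_deg[sel] * pi / 180
    f <- 2 * pi * pf$value[sel] * sin(th)
    sum(diff(th) * (head(f, -1) + tail(f, -1)) / 2)
  }
  expect_gt(forward(1), forward(0.1))
  expect_gt(forward(10), forward(1))
})

test_that("out-of-range wavelengths are rejected", {
  expect_error(spectral_grid(350), "400")
  expect_error(pure_water_absorption(c(390)), "400")
})
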