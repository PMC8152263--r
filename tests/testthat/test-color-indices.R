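flat_spectrum <- function(value = 0.005,
                          wl = c(410, 440, 490, 550, 555, 560, 665, 670, 680)) {
  tibble::tibble(wavelength = wl, rrs = value)
}

test_that("band ratio and difference are exact arithmetic with band matching", {
  spec <- tibble::tibble(wavelength = c(410, 560), rrs = c(0.008, 0.002))
  expect_equal(band_ratio(spec, 410, 560), 4)
  # nearest-band lookup within 5 nm (443 resolves to 440-type bands)
  spec2 <- tibble::tibble(wavelength = c(440, 555), rrs = c(0.01, 0.004))
  expect_equal(band_ratio(spec2, 443, 555), 2.5)
  expect_error(band_ratio(spec2, 420, 555), "no band")
  expect_identical(band_difference(flat_spectrum(), 550, 440), 0)
  spec3 <- tibble::tibble(wavelength = c(440, 550), rrs = c(0.009, 0.002))
  expect_equal(band_difference(spec3, 550, 440), -0.007)
  expect_identical(band_difference(spec3, 550, 440),
                   -band_difference(spec3, 440, 550))
  expect_true(all(flat_spectrum()$rrs / flat_spectrum()$rrs == 1))
  expect_warning(band_ratio(tibble::tibble(wavelength = c(440, 555),
                                           rrs = c(0.01, 0)), 440, 555),
                 "undefined")
})

test_that("color index matches its defining formula and vanishes on affine spectra", {
  spec <- tibble::tibble(wavelength = c(440, 555, 670),
                         rrs = c(0.009, 0.002, 0.0002))
  # hand evaluation: (555-440)/(670-440) = 0.5 exactly
  expect_equal(color_index(spec, 440, 555, 670), -0.0026, tolerance = 1e-12)
  expect_identical(color_index(flat_spectrum(), 440, 555, 670), 0)
  expect_error(color_index(spec, 555, 440, 670), "lambda_blue")
  # property: CI is exactly zero for any spectrum affine in wavelength
  set.seed(31)
  for (i in 1:25) {
    a <- runif(1, -1e-5, 1e-5)
    b <- runif(1, 0, 0.01)
    wl <- sort(sample(seq(400, 700, 5), 8))
    spec_aff <- tibble::tibble(wavelength = wl, rrs = a * wl + b)
    combos <- utils::combn(wl, 3)
    j <- sample(ncol(combos), 1)
    expect_equal(color_index(spec_aff, combos[1, j], combos[2, j], combos[3, j],
                             tol = 0), 0, tolerance = 1e-15)
  }
})

test_that("relative difference uses the magnitude of the reference", {
  expect_equal(relative_difference(-5.95e-3, -3.11e-3), -91.3, tolerance = 1e-3)
  expect_equal(relative_difference(0.67e-3, -3.11e-3), 121.5, tolerance = 1e-3)
  expect_identical(relative_difference(0.5, 0.5), 0)
  expect_warning(out <- relative_difference(1, 0), "undefined")
  expect_true(is.na(out))
})

test_that("fold change averages the in-range reflectance ratio", {
  nat <- flat_spectrum(0.002)
  pol <- flat_spectrum(0.010)
  expect_equal(fold_change(pol, nat, c(400, 700)), 5)
  expect_identical(fold_change(nat, nat, c(510, 590)), 1)
  # a range holding a single band equals that band's ratio
  pol2 <- nat
  pol2$rrs[pol2$wavelength == 410] <- 0.007
  expect_equal(fold_change(pol2, nat, c(405, 415)), 3.5)
  expect_error(fold_change(pol, nat, c(591, 599)), "no bands")
})

test_that("the band metrics table covers ratios, differences and color indices", {
  pol <- flat_spectrum(0.004)
  nat <- flat_spectrum(0.002)
  tab <- band_metrics_table(pol, nat)
  expect_true(all(c("ratio", "difference", "color_index") %in% tab$type))
  expect_true(all(tab$polluted[tab$type == "ratio"] == 1))
  expect_true(all(tab$relative_difference_pct[tab$type == "ratio"] == 0))
  expect_true(all(is.na(tab$relative_difference_pct[tab$type == "color_index"])))
})
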