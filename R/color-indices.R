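#' Ocean-color band analytics
#'
#' Band ratios, band differences, the color index and comparison metrics
#' computed from a remote sensing reflectance spectrum. Band lookup is
#' nearest-neighbour with a 5-nm tolerance, matching the interchangeable use
#' of nearby instrument bands (e.g., 440/443/445 nm).
#'
#' @param rrs A tibble with columns `wavelength` and `rrs` (e.g., an
#'   `rrs_result`).
#' @param lambda1,lambda2 Band wavelengths in nm.
#' @param tol Band-matching tolerance in nm.
#' @return A single numeric value.
#' @examples
#' spec <- tibble::tibble(wavelength = c(410, 560), rrs = c(0.008, 0.002))
#' band_ratio(spec, 410, 560) # 4
#' @name band_metrics
NULL

rrs_at <- function(rrs, lambda, tol = 5) {
  rrs$rrs[match_band(rrs$wavelength, lambda, tol)]
}

#' @rdname band_metrics
#' @export
band_ratio <- function(rrs, lambda1, lambda2, tol = 5) {
  num <- rrs_at(rrs, lambda1, tol)
  den <- rrs_at(rrs, lambda2, tol)
  if (den <= 0) {
    warn(sprintf("R_rs(%g) <= 0: band ratio undefined", lambda2))
    return(NA_real_)
  }
  num / den
}

#' @rdname band_metrics
#' @export
band_difference <- function(rrs, lambda1, lambda2, tol = 5) {
  rrs_at(rrs, lambda1, tol) - rrs_at(rrs, lambda2, tol)
}

#' Color index of a reflectance spectrum
#'
#' Signed distance of the green-band reflectance from the linear baseline
#' drawn between the blue and red bands:
#' \deqn{CI = R_{rs}(\lambda_g) - \left[R_{rs}(\lambda_b) +
#'   \frac{\lambda_g - \lambda_b}{\lambda_r - \lambda_b}
#'   (R_{rs}(\lambda_r) - R_{rs}(\lambda_b))\right].}
#' Negative for most clear ocean waters; vanishes for any spectrum affine in
#' wavelength.
#'
#' @inheritParams band_metrics
#' @param lambda_blue,lambda_green,lambda_red Band wavelengths, strictly
#'   increasing; conventionally the instrument bands closest to 443, 555 and
#'   670 nm.
#' @return CI in sr^-1.
#' @export
color_index <- function(rrs, lambda_blue = 443, lambda_green = 555,
                        lambda_red = 670, tol = 5) {
  if (!(lambda_blue < lambda_green && lambda_green < lambda_red)) {
    abort("bands must satisfy lambda_blue < lambda_green < lambda_red")
  }
  rb <- rrs_at(rrs, lambda_blue, tol)
  rg <- rrs_at(rrs, lambda_green, tol)
  rr <- rrs_at(rrs, lambda_red, tol)
  rg - (rb + (lambda_green - lambda_blue) / (lambda_red - lambda_blue) * (rr - rb))
}

#' Percentage relative difference between polluted and natural metric values
#'
#' \eqn{100 (polluted - natural) / |natural|}. The absolute value in the
#' denominator keeps the sign of the change itself (a metric moving further
#' from zero in the negative direction reports a negative relative
#' difference).
#'
#' @param polluted,natural Metric values (e.g., band ratios or color
#'   indices) for polluted and unpolluted water.
#' @return Percentage relative difference (scalar or vector).
#' @examples
#' relative_difference(-5.95e-3, -3.11e-3) # about -91
#' @export
relative_difference <- function(polluted, natural) {
  bad <- is.na(natural) | natural == 0
  out <- 100 * (polluted - natural) / abs(natural)
  out[bad] <- NA_real_
  if (any(bad & !is.na(natural))) {
    warn("relative difference undefined where natural == 0")
  }
  out
}

#' Mean reflectance fold change over a spectral range
#'
#' Mean over bands within `band_range` of the polluted-to-natural
#' reflectance ratio. Conventional ranges: blue 400--510, green 510--590,
#' red 590--700 nm.
#'
#' @param polluted_rrs,natural_rrs Spectra on a shared wavelength grid.
#' @param band_range Length-2 numeric interval in nm.
#' @return Mean fold change (dimensionless).
#' @export
fold_change <- function(polluted_rrs, natural_rrs, band_range) {
  if (!isTRUE(all.equal(polluted_rrs$wavelength, natural_rrs$wavelength))) {
    abort("spectra are on different wavelength grids")
  }
  sel <- polluted_rrs$wavelength >= band_range[1] &
    polluted_rrs$wavelength <= band_range[2]
  if (!any(sel)) abort("no bands within the requested range")
  mean(polluted_rrs$rrs[sel] / natural_rrs$rrs[sel])
}

#' Band metrics table for a polluted/natural spectrum pair
#'
#' Computes the standard set of ocean-color diagnostics: five band ratios
#' (410/560, 440/550, 490/550, 550/680, 420/665), three band differences
#' (550-440, 665-440, 680-490) and the color index on the eight
#' blue/green/red band combinations built from {440, 445} x {550, 555} x
#' {670, 675}, for each spectrum and their percentage relative differences.
#'
#' @param polluted_rrs,natural_rrs Spectra on a shared wavelength grid
#'   (`natural_rrs` may be `NULL` to tabulate one spectrum only).
#' @param tol Band-matching tolerance in nm.
#' @return A tibble with columns `metric`, `type`, `polluted`, `natural`,
#'   `relative_difference_pct`.
#' @export
band_metrics_table <- function(polluted_rrs, natural_rrs = NULL, tol = 5) {
  ratios <- list(c(410, 560), c(440, 550), c(490, 550), c(550, 680), c(420, 665))
  diffs <- list(c(550, 440), c(665, 440), c(680, 490))
  cis <- expand.grid(b = c(440, 445), g = c(550, 555), r = c(670, 675))

  # keep only metrics whose bands are representable on the grid
  grid <- (polluted_rrs %||% natural_rrs)$wavelength
  on_grid <- function(l) {
    all(vapply(l, function(b) min(abs(grid - b)) <= tol, logical(1)))
  }
  ratios <- purrr::keep(ratios, on_grid)
  diffs <- purrr::keep(diffs, on_grid)
  cis <- cis[apply(cis, 1, on_grid), , drop = FALSE]

  one <- function(rrs) {
    if (is.null(rrs)) return(NULL)
    c(
      map_dbl(ratios, ~ band_ratio(rrs, .x[1], .x[2], tol)),
      map_dbl(diffs, ~ band_difference(rrs, .x[1], .x[2], tol)),
      purrr::pmap_dbl(cis, function(b, g, r) color_index(rrs, b, g, r, tol))
    )
  }
  metric <- c(
    purrr::map_chr(ratios, ~ sprintf("ratio_%g/%g", .x[1], .x[2])),
    purrr::map_chr(diffs, ~ sprintf("diff_%g-%g", .x[1], .x[2])),
    purrr::pmap_chr(cis, function(b, g, r) sprintf("ci_%g_%g_%g", b, g, r))
  )
  type <- c(rep("ratio", length(ratios)), rep("difference", length(diffs)),
            rep("color_index", nrow(cis)))
  pol <- one(polluted_rrs)
  nat <- one(natural_rrs)
  out <- tibble(metric = metric, type = type, polluted = pol)
  out$natural <- if (is.null(nat)) NA_real_ else nat
  out$relative_difference_pct <- if (is.null(nat)) NA_real_ else {
    suppressWarnings(relative_difference(pol, nat))
  }
  out
}
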