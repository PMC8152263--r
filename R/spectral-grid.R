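#' Spectral grids for visible-range ocean color simulation
#'
#' A spectral grid is a strictly increasing vector of wavelengths (nm) within
#' the visible window 400--700 nm. The default grid has 27 wavelengths and
#' contains every band used by the shipped ocean-color analytics (410, 420,
#' 440, 443, 445, 490, 550, 555, 560, 650, 665, 670, 675, 680 nm).
#'
#' @param wavelengths Numeric vector of wavelengths in nm.
#' @return A validated numeric vector of class `spectral_grid`.
#' @examples
#' default_grid()
#' spectral_grid(c(440, 555, 670))
#' @export
spectral_grid <- function(wavelengths = default_grid()) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1 || anyNA(wavelengths)) {
    abort("wavelengths must be a non-empty numeric vector without NA")
  }
  if (any(diff(wavelengths) <= 0)) {
    abort("wavelengths must be strictly increasing")
  }
  if (min(wavelengths) < 400 || max(wavelengths) > 700) {
    abort("wavelengths must lie within [400, 700] nm")
  }
  structure(wavelengths, class = c("spectral_grid", "numeric"))
}

#' @rdname spectral_grid
#' @export
default_grid <- function() {
  spectral_grid(c(
    400, 410, 420, 430, 440, 443, 445, 460, 475, 490, 505, 520, 535,
    550, 555, 560, 570, 590, 610, 630, 650, 665, 670, 675, 680, 690, 700
  ))
}

#' @rdname spectral_grid
#' @details `reduced_grid()` is a 9-band grid used for desk-scale experiment
#'   sweeps; it keeps one band in each of the blue (400--510), green
#'   (510--590) and red (590--700) ranges plus the color-index bands.
#' @export
reduced_grid <- function() {
  spectral_grid(c(410, 440, 490, 550, 555, 560, 650, 670, 680))
}

as_grid <- function(x) {
  if (inherits(x, "spectral_grid")) x else spectral_grid(x)
}

#' Trophic classification of ocean water by chlorophyll concentration
#'
#' Classifies Case-1 water by chlorophyll-a concentration: oligotrophic
#' (chl <= 0.1), mesotrophic (0.1 < chl <= 1.67) or eutrophic
#' (chl > 1.67 mg/m3).
#'
#' @param chl Chlorophyll-a concentration in mg/m3 (must be > 0).
#' @return Character vector of trophic class labels.
#' @examples
#' trophic_class(c(0.1, 1, 10))
#' @export
trophic_class <- function(chl) {
  if (any(chl <= 0)) abort("chl must be > 0")
  dplyr::case_when(
    chl <= 0.1 ~ "oligotrophic",
    chl <= 1.67 ~ "mesotrophic",
    TRUE ~ "eutrophic"
  )
}

# nearest-band lookup with a tolerance (nm); errors when no band is close
match_band <- function(grid, lambda, tol = 5) {
  i <- which.min(abs(grid - lambda))
  if (abs(grid[i] - lambda) > tol) {
    abort(sprintf("no band within %g nm of %g nm on the grid", tol, lambda))
  }
  i
}
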