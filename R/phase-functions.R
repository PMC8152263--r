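#' Scattering phase functions
#'
#' A phase function is the angular probability density of scattering,
#' tabulated on a grid of scattering angles (degrees, 0--180) with values in
#' sr^-1. The normalization convention used throughout the package is
#' \deqn{\int_0^{\pi} p(\theta)\, 2\pi \sin\theta \, d\theta = 1,}
#' evaluated by trapezoidal quadrature on the tabulated grid, so a freshly
#' constructed phase function integrates to 1 to machine precision with
#' respect to that quadrature.
#'
#' The default angle grid is 0--180 deg at 0.5 deg steps with logarithmically
#' dense refinement below 5 deg, because forward peaks of particle and droplet
#' scattering dominate the sampling accuracy.
#'
#' @param angles Scattering angles in degrees.
#' @param values Density values (sr^-1), same length as `angles`.
#' @return A tibble of class `phase_function` with columns `angle_deg`,
#'   `value`.
#' @examples
#' pf <- pf_rayleigh()
#' pf_integral(pf)
#' @name phase_function
NULL

#' @rdname phase_function
#' @export
phase_function <- function(angles, values) {
  if (length(angles) != length(values)) abort("angles and values differ in length")
  if (any(diff(angles) <= 0)) abort("angles must be strictly increasing")
  if (min(angles) < 0 || max(angles) > 180) abort("angles must lie in [0, 180]")
  if (any(values < 0) || anyNA(values)) abort("phase function values must be >= 0")
  structure(
    tibble(angle_deg = as.numeric(angles), value = as.numeric(values)),
    class = c("phase_function", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname phase_function
#' @export
pf_angle_grid <- function() {
  sort(unique(c(
    0,
    10^seq(log10(0.002), log10(5), length.out = 70),
    seq(5.5, 180, by = 0.5)
  )))
}

#' @rdname phase_function
#' @details `pf_integral()` returns \eqn{2\pi \int p(\theta) \sin\theta\,
#'   d\theta} by trapezoidal quadrature (the repo-wide convention).
#' @export
pf_integral <- function(pf) {
  th <- pf$angle_deg * pi / 180
  f <- 2 * pi * pf$value * sin(th)
  sum(diff(th) * (head(f, -1) + tail(f, -1)) / 2)
}

pf_normalize <- function(angles, values) {
  pf <- phase_function(angles, values)
  phase_function(pf$angle_deg, pf$value / pf_integral(pf))
}

#' @rdname phase_function
#' @details `pf_backscatter_fraction()` integrates over 90--180 degrees.
#' @export
pf_backscatter_fraction <- function(pf) {
  th <- pf$angle_deg * pi / 180
  f <- 2 * pi * pf$value * sin(th)
  w <- diff(th) * (head(f, -1) + tail(f, -1)) / 2
  mid <- (head(th, -1) + tail(th, -1)) / 2
  sum(w[mid > pi / 2]) / sum(w)
}

#' @rdname phase_function
#' @details `pf_isotropic()` is the constant density 1/(4 pi).
#' @export
pf_isotropic <- function(angles = pf_angle_grid()) {
  phase_function(angles, rep(1 / (4 * pi), length(angles)))
}

#' @rdname phase_function
#' @details `pf_rayleigh()` is the pure-seawater (molecular) phase function,
#'   proportional to \eqn{1 + 0.835 \cos^2\theta}, normalized.
#' @export
pf_rayleigh <- function(angles = pf_angle_grid()) {
  th <- angles * pi / 180
  pf_normalize(angles, 1 + 0.835 * cos(th)^2)
}

#' Fournier-Forand particle phase function
#'
#' Analytic phase function for an ensemble of particles with a Junge
#' (hyperbolic) size distribution of slope `mu` and relative refractive index
#' `n`. Used as the particulate phase function of Case-1 water, selected by
#' the particulate backscattering ratio.
#'
#' @param bb_fraction Target backscattering ratio b_b/b; when supplied, `mu`
#'   is solved from the closed-form backscatter fraction at fixed `n`.
#' @param n Real relative refractive index of the particles (default 1.05,
#'   typical of phytoplankton).
#' @param mu Junge slope; overrides `bb_fraction` when given.
#' @param angles Angle grid in degrees.
#' @return A `phase_function`.
#' @examples
#' pf <- pf_fournier_forand(bb_fraction = 0.01)
#' pf_backscatter_fraction(pf)
#' @export
pf_fournier_forand <- function(bb_fraction = NULL, n = 1.05, mu = NULL,
                               angles = pf_angle_grid()) {
  if (is.null(mu)) {
    if (is.null(bb_fraction)) abort("supply either bb_fraction or mu")
    mu <- ff_mu_for_bb(bb_fraction, n)
  }
  nu <- (3 - mu) / 2
  th <- angles * pi / 180
  s2 <- sin(th / 2)^2
  s2[s2 < 1e-12] <- 1e-12 # integrable forward divergence; clamp at theta -> 0
  delta <- 4 / (3 * (n - 1)^2) * s2
  d180 <- 4 / (3 * (n - 1)^2)
  p <- 1 / (4 * pi * (1 - delta)^2 * delta^nu) *
    (nu * (1 - delta) - (1 - delta^nu) +
       (delta * (1 - delta^nu) - nu * (1 - delta)) / s2) +
    (1 - d180^nu) / (16 * pi * (d180 - 1) * d180^nu) * (3 * cos(th)^2 - 1)
  p[p < 0] <- 0 # guard tiny negative round-off near zeros
  pf_normalize(angles, p)
}

# closed-form Fournier-Forand backscatter fraction, and its inversion for mu
ff_backscatter_fraction <- function(mu, n) {
  nu <- (3 - mu) / 2
  d90 <- 2 / (3 * (n - 1)^2)
  1 - (1 - d90^(nu + 1) - 0.5 * (1 - d90^nu)) / ((1 - d90) * d90^nu)
}

ff_mu_for_bb <- function(bb, n = 1.05) {
  if (bb <= 0 || bb >= 0.5) abort("bb_fraction must be in (0, 0.5)")
  uniroot(
    function(mu) ff_backscatter_fraction(mu, n) - bb,
    interval = c(3.001, 4.999), tol = 1e-10
  )$root
}

#' Inverse-CDF table of scattering angle cosines
#'
#' Tabulates the quantile function of cos(theta) implied by a phase function,
#' at `n_quantiles` equispaced probabilities. This is the sampling table used
#' by the Monte Carlo kernel (linear interpolation between quantiles).
#'
#' @param pf A `phase_function`.
#' @param n_quantiles Number of equispaced quantiles.
#' @return Numeric vector of cos(theta) values of length `n_quantiles + 1`,
#'   from cos at probability 0 to probability 1.
#' @export
pf_inverse_cdf <- function(pf, n_quantiles = 4096) {
  th <- pf$angle_deg * pi / 180
  f <- 2 * pi * pf$value * sin(th)
  cw <- c(0, cumsum(diff(th) * (head(f, -1) + tail(f, -1)) / 2))
  cw <- cw / cw[length(cw)]
  # CDF may be flat where sin(theta)=0 at endpoints; keep strictly increasing
  keep <- c(TRUE, diff(cw) > 0)
  approx(cw[keep], cos(th)[keep], xout = seq(0, 1, length.out = n_quantiles + 1),
         rule = 2)$y
}

#' Draw scattering angles from a tabulated phase function
#'
#' Inverse-CDF sampling of the polar scattering angle with uniform azimuth.
#' Uses R's RNG stream (control with [set.seed()]).
#'
#' @param pf A `phase_function`.
#' @param n Number of draws.
#' @return A tibble with columns `theta_deg` and `phi_rad`.
#' @export
sample_scattering <- function(pf, n = 1) {
  tab <- pf_inverse_cdf(pf)
  u <- runif(n) * (length(tab) - 1)
  i <- pmin(floor(u), length(tab) - 2)
  fr <- u - i
  ct <- tab[i + 1] * (1 - fr) + tab[i + 2] * fr
  tibble(
    theta_deg = acos(pmin(1, pmax(-1, ct))) * 180 / pi,
    phi_rad = runif(n, 0, 2 * pi)
  )
}

#' Locate the secondary scattering peak of an oil-droplet phase function
#'
#' Dispersed-oil phase functions show a characteristic side peak near
#' 90--100 degrees (the primary rainbow of droplets with relative index
#' around 1.1). This diagnostic finds the largest strict local maximum of the
#' tabulated density for angles in (60, 150) degrees.
#'
#' @param pf A `phase_function`.
#' @return The angle (degrees) of the largest interior local maximum, or
#'   `NA_real_` when none exists.
#' @export
oil_phase_peak_check <- function(pf) {
  a <- pf$angle_deg
  v <- pf$value
  n <- length(v)
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1
  idx <- idx[a[idx] > 60 & a[idx] < 150]
  if (length(idx) == 0) return(NA_real_)
  a[idx[which.max(v[idx])]]
}
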