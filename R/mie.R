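#' Lorenz-Mie scattering of a single sphere
#'
#' Computes extinction, scattering and absorption efficiencies and the
#' complex amplitude functions S1, S2 for a homogeneous sphere of size
#' parameter `x` and relative complex refractive index `m` suspended in a
#' non-absorbing medium. Uses the standard partial-wave series: the
#' logarithmic derivative of the Riccati-Bessel function of the internal
#' argument by downward recurrence (started above the truncation order), the
#' Riccati-Bessel functions of the external argument by upward recurrence,
#' and truncation at \eqn{n_{max} = \lceil x + 4x^{1/3} + 2 \rceil}.
#'
#' @param x Size parameter (dimensionless, > 0); for a droplet of diameter D
#'   in a medium of index n_med, \eqn{x = \pi D n_{med} / \lambda_{vac}}.
#' @param m Relative complex refractive index (oil index / medium index).
#' @param angles Scattering angles in degrees at which to evaluate S1, S2.
#' @return A list of class `mie_result`: `x`, `m_rel`, `q_ext`, `q_sca`,
#'   `q_abs`, `angles` and complex vectors `s1`, `s2`.
#' @examples
#' r <- mie_single(10, complex(real = 1.1, imaginary = 1e-3))
#' r$q_ext - (r$q_sca + r$q_abs)
#' @export
mie_single <- function(x, m, angles = pf_angle_grid()) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0) abort("x must be a single value > 0")
  if (any(angles < 0 | angles > 180)) abort("angles must lie in [0, 180]")
  m <- as.complex(m)
  co <- mie_coeffs(x, m)
  n <- seq_along(co$a)
  w <- 2 * n + 1
  q_ext <- (2 / x^2) * sum(w * Re(co$a + co$b))
  q_sca <- (2 / x^2) * sum(w * (Mod(co$a)^2 + Mod(co$b)^2))
  if (!all(is.finite(c(q_ext, q_sca)))) abort("Mie series did not converge")
  if (Im(m) == 0) {
    # non-absorbing sphere: enforce the exact identity
    q_ext <- q_sca
    q_abs <- 0
  } else {
    q_abs <- q_ext - q_sca
  }
  pt <- mie_pi_tau(angles, length(n))
  cn <- w / (n * (n + 1))
  s1 <- drop(pt$pi %*% (cn * co$a) + pt$tau %*% (cn * co$b))
  s2 <- drop(pt$pi %*% (cn * co$b) + pt$tau %*% (cn * co$a))
  structure(
    list(x = x, m_rel = m, q_ext = q_ext, q_sca = q_sca, q_abs = q_abs,
         angles = angles, s1 = s1, s2 = s2),
    class = "mie_result"
  )
}

# Mie expansion coefficients a_n, b_n, n = 1..n_max
mie_coeffs <- function(x, m) {
  n_max <- ceiling(x + 4 * x^(1 / 3) + 2)
  rho <- m * x
  # downward recurrence for the logarithmic derivative D_n(m x)
  n_start <- max(n_max, ceiling(Mod(rho))) + 16
  D <- complex(length.out = n_start + 1)
  for (n in n_start:1) {
    D[n] <- (n + 1) / rho - 1 / (D[n + 1] + (n + 1) / rho)
  }
  D <- D[1:n_max]
  # upward recurrences for psi_n(x), chi_n(x)
  psi <- numeric(n_max)
  chi <- numeric(n_max)
  psi_m1 <- cos(x); psi_0 <- sin(x)
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  for (n in 1:n_max) {
    psi[n] <- (2 * n - 1) / x * psi_0 - psi_m1
    chi[n] <- (2 * n - 1) / x * chi_0 - chi_m1
    psi_m1 <- psi_0; psi_0 <- psi[n]
    chi_m1 <- chi_0; chi_0 <- chi[n]
  }
  psi_l <- c(sin(x), psi[-n_max])    # psi_{n-1}
  chi_l <- c(cos(x), chi[-n_max])    # chi_{n-1}
  xi <- complex(real = psi, imaginary = -chi)
  xi_l <- complex(real = psi_l, imaginary = -chi_l)
  n <- 1:n_max
  da <- D / m + n / x
  db <- D * m + n / x
  list(
    a = (da * psi - psi_l) / (da * xi - xi_l),
    b = (db * psi - psi_l) / (db * xi - xi_l)
  )
}

# angular functions pi_n, tau_n as (n_angle x n_max) matrices; cached on the
# (angles, n_max) key because they are independent of x and m
mie_pi_tau <- function(angles, n_max) {
  key <- paste0("pitau_", n_max, "_", length(angles), "_",
                signif(sum(angles), 12))
  hit <- the[[key]]
  if (!is.null(hit)) return(hit)
  mu <- cos(angles * pi / 180)
  na <- length(mu)
  PI <- matrix(0, na, n_max)
  TAU <- matrix(0, na, n_max)
  pim1 <- rep(0, na) # pi_0
  pin <- rep(1, na)  # pi_1
  for (n in 1:n_max) {
    TAU[, n] <- n * mu * pin - (n + 1) * pim1
    PI[, n] <- pin
    if (n < n_max) {
      pip <- ((2 * n + 1) * mu * pin - (n + 1) * pim1) / n
      pim1 <- pin
      pin <- pip
    }
  }
  out <- list(pi = PI, tau = TAU)
  the[[key]] <- out
  out
}

#' Inherent optical properties of a polydisperse oil-droplet suspension
#'
#' Integrates single-sphere Lorenz-Mie cross sections over a droplet size
#' distribution to produce the absorption coefficient, scattering coefficient
#' and scattering phase function of a dispersed-oil suspension at the stated
#' volume concentration. Number densities are recovered from the volume
#' density via the sphere volume \eqn{\pi D^3/6}; the relative index is the
#' oil complex index divided by the (real) seawater index, and the size
#' parameter uses the wavelength in the medium,
#' \eqn{x = \pi D n_{med}/\lambda_{vac}}. The medium is treated as
#' non-absorbing in the Mie solution: saline water absorption enters the
#' radiative transfer through the water IOPs, not through the droplet model.
#'
#' @param oil_index Tibble with columns `wavelength`, `n`, `k` (e.g., from
#'   [make_oil_index()]); must cover the requested wavelengths.
#' @param psd Size distribution tibble with columns `diameter_um`,
#'   `density_ppm_per_um` (e.g., from [make_psd()]).
#' @param wavelengths Wavelengths in nm.
#' @param medium_index_fn Function of wavelength (nm) returning the real
#'   medium index; defaults to [seawater_refractive_index()] at 35 PSU, 20 C.
#' @param angles Phase-function angle grid (degrees).
#' @return A tibble of class `oil_iops` with columns `wavelength`, `a_oil`,
#'   `b_oil` (1/m at the distribution's total ppm). The per-wavelength phase
#'   functions (list of [phase_function()]), the total ppm and the inputs are
#'   attached as attributes.
#' @export
polydisperse_iops <- function(oil_index, psd, wavelengths,
                              medium_index_fn = function(l)
                                seawater_refractive_index(l, 35, 20),
                              angles = pf_angle_grid()) {
  grid <- as_grid(wavelengths)
  lam <- as.numeric(grid)
  if (min(lam) < min(oil_index$wavelength) - 1e-9 ||
      max(lam) > max(oil_index$wavelength) + 1e-9) {
    abort("oil_index does not cover the requested wavelengths")
  }
  interp <- function(y) {
    if (nrow(oil_index) == 1) rep(y, length(lam))
    else approx(oil_index$wavelength, y, xout = lam)$y
  }
  n_oil <- interp(oil_index$n)
  k_oil <- interp(oil_index$k)
  total_ppm <- psd_total_ppm(psd)

  D <- psd$diameter_um
  wbin <- trapezoid_weights(D)
  vol_ppm <- psd$density_ppm_per_um * wbin            # ppm of oil per bin
  num <- vol_ppm * 1e-6 / (pi / 6 * (D * 1e-6)^3)     # droplets per m^3
  area <- pi / 4 * (D * 1e-6)^2                       # geometric cross section, m^2

  a_oil <- numeric(length(lam))
  b_oil <- numeric(length(lam))
  pfs <- vector("list", length(lam))
  for (j in seq_along(lam)) {
    nm <- medium_index_fn(lam[j])
    m <- complex(real = n_oil[j], imaginary = k_oil[j]) / nm
    beta <- 0
    for (i in seq_along(D)) {
      if (num[i] <= 0) next
      x <- pi * D[i] * 1e3 * nm / lam[j]
      r <- mie_single(x, m, angles)
      b_oil[j] <- b_oil[j] + num[i] * area[i] * r$q_sca
      a_oil[j] <- a_oil[j] + num[i] * area[i] * r$q_abs
      beta <- beta + num[i] * (Mod(r$s1)^2 + Mod(r$s2)^2) / 2
    }
    pfs[[j]] <- pf_normalize(angles, beta)
  }
  out <- tibble(wavelength = lam, a_oil = a_oil, b_oil = b_oil)
  structure(
    out,
    ppm = total_ppm,
    pf = pfs,
    psd = psd,
    oil_index = oil_index,
    class = c("oil_iops", class(out))
  )
}

#' Rescale dispersed-oil IOPs to a different volume concentration
#'
#' Oil absorption and scattering are linear in concentration; the phase
#' function is concentration-independent.
#'
#' @param oil An `oil_iops` object.
#' @param ppm Target volume concentration in ppm.
#' @return An `oil_iops` object at the new concentration.
#' @export
scale_oil_iops <- function(oil, ppm) {
  if (ppm < 0) abort("ppm must be >= 0")
  f <- ppm / attr(oil, "ppm")
  out <- mutate(oil, a_oil = .data$a_oil * f, b_oil = .data$b_oil * f)
  attrs <- attributes(oil)
  for (nm in setdiff(names(attrs), c("names", "row.names", "class"))) {
    attr(out, nm) <- attrs[[nm]]
  }
  attr(out, "ppm") <- ppm
  class(out) <- class(oil)
  out
}

trapezoid_weights <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(1, n))
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  w
}

psd_total_ppm <- function(psd) {
  sum(psd$density_ppm_per_um * trapezoid_weights(psd$diameter_um))
}
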