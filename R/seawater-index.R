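#' Real refractive index of saline water
#'
#' Empirical parameterization (Quan & Fry style) of the real refractive index
#' of seawater as a function of wavelength, salinity and temperature. This is
#' the medium index used when converting oil optical constants to relative
#' indices for Lorenz-Mie calculations, and for Snell/Fresnel computations at
#' the sea surface.
#'
#' @param lambda Wavelength in nm, within [400, 700].
#' @param salinity Salinity in PSU, within [0, 40]. Default 35.
#' @param temperature Temperature in degrees Celsius, within [0, 30].
#'   Default 20.
#' @return Numeric vector of (dimensionless) refractive indices, about 1.34
#'   in the mid-visible.
#' @examples
#' seawater_refractive_index(550)
#' @export
seawater_refractive_index <- function(lambda, salinity = 35, temperature = 20) {
  if (any(lambda < 400 | lambda > 700)) abort("lambda must be within [400, 700] nm")
  if (salinity < 0 || salinity > 40) abort("salinity must be within [0, 40] PSU")
  if (temperature < 0 || temperature > 30) abort("temperature must be within [0, 30] C")
  S <- salinity
  Tc <- temperature
  1.31405 +
    (1.779e-4 - 1.05e-6 * Tc + 1.6e-8 * Tc^2) * S -
    2.02e-6 * Tc^2 +
    (15.868 + 0.01155 * S - 0.00423 * Tc) / lambda -
    4382 / lambda^2 +
    1.1455e6 / lambda^3
}
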