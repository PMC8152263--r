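#' Bio-optical model parameters for Case-1 water
#'
#' Collects the tunable constants of the chlorophyll-parameterized water
#' model. Defaults follow the widely used Case-1 parameterizations: a
#' power-law pure-seawater scattering spectrum, a CDOM exponential tied to
#' particulate absorption at 440 nm, the Loisel-Morel particulate scattering
#' law with the Morel chlorophyll-dependent spectral slope, and a
#' Fournier-Forand particulate phase function selected by a
#' chlorophyll-dependent backscattering ratio.
#'
#' @param b_water_ref Pure-seawater scattering at `lambda_ref_b` (1/m).
#' @param lambda_ref_b Anchor wavelength of the scattering power law (nm).
#' @param gamma Power-law exponent of pure-seawater scattering.
#' @param cdom_fraction CDOM absorption at `lambda_ref_cdom` as a fraction of
#'   particulate absorption there.
#' @param cdom_slope CDOM spectral slope (1/nm).
#' @param lambda_ref_cdom CDOM reference wavelength (nm).
#' @param bp_B,bp_p Amplitude and chlorophyll exponent of particulate
#'   scattering at `lambda_ref_bp`.
#' @param lambda_ref_bp Particulate scattering reference wavelength (nm).
#' @param ff_n Relative refractive index used by the Fournier-Forand
#'   particulate phase function.
#' @return A named list of class `water_params`.
#' @export
water_params <- function(b_water_ref = 0.0019, lambda_ref_b = 550, gamma = 4.32,
                         cdom_fraction = 0.2, cdom_slope = 0.014,
                         lambda_ref_cdom = 440,
                         bp_B = 0.416, bp_p = 0.766, lambda_ref_bp = 550,
                         ff_n = 1.05) {
  structure(
    list(
      b_water_ref = b_water_ref, lambda_ref_b = lambda_ref_b, gamma = gamma,
      cdom_fraction = cdom_fraction, cdom_slope = cdom_slope,
      lambda_ref_cdom = lambda_ref_cdom,
      bp_B = bp_B, bp_p = bp_p, lambda_ref_bp = lambda_ref_bp, ff_n = ff_n
    ),
    class = "water_params"
  )
}

load_table <- function(name) {
  if (is.null(the[[name]])) {
    path <- system.file("extdata", paste0(name, ".csv"), package = "oildroprt")
    the[[name]] <- readr::read_csv(path, show_col_types = FALSE)
  }
  the[[name]]
}

#' Pure-water absorption spectrum
#'
#' Clear-water absorption coefficients interpolated linearly from the
#' embedded published table (400--700 nm at 10 nm).
#'
#' @param wavelengths Wavelengths in nm (a [spectral_grid()] or numeric).
#' @return Numeric vector of absorption coefficients (1/m).
#' @examples
#' pure_water_absorption(c(440, 555, 670))
#' @export
pure_water_absorption <- function(wavelengths) {
  grid <- as_grid(wavelengths)
  tab <- load_table("pure_water_absorption")
  if (min(grid) < min(tab$wavelength_nm) || max(grid) > max(tab$wavelength_nm)) {
    abort("wavelength outside the tabulated pure-water absorption range")
  }
  approx(tab$wavelength_nm, tab$a_m1, xout = as.numeric(grid))$y
}

#' Pure-seawater scattering spectrum
#'
#' Power law \eqn{b_w(\lambda) = b_w(\lambda_0) (\lambda_0/\lambda)^\gamma}
#' with constants from [water_params()].
#'
#' @inheritParams pure_water_absorption
#' @param params A [water_params()] list.
#' @return Numeric vector of scattering coefficients (1/m).
#' @export
pure_water_scattering <- function(wavelengths, params = water_params()) {
  grid <- as_grid(wavelengths)
  params$b_water_ref * (params$lambda_ref_b / as.numeric(grid))^params$gamma
}

#' Particulate (phytoplankton) absorption spectrum
#'
#' Power law in chlorophyll, \eqn{a_p(\lambda) = A(\lambda)\,
#' \mathrm{chl}^{E(\lambda)}}, with the embedded coefficient table: amplitude
#' anchored at the published 440-nm relation a_p(440) = 0.0378 chl^0.627 and
#' spectral shape from the standard normalized chlorophyll-specific
#' absorption curve.
#'
#' @inheritParams pure_water_absorption
#' @param chl Chlorophyll-a concentration in mg/m3 (>= 0).
#' @return Numeric vector of absorption coefficients (1/m).
#' @export
particle_absorption <- function(wavelengths, chl) {
  if (chl < 0) abort("chl must be >= 0")
  grid <- as_grid(wavelengths)
  tab <- load_table("chl_specific_absorption")
  A <- approx(tab$wavelength_nm, tab$A, xout = as.numeric(grid))$y
  E <- approx(tab$wavelength_nm, tab$E, xout = as.numeric(grid))$y
  if (chl == 0) return(rep(0, length(grid)))
  A * chl^E
}

#' CDOM absorption spectrum
#'
#' Exponential model tied to particulate absorption at the reference band:
#' \eqn{a_{CDOM}(\lambda) = f_c\, a_p(\lambda_{ref})
#' \exp(-S(\lambda - \lambda_{ref}))}.
#'
#' @inheritParams particle_absorption
#' @param params A [water_params()] list.
#' @return Numeric vector of absorption coefficients (1/m).
#' @export
cdom_absorption <- function(wavelengths, chl, params = water_params()) {
  if (chl < 0) abort("chl must be >= 0")
  grid <- as_grid(wavelengths)
  a440 <- particle_absorption(params$lambda_ref_cdom, chl)
  params$cdom_fraction * a440 *
    exp(-params$cdom_slope * (as.numeric(grid) - params$lambda_ref_cdom))
}

# Morel chlorophyll-dependent spectral slope of particulate scattering,
# clipped to [-1, 0] and zero for chl >= 2 mg/m3
bp_spectral_slope <- function(chl) {
  if (chl >= 2) return(0)
  min(0, max(-1, 0.5 * (log10(chl) - 0.3)))
}

#' Particulate scattering spectrum
#'
#' Loisel-Morel law \eqn{b_p(\lambda) = B\,\mathrm{chl}^{p}
#' (\lambda/\lambda_0)^{v(\mathrm{chl})}} with the Morel chlorophyll-dependent
#' exponent \eqn{v = 0.5(\log_{10}\mathrm{chl} - 0.3)}, clipped to
#' \eqn{[-1, 0]} and zero for chl >= 2 mg/m3, so clear water scatters
#' blue-enhanced and green water spectrally flat.
#'
#' @inheritParams cdom_absorption
#' @return Numeric vector of scattering coefficients (1/m).
#' @export
particle_scattering <- function(wavelengths, chl, params = water_params()) {
  if (chl < 0) abort("chl must be >= 0")
  grid <- as_grid(wavelengths)
  if (chl == 0) return(rep(0, length(grid)))
  v <- bp_spectral_slope(chl)
  params$bp_B * chl^params$bp_p *
    (as.numeric(grid) / params$lambda_ref_bp)^v
}

# chlorophyll-dependent particulate backscattering ratio (Ulloa-style)
particle_bb_fraction <- function(chl) {
  0.002 + 0.01 * (0.5 - 0.25 * log10(chl))
}

#' Bulk scattering phase function of Case-1 water
#'
#' Mixture of the pure-seawater (Rayleigh-like) phase function and a
#' Fournier-Forand particulate phase function, weighted by the scattering
#' fractions \eqn{b_w/b_{tot}} and \eqn{b_p/b_{tot}} at the requested
#' wavelength. The particulate component's backscattering ratio is the
#' chlorophyll-dependent \eqn{b_{bp}/b_p = 0.002 + 0.01(0.5 -
#' 0.25\log_{10}\mathrm{chl})}.
#'
#' @param chl Chlorophyll-a concentration in mg/m3 (> 0).
#' @param lambda Wavelength in nm.
#' @param params A [water_params()] list.
#' @return A [phase_function()].
#' @export
water_phase_function <- function(chl, lambda, params = water_params()) {
  if (chl <= 0) abort("chl must be > 0")
  bw <- pure_water_scattering(lambda, params)
  bp <- particle_scattering(lambda, chl, params)
  pr <- pf_rayleigh()
  pp <- pf_fournier_forand(bb_fraction = particle_bb_fraction(chl), n = params$ff_n)
  w <- bw / (bw + bp)
  phase_function(pr$angle_deg, w * pr$value + (1 - w) * pp$value)
}

#' Inherent optical properties of Case-1 ocean water
#'
#' Assembles the absorption and scattering budget of natural seawater as a
#' function of chlorophyll-a concentration: pure water, phytoplankton
#' particles, and CDOM. Total coefficients are exact sums of the components.
#'
#' @param chl Chlorophyll-a concentration in mg/m3 (> 0).
#' @param wavelengths Wavelengths in nm (defaults to the 27-band grid).
#' @param params A [water_params()] list.
#' @return A tibble of class `water_iops` with columns `wavelength`,
#'   `a_water`, `a_particle`, `a_cdom`, `a_tot`, `b_water`, `b_particle`,
#'   `b_tot` (all 1/m). The chlorophyll value, parameters and the two
#'   component phase functions (`pf_water`, `pf_particle`) are stored as
#'   attributes.
#' @examples
#' w <- water_iops(0.1, c(440, 555, 670))
#' w$a_tot - (w$a_water + w$a_particle + w$a_cdom) # exactly zero
#' @export
water_iops <- function(chl, wavelengths = default_grid(),
                       params = water_params()) {
  if (chl <= 0) abort("chl must be > 0")
  grid <- as_grid(wavelengths)
  out <- tibble(
    wavelength = as.numeric(grid),
    a_water = pure_water_absorption(grid),
    a_particle = particle_absorption(grid, chl),
    a_cdom = cdom_absorption(grid, chl, params),
    b_water = pure_water_scattering(grid, params),
    b_particle = particle_scattering(grid, chl, params)
  ) |>
    mutate(
      a_tot = .data$a_water + .data$a_particle + .data$a_cdom,
      b_tot = .data$b_water + .data$b_particle
    )
  structure(
    out,
    chl = chl,
    trophic = trophic_class(chl),
    params = params,
    pf_water = pf_rayleigh(),
    pf_particle = pf_fournier_forand(
      bb_fraction = particle_bb_fraction(chl), n = params$ff_n
    ),
    class = c("water_iops", class(out))
  )
}
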