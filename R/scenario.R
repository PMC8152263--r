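#' Simulation scenario: boundary conditions of the radiative transfer run
#'
#' Collects every boundary condition of the simulated experiment: solar
#' geometry, sea state, receiver geometry, water column extent, the oil-bearing
#' surface mixed layer, bottom reflectance and the photon budget.
#'
#' @param sun_zenith Sun zenith angle in degrees (default 30).
#' @param wind_speed Wind speed in m/s for the Cox-Munk slope distribution
#'   (default 5).
#' @param receiver_half_angle Receiver half-angle in degrees for the
#'   nadir-viewing radiance tally at 0+ (default 3.5, typical of field
#'   radiometers).
#' @param ocean_depth Water column depth in m (default 1000; deep enough that
#'   the bottom does not influence the reflectance).
#' @param mixed_layer_depth Depth of the oil-bearing surface mixed layer in m
#'   (default 30).
#' @param oil_ppm Oil volume concentration in the mixed layer, ppm
#'   (default 1).
#' @param bottom_mirror,bottom_diffuse Probabilities of specular and
#'   Lambertian bottom reflection (defaults 0.02 and 0.08; the rest is
#'   absorbed).
#' @param sky_diffuse_fraction Function of wavelength (nm) giving the diffuse
#'   fraction of downwelling sky irradiance; default declines smoothly from
#'   0.35 at 400 nm to 0.15 at 700 nm. Diffuse radiance is
#'   cardioid-distributed.
#' @param n_photons Photons traced per wavelength (default 1e5; desk-scale.
#'   Increase for publication-quality noise).
#' @param n_batches Batches used for the Monte Carlo standard error.
#' @param weight_cutoff Photon weight below which the residual weight is
#'   deposited as water-column absorption and the photon terminated.
#' @param salinity,temperature Seawater state for the refractive index.
#' @return A list of class `rt_scenario`.
#' @examples
#' sc <- scenario(n_photons = 1e4)
#' @export
scenario <- function(sun_zenith = 30, wind_speed = 5, receiver_half_angle = 3.5,
                     ocean_depth = 1000, mixed_layer_depth = 30, oil_ppm = 1,
                     bottom_mirror = 0.02, bottom_diffuse = 0.08,
                     sky_diffuse_fraction = sky_diffuse_default,
                     n_photons = 1e5, n_batches = 100, weight_cutoff = 1e-6,
                     salinity = 35, temperature = 20) {
  if (ocean_depth <= 0 || mixed_layer_depth <= 0) abort("depths must be > 0")
  if (mixed_layer_depth > ocean_depth) {
    abort("mixed_layer_depth must not exceed ocean_depth")
  }
  for (f in c(bottom_mirror, bottom_diffuse)) {
    if (f < 0 || f > 1) abort("bottom reflectance fractions must be in [0, 1]")
  }
  if (bottom_mirror + bottom_diffuse > 1) {
    abort("bottom_mirror + bottom_diffuse must not exceed 1")
  }
  if (sun_zenith < 0 || sun_zenith >= 90) abort("sun_zenith must be in [0, 90)")
  if (wind_speed < 0) abort("wind_speed must be >= 0")
  if (oil_ppm < 0) abort("oil_ppm must be >= 0")
  if (n_photons < 1) abort("n_photons must be >= 1")
  structure(
    list(
      sun_zenith = sun_zenith, wind_speed = wind_speed,
      receiver_half_angle = receiver_half_angle,
      ocean_depth = ocean_depth, mixed_layer_depth = mixed_layer_depth,
      oil_ppm = oil_ppm,
      bottom_mirror = bottom_mirror, bottom_diffuse = bottom_diffuse,
      sky_diffuse_fraction = sky_diffuse_fraction,
      n_photons = as.integer(n_photons), n_batches = as.integer(n_batches),
      weight_cutoff = weight_cutoff,
      salinity = salinity, temperature = temperature
    ),
    class = "rt_scenario"
  )
}

#' @rdname scenario
#' @param lambda Wavelength in nm.
#' @export
sky_diffuse_default <- function(lambda) {
  0.35 - 0.20 * (lambda - 400) / 300
}

#' Cox-Munk slope variance
#'
#' Total mean-square slope of the wind-roughened sea surface,
#' \eqn{\sigma^2 = 0.003 + 0.00512 W} (isotropic variant, W in m/s).
#'
#' @param wind_speed Wind speed in m/s (>= 0).
#' @return Total slope variance (dimensionless).
#' @export
cox_munk_variance <- function(wind_speed) {
  if (any(wind_speed < 0)) abort("wind_speed must be >= 0")
  0.003 + 0.00512 * wind_speed
}

#' Sample sea-surface wave slopes
#'
#' Draws facet slope components from the isotropic Cox-Munk Gaussian (each
#' component has variance \eqn{\sigma^2/2}) and returns the corresponding
#' upward facet normals. Uses R's RNG stream.
#'
#' @param wind_speed Wind speed in m/s.
#' @param n Number of draws.
#' @return A tibble with slope components `sx`, `sy` and unit normal
#'   components `nx`, `ny`, `nz` (z up).
#' @export
sample_surface_slope <- function(wind_speed, n = 1) {
  s2 <- cox_munk_variance(wind_speed)
  sx <- rnorm(n, 0, sqrt(s2 / 2))
  sy <- rnorm(n, 0, sqrt(s2 / 2))
  nrm <- sqrt(1 + sx^2 + sy^2)
  tibble(sx = sx, sy = sy, nx = -sx / nrm, ny = -sy / nrm, nz = 1 / nrm)
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized Fresnel reflectances at a dielectric
#' interface. For relative index below 1 (photon moving from water to air)
#' incidence beyond the critical angle returns total internal reflection.
#'
#' @param incidence_angle Angle of incidence in degrees, within [0, 90].
#' @param n_rel Ratio of transmitted-side to incident-side refractive index.
#' @return Reflectance fraction in [0, 1].
#' @examples
#' fresnel_reflectance(0, 1.34)   # ~0.0211
#' fresnel_reflectance(90, 1.34)  # 1
#' @export
fresnel_reflectance <- function(incidence_angle, n_rel) {
  if (any(incidence_angle < 0 | incidence_angle > 90)) {
    abort("incidence_angle must be in [0, 90] degrees")
  }
  if (n_rel <= 0) abort("n_rel must be > 0")
  vapply(incidence_angle, function(a) {
    fresnel_cpp(cos(a * pi / 180), n_rel)
  }, numeric(1))
}

#' Combine water and oil IOPs into a layered medium
#'
#' Builds the layered optical description the Monte Carlo solver consumes.
#' With oil present, the column has two layers: the surface mixed layer
#' (water plus oil, added coefficient by coefficient, with the oil rescaled
#' linearly to `scenario$oil_ppm`) above pure water down to the bottom.
#' Without oil (or at 0 ppm) the column is a single homogeneous layer.
#'
#' @param water A [water_iops()] object.
#' @param oil An `oil_iops` object on the same wavelength grid, or `NULL`.
#' @param scenario An [scenario()] object.
#' @return A list of class `layered_medium`: per-layer depth bounds, total
#'   `a` and `b` spectra, and per-component scattering tables (component
#'   scattering spectrum plus phase function(s)).
#' @export
mix_iops <- function(water, oil = NULL, scenario = oildroprt::scenario()) {
  lam <- water$wavelength
  if (!is.null(oil)) {
    if (!isTRUE(all.equal(lam, oil$wavelength))) {
      abort("water and oil IOPs are on different wavelength grids")
    }
    oil <- scale_oil_iops(oil, scenario$oil_ppm)
    if (scenario$oil_ppm == 0) oil <- NULL
  }
  water_components <- list(
    list(name = "seawater", b = water$b_water, pf = attr(water, "pf_water")),
    list(name = "particles", b = water$b_particle, pf = attr(water, "pf_particle"))
  )
  deep <- list(
    a = water$a_tot, b = water$b_tot, components = water_components
  )
  layers <- if (is.null(oil)) {
    list(c(deep, list(z_top = 0, z_bottom = scenario$ocean_depth)))
  } else {
    top <- list(
      z_top = 0, z_bottom = scenario$mixed_layer_depth,
      a = water$a_tot + oil$a_oil,
      b = water$b_tot + oil$b_oil,
      components = c(water_components, list(
        list(name = "oil", b = oil$b_oil, pf = attr(oil, "pf"))
      ))
    )
    list(top, c(deep, list(z_top = scenario$mixed_layer_depth,
                           z_bottom = scenario$ocean_depth)))
  }
  structure(
    list(wavelength = lam, layers = layers),
    class = "layered_medium"
  )
}
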