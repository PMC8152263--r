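#' Simulate remote sensing reflectance by Monte Carlo photon tracing
#'
#' Traces photon packets through the atmosphere-ocean system for every
#' wavelength of the medium's grid and returns the remote sensing reflectance
#' at 0+ (water-leaving radiance within the nadir receiver cone divided by
#' the downwelling irradiance just above the surface), its Monte Carlo
#' standard error, and the photon-weight budget.
#'
#' Photons are launched as a direct solar beam at the scenario sun zenith
#' plus a cardioid-distributed diffuse sky component, refracted or reflected
#' at a Cox-Munk wavy surface, propagated with exponential path sampling
#' against the beam attenuation `a + b`, and scattered by a component (pure
#' seawater, particles, oil) chosen in proportion to its scattering
#' coefficient, with the deflection drawn from that component's phase
#' function. Absorption is handled by weight attenuation; residual weight
#' below `weight_cutoff` is deposited as water-column absorption so the
#' budget closes exactly. Surface-reflected sky and sun light never enters
#' the water and is excluded from the water-leaving tally by construction.
#'
#' @param medium A `layered_medium` from [mix_iops()], or a [water_iops()]
#'   object (a homogeneous, unpolluted column).
#' @param scenario An [scenario()] object.
#' @param oil Optional `oil_iops`, used when `medium` is a `water_iops`.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called so
#'   the run is exactly reproducible.
#' @return A tibble of class `rrs_result` with per-wavelength columns:
#'   `rrs` (sr^-1), `stderr`, `r0minus` (irradiance reflectance just below
#'   the surface), `budget_absorbed`, `budget_bottom`,
#'   `budget_water_leaving`, `budget_surface_lost` (fractions summing to 1).
#' @examples
#' \donttest{
#' w <- water_iops(0.1, c(440, 555, 670))
#' r <- simulate_rrs(w, scenario(n_photons = 2e4), seed = 1)
#' }
#' @export
simulate_rrs <- function(medium, scenario = oildroprt::scenario(), oil = NULL,
                         seed = NULL) {
  if (inherits(medium, "water_iops")) {
    medium <- mix_iops(medium, oil, scenario)
  }
  if (!inherits(medium, "layered_medium")) {
    abort("medium must be a layered_medium or water_iops")
  }
  if (!is.null(seed)) set.seed(seed)
  lam <- medium$wavelength
  n <- scenario$n_photons
  nb <- scenario$n_batches
  omega <- 2 * pi * (1 - cos(scenario$receiver_half_angle * pi / 180))
  s2 <- cox_munk_variance(scenario$wind_speed)

  # inverse-CDF tables, computed once per distinct phase function
  cdf_cache <- new.env(parent = emptyenv())
  pf_table <- function(pf) {
    key <- paste0("k", signif(sum(pf$value), 15))
    if (is.null(cdf_cache[[key]])) cdf_cache[[key]] <- pf_inverse_cdf(pf)
    cdf_cache[[key]]
  }

  rows <- purrr::map(seq_along(lam), function(j) {
    layer_bottom <- map_dbl(medium$layers, "z_bottom")
    layer_a <- map_dbl(medium$layers, function(l) l$a[j])
    layer_b <- map_dbl(medium$layers, function(l) l$b[j])
    cumfrac <- list()
    tabs <- list()
    for (li in seq_along(medium$layers)) {
      comps <- medium$layers[[li]]$components
      bcomp <- map_dbl(comps, function(cp) cp$b[j])
      bt <- sum(bcomp)
      cumfrac[[li]] <- if (bt > 0) cumsum(bcomp) / bt else rep(1, length(bcomp))
      tabs[[li]] <- map(comps, function(cp) {
        pf <- cp$pf
        if (!inherits(pf, "phase_function")) pf <- pf[[j]]
        pf_table(pf)
      })
    }
    fd <- min(1, max(0, scenario$sky_diffuse_fraction(lam[j])))
    nw <- seawater_refractive_index(lam[j], scenario$salinity,
                                    scenario$temperature)
    res <- mc_simulate_cpp(
      n, nb, layer_bottom, layer_a, layer_b, cumfrac, tabs,
      scenario$sun_zenith, fd, s2, scenario$receiver_half_angle, nw,
      scenario$bottom_mirror, scenario$bottom_diffuse,
      scenario$weight_cutoff
    )
    sizes <- ceiling((seq_len(nb)) * n / nb) - ceiling((seq_len(nb) - 1) * n / nb)
    batch_rrs <- res$cone_batch / (sizes * omega)
    tibble(
      wavelength = lam[j],
      rrs = res$cone_sum / (n * omega),
      stderr = stats::sd(batch_rrs) / sqrt(nb),
      r0minus = if (res$ed0m > 0) res$eu0m / res$ed0m else 0,
      budget_absorbed = res$absorbed_column / n,
      budget_bottom = res$absorbed_bottom / n,
      budget_water_leaving = res$water_leaving / n,
      budget_surface_lost = res$surface_lost / n
    )
  })
  out <- bind_rows(rows)
  structure(
    out,
    scenario = scenario,
    n_photons = n,
    class = c("rrs_result", class(out))
  )
}
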