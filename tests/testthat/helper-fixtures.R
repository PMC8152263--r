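# shared small fixtures for fast tests

tiny_grid <- function() spectral_grid(c(440, 555, 670))

quick_scenario <- function(n_photons = 2e4, ...) {
  scenario(n_photons = n_photons, n_batches = 20, ...)
}

# hand-built homogeneous medium with a single scattering component,
# for controlled Monte Carlo physics checks
homogeneous_medium <- function(a, b, pf, wavelengths = 550, depth = 1000) {
  structure(
    list(
      wavelength = as.numeric(wavelengths),
      layers = list(list(
        z_top = 0, z_bottom = depth,
        a = rep(a, length(wavelengths)),
        b = rep(b, length(wavelengths)),
        components = list(list(
          name = "medium",
          b = rep(b, length(wavelengths)),
          pf = pf
        ))
      ))
    ),
    class = "layered_medium"
  )
}

budget_sum <- function(r) {
  r$budget_absorbed + r$budget_bottom + r$budget_water_leaving +
    r$budget_surface_lost
}
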