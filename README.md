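# oildroprt

Dispersed oil — clouds of micrometre-sized droplets mixed into the upper
ocean — is not detected by the slick-oriented sensors used for spill
monitoring, yet it measurably perturbs ocean color. `oildroprt` is an R
package for simulating that perturbation end to end, for researchers in
marine optics and ocean-color remote sensing:

* **Case-1 bio-optical water model** — absorption and scattering of natural
  seawater as a function of chlorophyll-a concentration
  (`water_iops()`): published pure-water absorption, power-law seawater
  scattering, particulate absorption `a_p = A(λ)·chl^E`, CDOM exponential,
  Loisel–Morel particulate scattering, and a Fournier–Forand particulate
  phase function selected by the chlorophyll-dependent backscattering ratio.
* **Lorenz–Mie droplet engine** (`mie_single()`, `polydisperse_iops()`) —
  efficiencies and phase functions of polydisperse oil droplets from complex
  refractive-index spectra and volume size distributions, with the size
  parameter `x = πD·n_med/λ` taken in the seawater medium.
* **Synthetic oil templates** (`oil_template()`, `make_oil_index()`,
  `make_psd()`) — biodiesel-like (BD), lubricant-like (CL) and crude-like
  (FL) optical constants and 2–3-mode log-normal size distributions that
  emulate the structure of laboratory measurements (amplitudes are clearly
  labelled surrogates).
* **Monte Carlo radiative transfer** (`simulate_rrs()`) — photon-packet
  transport through a two-layer ocean (oil in the top 30 m mixed layer)
  under a Cox–Munk wind-roughened surface, yielding the remote sensing
  reflectance at 0⁺,

  $$R_{rs}(\lambda) = \frac{L_w(\lambda)}{E_d(\lambda)} \quad [\mathrm{sr^{-1}}],$$

  with Monte Carlo standard errors and an exactly closed photon-weight
  budget.
* **Ocean-color analytics** (`band_ratio()`, `band_difference()`,
  `color_index()`, `fold_change()`, `band_metrics_table()`) — the standard
  diagnostics, including the color index

  $$CI = R_{rs}(\lambda_g) - \Big[R_{rs}(\lambda_b) +
  \tfrac{\lambda_g-\lambda_b}{\lambda_r-\lambda_b}
  \big(R_{rs}(\lambda_r)-R_{rs}(\lambda_b)\big)\Big]$$

  on the instrument bands nearest 443/555/670 nm.
* **Experiment pipeline** (`run_experiment()`,
  `summarize_directional_findings()`) — the full 3 water types × {none, BD,
  CL, FL} grid with band-metric tables, fold changes, a run manifest, and a
  pass/fail report of the qualitative dispersed-oil signatures.

Everything is tibble-first and pipe-friendly; results have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Unpolluted oligotrophic water (chl-a = 0.1 mg/m³) at the color-index bands:

```r
library(oildroprt)

water <- water_iops(0.1, c(440, 555, 670))
water
#>   wavelength a_water a_particle    a_cdom  b_water b_particle  a_tot  b_tot
#> 1        440 0.00635    0.00892 0.00178   0.00498      0.0824 0.0171 0.0874
#> 2        555 0.0592     0.00290 0.000357  0.00183      0.0709 0.0625 0.0727
#> 3        670 0.439      0.00531 0.0000713 0.000810     0.0627 0.444  0.0635

rrs <- simulate_rrs(water, scenario(n_photons = 1e6), seed = 1)
as.data.frame(rrs)[, c("wavelength", "rrs", "stderr")]
#>   wavelength          rrs       stderr
#> 1        440 9.507454e-03 0.0005999211
#> 2        555 1.028378e-03 0.0001605596
#> 3        670 9.869787e-05 0.0000328623

1e3 * color_index(rrs, 440, 555, 670)
#> [1] -3.77
```

The spectrum is classic clear-ocean: high blue reflectance (~9.5×10⁻³ sr⁻¹
at 440 nm), low green, nearly black red (water absorption 0.44 m⁻¹ at
670 nm). The color index — the distance of the green band below the
blue–red baseline — is about −3.8×10⁻³ sr⁻¹ at this photon budget
(published value −3.11×10⁻³ sr⁻¹; at 10⁶ photons the Monte Carlo noise on
the blue band still moves CI by several tenths).

Adding a dispersed oil takes two more lines:

```r
oil <- oil_iops("CL", c(440, 555, 670), ppm = 1)   # Lorenz-Mie, 1 ppm
polluted <- simulate_rrs(water, scenario(n_photons = 1e6), oil = oil, seed = 2)
fold_change(polluted, rrs, c(400, 700))            # broadband R_rs increase
```

and the full study grid is
`run_experiment(experiment_config()) |> summarize_directional_findings()`.
A command-line wrapper for single simulations and the full grid ships in
`inst/cli/oildroprt.R`.

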