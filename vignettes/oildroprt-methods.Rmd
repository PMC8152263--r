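---
title: "Simulating the ocean-color signature of dispersed oil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the ocean-color signature of dispersed oil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Dispersed oil — micrometre-sized droplets mixed into the upper water column
rather than floating as a slick — is essentially invisible to the oil-spill
sensors in operational use, yet it changes the inherent optical properties
(IOPs) of seawater and therefore the remote sensing reflectance
$R_{rs} = L_w / E_d$ (water-leaving radiance over downwelling irradiance just
above the surface, sr$^{-1}$). `oildroprt` simulates that perturbation end to
end: a chlorophyll-parameterized model of natural ocean water, a Lorenz–Mie
model of the oil-droplet IOPs, a Monte Carlo solution of radiative transfer
under a wind-roughened surface, and the ocean-color analytics (band ratios,
band differences, color index) used to quantify the change. This vignette is
the package's account of the science: the models, the tunable parameters and
their defaults, the numerical choices, and the limits of what the synthetic
experiments can show.

## The bio-optical water model

Case-1 waters are those whose optics covary with the chlorophyll-a
concentration `chl` (mg/m$^3$); the package uses `chl` = 0.1, 1 and
10 mg/m$^3$ as representative oligotrophic, mesotrophic and eutrophic
conditions, with `chl` constant over depth. Total absorption and scattering
are exact sums of components:

$$a_{tot} = a_w + a_p + a_{CDOM}, \qquad b_{tot} = b_w + b_p.$$

* **Pure water absorption** $a_w(\lambda)$ is linearly interpolated from the
  published clear-water table shipped in `inst/extdata` (400–700 nm, 10-nm
  steps).
* **Pure seawater scattering** is the power law
  $b_w(\lambda) = b_w(550)\,(550/\lambda)^{4.32}$ with
  $b_w(550) = 0.0019\ \mathrm{m^{-1}}$.
* **Particulate (phytoplankton) absorption** is
  $a_p(\lambda) = A(\lambda)\,\mathrm{chl}^{E}$. The amplitude is anchored at
  the widely used power law $a_p(440) = 0.0378\,\mathrm{chl}^{0.627}$, and
  the spectral shape of $A(\lambda)$ follows the standard normalized
  chlorophyll-specific absorption curve. Among the published
  parameterization family this anchor reproduces observed oligotrophic
  blue-band reflectance well; both tables ship as CSV and can be replaced.
* **CDOM absorption** is tied to the particles:
  $a_{CDOM}(\lambda) = f_c\,a_p(440)\,e^{-S(\lambda - 440)}$ with the common
  Case-1 defaults $f_c = 0.2$ and $S = 0.014\ \mathrm{nm^{-1}}$.
* **Particulate scattering** follows
  $b_p(\lambda) = 0.416\,\mathrm{chl}^{0.766}(\lambda/550)^{v}$ with the
  chlorophyll-dependent slope $v = 0.5(\log_{10}\mathrm{chl} - 0.3)$ clipped
  to $[-1, 0]$ and set to zero for chl $\ge 2$. The exponent applies to
  $\lambda/\lambda_0$ (not its inverse), so clear water scatters
  blue-enhanced and green water is spectrally flat — the physically expected
  behaviour of the cited parameterization family.

The bulk phase function mixes a Rayleigh-like pure-seawater shape
($\propto 1 + 0.835\cos^2\theta$) with a Fournier–Forand particulate shape,
weighted by $b_w/b_{tot}$ and $b_p/b_{tot}$. The Fournier–Forand slope
parameter is solved (at fixed relative index $n = 1.05$) so that the
particulate backscattering ratio equals
$b_{bp}/b_p = 0.002 + 0.01\,(0.5 - 0.25\log_{10}\mathrm{chl})$, the standard
chlorophyll-dependent value. All phase functions use the repo-wide
convention $\int_0^\pi p(\theta)\,2\pi\sin\theta\,d\theta = 1$, evaluated by
trapezoidal quadrature on a 0–180° grid with 0.5° steps and logarithmic
refinement below 5° (forward peaks dominate sampling accuracy; the
integrable forward divergence of Fournier–Forand is clamped at the smallest
tabulated angle).

## Oil droplet optics

Droplet IOPs come from the Lorenz–Mie partial-wave series for homogeneous
spheres (`mie_single()`): logarithmic derivative of the internal
Riccati–Bessel function by downward recurrence, external functions by upward
recurrence, truncation at $n_{max} = \lceil x + 4x^{1/3} + 2\rceil$. The
size parameter uses the wavelength in the medium,
$x = \pi D\,n_{med}/\lambda_{vac}$, with the seawater index from an
empirical fit in wavelength, salinity (35 PSU) and temperature (20 °C). The
medium is treated as non-absorbing in the Mie solution — saline-water
absorption enters the radiative transfer through the water IOPs, not through
the droplet model — and the droplet's complex index is divided by the real
medium index. The test suite cross-checks the series against an
independently coded continued-fraction implementation ($10^{-6}$ relative on
the efficiencies) and against the Rayleigh closed form at $x = 10^{-3}$.

`polydisperse_iops()` integrates number-weighted cross sections over a
binned volume size distribution (ppm/µm; number density recovered through
the sphere volume $\pi D^3/6$), so the absorption and scattering
coefficients are exactly linear in the total volume concentration, and the
suspension phase function is the cross-section-weighted average of the
single-sphere phase functions. Polydisperse oil phase functions show the
characteristic side maximum near 90–100° — the primary rainbow of droplets
with relative index around 1.1 — which `oil_phase_peak_check()` locates.

## Synthetic oil templates

The measured optical constants and droplet size distributions of the three
study oils (a biodiesel BD, a cylinder lubricant CL, a crude FL) are
figure-only in the source study, so the package ships synthetic templates
that emulate their statistical structure; every numeric amplitude is a
calibrated surrogate, never a measured value. The structural constraints
are: real index a smooth 4th-order polynomial within 1.45–1.53; imaginary
index exponentially decreasing for CL and FL with the FL amplitude two
orders of magnitude larger (strong blue absorption); a three-bump structure
for BD; and 2–3-mode log-normal volume size distributions (geometric width
1.5 by default) with main modes peaking at 5 µm (BD, FL) and 7 µm (CL) and
negligible volume above ~100 µm.

The free amplitudes were calibrated once so that the qualitative experiment
outcome is physically coherent across trophic types: FL's absorption impact
on clear-water total absorption is far larger than BD's or CL's, all three
oils contribute large scattering impacts, and the biodiesel template uses a
strongly dispersive real index (1.51 at 400 nm to 1.45 at 700 nm). That
dispersion is the one physical lever that makes BD's *backscatter*
blue-weighted — backward scattering of weak refractors scales steeply with
$n_{rel} - 1$ — which is what raises the green-to-red (550/680) band ratio
of BD-polluted water while lubricant- and crude-like oils lower it. With
molecular scattering dominating the backscatter of clear water, no
achievable droplet size structure alone reproduces that signature: sub-µm
modes scatter red-enhanced in the Mie resonance region, and µm modes are
spectrally too flat. `jitter_template()` provides seeded ±10% perturbations
for robustness sweeps; the structural invariants survive by construction.

## Monte Carlo radiative transfer

`simulate_rrs()` traces photon packets per wavelength through a
plane-parallel ocean of one or two homogeneous layers (oil occupies the top
30 m mixed layer at 1 ppm by default; the column is 1000 m deep so the
bottom — 2% specular, 8% Lambertian, 90% absorbing — never influences the
result, which the tests verify). Launch mixes a direct solar beam at 30°
zenith with a cardioid-distributed diffuse sky whose fraction declines
linearly from 0.35 (400 nm) to 0.15 (700 nm) — $R_{rs}$ is weakly sensitive
to this split for a near-nadir receiver, and the curve is configurable. The
surface is an isotropic Cox–Munk facet model (slope variance
$\sigma^2 = 0.003 + 0.00512\,W$, $W = 5$ m/s by default) with unpolarized
Fresnel reflection/refraction at the sampled facet; reflected directions
that still face the surface re-test it, and sky photons reflected at the
surface are tallied as surface loss, never as water-leaving signal.

Transport is semi-analog: path lengths are exponential against $c = a + b$,
and at each collision the absorbed fraction $a/c$ is deposited while the
packet scatters with weight multiplied by the single-scattering albedo. The
scattering component (seawater molecules, particles, oil) is chosen in
proportion to its share of $b$, and the deflection is drawn from that
component's phase function by inverse-CDF lookup (4096 equispaced quantiles
of $\cos\theta$, linear interpolation). Packets below the weight cutoff
($10^{-6}$) deposit their residual weight as water-column absorption and
terminate. This cutoff — rather than boosted-survivor Russian roulette —
makes the four-way budget (column absorption, bottom absorption,
water-leaving, surface loss) telescope to exactly 1 on every run, at the
price of a truncation bias bounded by the cutoff itself, i.e. $\le 10^{-6}$
of the launched weight and far below the Monte Carlo noise at any photon
budget used here.

$R_{rs}$ is estimated by binning the weight of water-leaving packets within
a receiver cone about the zenith (half-angle 3.5°, as in field radiometers)
and dividing by the cone solid angle and the launched weight ($E_d$ at
$0^+$). The standard error comes from batch means (100 batches by default)
and scales as $n^{-1/2}$, which the acceptance suite checks. The irradiance
reflectance just beneath the surface ($E_u/E_d$ at $0^-$) is tallied too and
validated against the single-scattering estimate
$0.33\,b_b/(a + b_b)$ within 35% for a flat-surface isotropic test medium.

**Problem sizes.** The package default is $10^5$ photons per wavelength —
enough for structural work. The acceptance computations use $10^7$ photons
per band for the oligotrophic color index (a few percent noise on the blue
band, which dominates the CI), and $6\times10^5$ photons per band for the
12-cell directional grid on the 9-band reduced grid. For that grid the
receiver half-angle is widened to 30°: with a 3.5° cone the unpolluted
red-band reflectance of clear water (~$10^{-4}\ \mathrm{sr^{-1}}$) receives
only a couple of photons at desk scale, while near-nadir radiance varies
slowly enough with angle that the wide cone preserves every sign and
ordering being tested. These sizes are the package's own desk-scale choices;
the same code runs at publication scale by raising `n_photons`.

## Ocean-color analytics

`band_ratio()`, `band_difference()`, `color_index()` and `fold_change()`
operate on any spectrum table with `wavelength` and `rrs` columns. Band
lookup is nearest-neighbour with a 5-nm tolerance, matching the
interchangeable use of adjacent instrument bands (440/443/445). The color
index

$$CI = R_{rs}(\lambda_g) - \left[R_{rs}(\lambda_b) +
\frac{\lambda_g - \lambda_b}{\lambda_r - \lambda_b}
\big(R_{rs}(\lambda_r) - R_{rs}(\lambda_b)\big)\right]$$

is the signed distance of the green band from the blue–red baseline; it
vanishes identically for spectra affine in $\lambda$ (a property test) and
is negative for clear ocean water. Percentage comparisons between polluted
and natural metrics use $100\,(x_{pol} - x_{nat})/|x_{nat}|$: dividing by
the *magnitude* keeps the sign of the change itself, which is the only
convention that reproduces the published sign pattern of CI changes (a
doubly-negative CI reports a negative relative difference, a sign-crossing
CI a positive one). Fold changes average the polluted/natural ratio over the
blue (400–510), green (510–590) and red (590–700 nm) ranges.

## Degenerate inputs and tie-breaks

Zero chlorophyll is allowed in the component formulas (power laws return
zero) but not in `water_iops()`; zero oil concentration collapses the
two-layer medium to the unpolluted column exactly; a zero-scattering medium
returns $R_{rs} = 0$ exactly with the budget split between absorption and
surface loss. Phase-function CDF inversion drops flat segments so the
quantile table stays strictly increasing; facet sampling rejects geometries
in which the photon cannot see the facet, and after 200 rejected attempts an
upward photon is treated as internally reflected (weight-conserving). Ties
in nearest-band lookup resolve to the lower band (`which.min`).

## Limitations

No Raman scattering, chlorophyll fluorescence or polarization; no Case-2
(sediment/mineral) constituents; droplets are homogeneous spheres (no
coatings, non-sphericity or effective-medium effects); the sea surface is
isotropic Cox–Munk without shadowing or whitecaps; chlorophyll and oil are
vertically uniform within their layers. The synthetic oil templates
reproduce the *structure* of the measured oils, not their values: passing
directional tests shows the pipeline responds to dispersed oil the way the
study found, not that any template matches a specific real oil. The one
quantitative bridge that needs no oil data at all — the color index of
unpolluted oligotrophic water — is reproduced within Monte Carlo noise and
model tolerance by `scripts/acceptance.R`.
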