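#' Synthetic oil optical templates
#'
#' The package ships three synthetic oil templates emulating the statistical
#' structure of laboratory measurements of a biodiesel (BD), a cylinder
#' lubricant (CL) and a crude oil (FL): a smooth 4th-order polynomial real
#' refractive index within 1.45--1.53, an imaginary index that decreases
#' exponentially with wavelength for CL and FL (FL about two orders of
#' magnitude larger) or shows three local maxima for BD, and 2--3-mode
#' log-normal volume size distributions with main modes at 5 um (BD, FL) and
#' 7 um (CL). All numeric amplitudes are calibrated surrogates, not measured
#' values; they are chosen once so that the qualitative impact ordering of
#' the three oils on clear ocean water holds (strong blue absorption for FL,
#' comparable large scattering impacts for all three).
#'
#' @param kind One of `"BD"`, `"CL"`, `"FL"`.
#' @return `oil_template()` returns a list of class `oil_template` with
#'   elements `kind`, `n_poly` (5 polynomial coefficients in
#'   u = (lambda - 550)/100), `k_model`, and `psd_modes` (tibble with
#'   `peak_um`, `sigma_g`, `fraction`).
#' @examples
#' tpl <- oil_template("CL")
#' idx <- make_oil_index("FL", c(440, 555, 670))
#' @export
oil_template <- function(kind = c("BD", "CL", "FL")) {
  kind <- match.arg(kind)
  tpl <- switch(kind,
    BD = list(
      kind = "BD",
      # strongly dispersive real index: biodiesel backscatter is blue-weighted
      n_poly = c(1.4760, -0.0210, 0.0018, -0.0003, 0.0001),
      k_model = list(
        type = "bumps",
        base = 8e-6, base_scale_nm = 150,
        centers = c(455, 545, 640),
        amplitudes = c(5.5e-5, 2.8e-5, 1.6e-5),
        widths = c(18, 16, 14)
      ),
      psd_modes = tibble(
        peak_um = c(0.5, 5, 15),
        sigma_g = c(1.4, 1.5, 1.5),
        fraction = c(0.03, 0.82, 0.15)
      )
    ),
    CL = list(
      kind = "CL",
      n_poly = c(1.4780, -0.0090, 0.0025, -0.0004, 0.0002),
      k_model = list(type = "exponential", amplitude = 2.5e-5, scale_nm = 110),
      psd_modes = tibble(
        peak_um = c(2, 7, 30),
        sigma_g = c(1.4, 1.5, 1.5),
        fraction = c(0.10, 0.60, 0.30)
      )
    ),
    FL = list(
      kind = "FL",
      n_poly = c(1.5050, -0.0100, 0.0030, -0.0005, 0.0002),
      k_model = list(type = "exponential", amplitude = 2.5e-3, scale_nm = 110),
      psd_modes = tibble(
        peak_um = c(1, 5, 25),
        sigma_g = c(1.4, 1.5, 1.5),
        fraction = c(0.06, 0.64, 0.30)
      )
    )
  )
  structure(tpl, class = "oil_template")
}

eval_template_n <- function(tpl, lam) {
  u <- (lam - 550) / 100
  n <- drop(outer(u, 0:4, `^`) %*% tpl$n_poly)
  pmin(1.53, pmax(1.45, n)) # hard clip keeps jittered variants in range
}

eval_template_k <- function(tpl, lam) {
  km <- tpl$k_model
  if (km$type == "exponential") {
    km$amplitude * exp(-(lam - 400) / km$scale_nm)
  } else {
    k <- km$base * exp(-(lam - 400) / km$base_scale_nm)
    for (j in seq_along(km$centers)) {
      k <- k + km$amplitudes[j] * exp(-(lam - km$centers[j])^2 / (2 * km$widths[j]^2))
    }
    k
  }
}

#' @rdname oil_template
#' @param wavelengths Wavelengths in nm.
#' @param template An `oil_template`; overrides `kind` when supplied.
#' @return `make_oil_index()` returns a tibble with columns `wavelength`,
#'   `n`, `k` (complex index spectrum of the pure oil).
#' @export
make_oil_index <- function(kind = c("BD", "CL", "FL"),
                           wavelengths = default_grid(), template = NULL) {
  tpl <- template %||% oil_template(kind)
  grid <- as_grid(wavelengths)
  lam <- as.numeric(grid)
  tibble(wavelength = lam, n = eval_template_n(tpl, lam), k = eval_template_k(tpl, lam))
}

#' @rdname oil_template
#' @param total_ppm Total volume concentration in ppm (> 0).
#' @param diameters Bin-center diameters in um; default 80 log-spaced bins
#'   over 0.25--90 um (negligible droplet volume above ~100 um).
#' @return `make_psd()` returns a tibble with columns `diameter_um`,
#'   `density_ppm_per_um`, normalized so that the trapezoidal integral of the
#'   density equals `total_ppm`.
#' @export
make_psd <- function(kind = c("BD", "CL", "FL"), total_ppm = 1,
                     diameters = 10^seq(log10(0.25), log10(90), length.out = 80),
                     template = NULL) {
  if (total_ppm <= 0) abort("total_ppm must be > 0")
  tpl <- template %||% oil_template(kind)
  dens <- rep(0, length(diameters))
  for (i in seq_len(nrow(tpl$psd_modes))) {
    pk <- tpl$psd_modes$peak_um[i]
    s <- log(tpl$psd_modes$sigma_g[i])
    f <- tpl$psd_modes$fraction[i]
    mu <- log(pk) + s^2 # ln-median such that the density peaks at peak_um
    dens <- dens + f * stats::dlnorm(diameters, meanlog = mu, sdlog = s)
  }
  raw <- sum(dens * trapezoid_weights(diameters))
  tibble(diameter_um = diameters, density_ppm_per_um = dens * total_ppm / raw)
}

#' @rdname oil_template
#' @param seed Integer seed for the perturbation draw.
#' @details `jitter_template()` applies seeded multiplicative perturbations
#'   (up to 10 percent) to the imaginary-index amplitude and the PSD mode
#'   fractions, for robustness sweeps. The real-index bounds and the sign
#'   structure of the imaginary index are preserved by construction.
#' @return `jitter_template()` returns a perturbed `oil_template`.
#' @export
jitter_template <- function(template, seed = 1) {
  tpl <- template
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  wig <- function(x) x * (1 + runif(length(x), -0.1, 0.1))
  if (tpl$k_model$type == "exponential") {
    tpl$k_model$amplitude <- wig(tpl$k_model$amplitude)
  } else {
    tpl$k_model$amplitudes <- wig(tpl$k_model$amplitudes)
    tpl$k_model$base <- wig(tpl$k_model$base)
  }
  f <- wig(tpl$psd_modes$fraction)
  tpl$psd_modes$fraction <- f / sum(f)
  tpl
}

#' Build dispersed-oil IOPs from a template
#'
#' Convenience wrapper: evaluates a synthetic oil template to a complex index
#' spectrum and size distribution, then runs the Lorenz-Mie polydisperse
#' integration.
#'
#' @inheritParams oil_template
#' @param wavelengths Wavelengths in nm.
#' @param ppm Total oil volume concentration in ppm.
#' @param template Optional `oil_template` overriding `kind`.
#' @param ... Passed to [polydisperse_iops()].
#' @return An `oil_iops` tibble (see [polydisperse_iops()]).
#' @export
oil_iops <- function(kind = c("BD", "CL", "FL"), wavelengths = default_grid(),
                     ppm = 1, template = NULL, ...) {
  tpl <- template %||% oil_template(kind)
  idx <- make_oil_index(template = tpl, wavelengths = wavelengths)
  psd <- make_psd(template = tpl, total_ppm = ppm)
  polydisperse_iops(idx, psd, wavelengths, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
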