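#' Tidy a simulated reflectance result
#'
#' @param x An `rrs_result`.
#' @param ... Unused.
#' @return A long tibble with one row per wavelength and budget component.
#' @method tidy rrs_result
#' @export
tidy.rrs_result <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(dplyr::starts_with("budget_"),
                        names_to = "budget_component", values_to = "fraction") |>
    mutate(budget_component = sub("^budget_", "", .data$budget_component))
}

#' One-row summary of a simulated reflectance result
#'
#' @param x An `rrs_result`.
#' @param ... Unused.
#' @return A tibble with photon budget, wavelength coverage and noise level.
#' @method glance rrs_result
#' @export
glance.rrs_result <- function(x, ...) {
  tibble(
    n_wavelengths = nrow(x),
    n_photons = attr(x, "n_photons"),
    rrs_max = max(x$rrs),
    median_rel_stderr = stats::median(x$stderr / pmax(x$rrs, .Machine$double.eps)),
    budget_closure = max(abs(x$budget_absorbed + x$budget_bottom +
                               x$budget_water_leaving + x$budget_surface_lost - 1))
  )
}

#' Plot a simulated reflectance spectrum
#'
#' @param object An `rrs_result`.
#' @param ... Unused.
#' @return A ggplot object: R_rs vs wavelength with +/- 2 SE ribbon.
#' @method autoplot rrs_result
#' @export
autoplot.rrs_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$wavelength, y = .data$rrs)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rrs - 2 * .data$stderr,
                                      ymax = .data$rrs + 2 * .data$stderr),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength [nm]", y = expression(R[rs] ~ "[" * sr^-1 * "]")) +
    ggplot2::theme_minimal()
}

#' Plot the absorption and scattering budget of a water model
#'
#' @param object A `water_iops` object.
#' @param ... Unused.
#' @return A ggplot object with one panel per coefficient type.
#' @method autoplot water_iops
#' @export
autoplot.water_iops <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-"wavelength", names_to = "component",
                        values_to = "value") |>
    mutate(kind = ifelse(grepl("^a", .data$component), "absorption [1/m]",
                         "scattering [1/m]"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$wavelength, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "wavelength [nm]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phase function on a log scale
#'
#' @param object A `phase_function`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_function
#' @export
autoplot.phase_function <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$angle_deg, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "scattering angle [deg]",
                  y = expression(p(theta) ~ "[" * sr^-1 * "]")) +
    ggplot2::theme_minimal()
}

#' Tidy an experiment bundle
#'
#' @param x An `experiment_bundle`.
#' @param ... Unused.
#' @return The long spectra tibble.
#' @method tidy experiment_bundle
#' @export
tidy.experiment_bundle <- function(x, ...) x$spectra

#' One-row summary of an experiment bundle
#'
#' @param x An `experiment_bundle`.
#' @param ... Unused.
#' @return A tibble with the grid dimensions and directional-check pass rate.
#' @method glance experiment_bundle
#' @export
glance.experiment_bundle <- function(x, ...) {
  report <- summarize_directional_findings(x)
  tibble(
    n_cells = nrow(x$cells),
    n_water_types = length(unique(x$cells$chl)),
    n_oils = length(setdiff(unique(x$cells$oil), "none")),
    n_checks = nrow(report),
    n_checks_passed = sum(report$pass, na.rm = TRUE)
  )
}

#' Plot all spectra of an experiment bundle
#'
#' @param object An `experiment_bundle`.
#' @param ... Unused.
#' @return A ggplot object faceted by trophic type.
#' @method autoplot experiment_bundle
#' @export
autoplot.experiment_bundle <- function(object, ...) {
  ggplot2::ggplot(object$spectra,
                  ggplot2::aes(x = .data$wavelength, y = .data$rrs,
                               colour = .data$oil)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trophic, scales = "free_y") +
    ggplot2::labs(x = "wavelength [nm]", y = expression(R[rs] ~ "[" * sr^-1 * "]")) +
    ggplot2::theme_minimal()
}
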