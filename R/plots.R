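#' Plot an energy profile with its activity threshold
#'
#' @param object an [windowed_energy()] profile.
#' @param threshold_factor threshold to overlay, as a multiple of the mean
#'   window energy (the detector's default 1.6).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot energy_profile
#' @export
autoplot.energy_profile <- function(object, threshold_factor = 1.6, ...) {
  df <- tidy(object)
  thr <- threshold_factor * mean(object$energies)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$energy)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = thr, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "sample", y = "window energy",
                  title = sprintf("Windowed energy (threshold %.3g)", thr)) +
    ggplot2::theme_minimal()
}

#' Plot per-species level histograms
#'
#' Faceted histograms of the per-clip level distribution, one panel per
#' species, from a [summarize_levels()] result.
#'
#' @param levels a [summarize_levels()] result.
#' @return a ggplot.
#' @export
plot_level_histograms <- function(levels) {
  stopifnot(is.list(levels), !is.null(levels$histogram))
  ggplot2::ggplot(levels$histogram,
                  ggplot2::aes(x = .data$bin_left + (.data$bin_right -
                                                       .data$bin_left) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = NULL, fill = "steelblue") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "level [dB]", y = "clips") +
    ggplot2::theme_minimal()
}

#' Plot scenario spectra and their attenuation
#'
#' @param spectra named list of [scenario_spectrum()] tibbles.
#' @return a ggplot with one curve per scenario on a log frequency axis.
#' @export
plot_scenario_spectra <- function(spectra) {
  df <- dplyr::bind_rows(
    purrr::imap(spectra, function(sp, nm) {
      dplyr::mutate(sp, scenario = nm)
    })) |>
    dplyr::filter(.data$frequency_hz > 0)  # drop DC for the log axis
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_hz,
                                   y = .data$magnitude_db,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency [Hz]", y = "magnitude [dB]") +
    ggplot2::theme_minimal()
}
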