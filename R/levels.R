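#' Sound pressure level configuration
#'
#' The per-clip level statistic is computed after offset correction
#' (subtracting each channel's mean) and a 50 Hz, 4th-order Butterworth
#' high-pass filter. By default levels are referenced to digital full
#' scale (dBFS, reference amplitude 1); with a calibration factor in
#' pascal per full-scale unit, levels are absolute SPL re 20 micropascal.
#'
#' @param hp_cutoff_hz,hp_order high-pass applied before the level.
#' @param reference `"full_scale"` (dBFS) or `"pascal_calibrated"`.
#' @param calibration_pa_per_unit pascal per full-scale unit; required for
#'   `"pascal_calibrated"`.
#' @return a `level_config` list.
#' @export
level_config <- function(hp_cutoff_hz = 50, hp_order = 4L,
                         reference = c("full_scale", "pascal_calibrated"),
                         calibration_pa_per_unit = NULL) {
  reference <- match.arg(reference)
  if (reference == "pascal_calibrated" &&
      (is.null(calibration_pa_per_unit) || calibration_pa_per_unit <= 0)) {
    stop("pascal-calibrated levels need a positive calibration_pa_per_unit",
         call. = FALSE)
  }
  structure(list(hp_cutoff_hz = hp_cutoff_hz, hp_order = as.integer(hp_order),
                 reference = reference,
                 calibration_pa_per_unit = calibration_pa_per_unit),
            class = "level_config")
}

#' Mean sound pressure level of a clip
#'
#' Per channel: subtract the channel mean (offset correction), apply the
#' high-pass, and compute the mean square. The mean squares are pooled
#' (averaged) across channels and the level is
#' `10 * log10(pooled / ref^2)`, one dB value per clip. Pooling mean
#' squares rather than averaging per-channel dB values keeps the scaling
#' law exact: scaling all samples by `a` shifts the level by exactly
#' `20 * log10(a)`.
#'
#' @param x a [clip()] or [recording()].
#' @param cfg a [level_config()].
#' @return the level in dB (dBFS by default).
#' @examples
#' sine <- sin(2 * pi * 1000 * (0:39999) / 16000)
#' clip_spl(clip(cbind(sine, sine, sine, sine), 16000))  # ~ -3.01 dBFS
#' @export
clip_spl <- function(x, cfg = level_config()) {
  stopifnot(inherits(x, "insect_recording"), inherits(cfg, "level_config"))
  if (n_samples(x) == 0L) stop("zero-length clip", call. = FALSE)
  hp <- design_butterworth("high_pass", cfg$hp_order, cfg$hp_cutoff_hz,
                           x$rate)
  centered <- sweep(x$samples, 2L, colMeans(x$samples))
  filtered <- apply_filter(hp, centered)
  if (!is.matrix(filtered)) filtered <- matrix(filtered, ncol = 1)
  pooled_ms <- mean(colMeans(filtered^2))
  ref <- if (cfg$reference == "full_scale") 1 else
    20e-6 / cfg$calibration_pa_per_unit
  10 * log10(pooled_ms / ref^2)
}

#' Per-species level summaries and histograms
#'
#' Summarizes per-clip levels stored in a manifest: arithmetic mean level
#' and clip count per species, plus fixed-width histogram bins of the
#' level distribution per species.
#'
#' @param manifest a manifest tibble with `species` and `spl_db` columns
#'   (no missing levels among summarized rows).
#' @param bin_width histogram bin width in dB.
#' @param range optional `c(lo, hi)` dB range for the bins; defaults to
#'   the data range expanded to whole bins.
#' @return a list with `summary` (tibble: `species`, `n_clips`,
#'   `mean_spl_db`) and `histogram` (tibble: `species`, `bin_left`,
#'   `bin_right`, `count`).
#' @export
summarize_levels <- function(manifest, bin_width = 1, range = NULL) {
  stopifnot(is.data.frame(manifest))
  rows <- manifest[!is.na(manifest$spl_db), , drop = FALSE]
  if (nrow(rows) == 0L) stop("no rows with spl_db to summarize",
                             call. = FALSE)
  summary <- rows |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_clips = dplyr::n(),
                     mean_spl_db = mean(.data$spl_db), .groups = "drop")
  if (is.null(range)) {
    range <- c(bin_width * floor(min(rows$spl_db) / bin_width),
               bin_width * ceiling(max(rows$spl_db) / bin_width))
    if (range[2] <= range[1]) range[2] <- range[1] + bin_width
  }
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  histogram <- rows |>
    dplyr::group_by(.data$species) |>
    dplyr::reframe({
      counts <- graphics::hist(pmin(pmax(.data$spl_db, range[1]), range[2]),
                               breaks = breaks, plot = FALSE)$counts
      tibble::tibble(bin_left = breaks[-length(breaks)],
                     bin_right = breaks[-1], count = counts)
    })
  list(summary = summary, histogram = tibble::as_tibble(histogram))
}

#' Append per-clip levels to a manifest
#'
#' Reads every clip file listed in the manifest, computes its level with
#' [clip_spl()], and fills the `spl_db` column.
#'
#' @param manifest a manifest tibble with a `path` column.
#' @param cfg a [level_config()].
#' @return the manifest with `spl_db` filled in.
#' @export
add_levels <- function(manifest, cfg = level_config()) {
  stopifnot(is.data.frame(manifest))
  manifest$spl_db <- purrr::map_dbl(manifest$path, function(p) {
    clip_spl(read_wave(p), cfg)
  })
  manifest
}
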