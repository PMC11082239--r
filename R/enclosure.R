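#' Sweep scenarios for enclosure attenuation measurement
#'
#' The enclosure's noise absorption is characterized by playing a sine
#' sweep outside it and recording inside under different door
#' configurations (open, inner door closed, fully closed). Each scenario
#' collects equal-length multichannel sweep excerpts (nominally nine 21 s
#' clips of four channels); the scenario's averaged smoothed magnitude
#' spectrum is compared against the open-door reference to read off the
#' attenuation in dB.
#'
#' @param name scenario label, e.g. `"open"`, `"inner_closed"`,
#'   `"fully_closed"`.
#' @param segments list of numeric matrices (samples x channels), all of
#'   equal dimensions.
#' @param rate_hz sample rate of the segments.
#' @return a `sweep_scenario` object.
#' @export
sweep_scenario <- function(name, segments, rate_hz) {
  if (!is.list(segments) || length(segments) < 1L) {
    stop("a scenario needs at least one segment", call. = FALSE)
  }
  segments <- lapply(segments, function(s) {
    if (is.vector(s)) matrix(s, ncol = 1) else s
  })
  dims <- vapply(segments, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all segments must have equal length and channel count",
         call. = FALSE)
  }
  structure(list(name = name, segments = segments, rate_hz = rate_hz),
            class = "sweep_scenario")
}

#' @rdname sweep_scenario
#' @param rec a [recording()].
#' @param timestamps start times of the sweep excerpts in seconds.
#' @param seg_s excerpt length in seconds (default 21: a 20 s sweep plus
#'   2 s of silence, minus the second of slack used when noting stamps).
#' @return `extract_sweep_segments()`: list of sample matrices, each
#'   exactly `seg_s * rate` samples, all channels, bit-identical to the
#'   source slice.
#' @export
extract_sweep_segments <- function(rec, timestamps, seg_s = 21) {
  stopifnot(inherits(rec, "insect_recording"))
  seg_len <- round(seg_s * rec$rate)
  lapply(timestamps, function(t0) {
    start <- round(t0 * rec$rate)
    if (start < 0 || start + seg_len > n_samples(rec)) {
      stop(sprintf(
        "sweep segment [%.3f, %.3f) s lies outside the %.3f s recording",
        t0, t0 + seg_s, duration_s(rec)), call. = FALSE)
    }
    rec$samples[(start + 1L):(start + seg_len), , drop = FALSE]
  })
}

#' Averaged smoothed magnitude spectrum of a sweep scenario
#'
#' Computes the one-sided amplitude spectrum of every channel of every
#' segment, averages the magnitudes in the linear domain across all
#' segments and channels, converts to dB and applies centered
#' moving-average smoothing. Averaging linearly before the dB conversion
#' is the standard spectral estimator and makes constructed attenuation
#' steps recover exactly.
#'
#' @param scenario a [sweep_scenario()].
#' @param smooth_window moving-average window (odd; default 51).
#' @param eps dB floor passed to [magnitude_spectrum_db()].
#' @return tibble with `frequency_hz` and `magnitude_db` (smoothed).
#' @export
scenario_spectrum <- function(scenario, smooth_window = 51L, eps = 1e-12) {
  stopifnot(inherits(scenario, "sweep_scenario"))
  mags <- NULL
  n_spec <- 0L
  freq <- NULL
  for (seg in scenario$segments) {
    for (ch in seq_len(ncol(seg))) {
      sp <- magnitude_spectrum_db(seg[, ch], scenario$rate_hz, eps = eps)
      if (is.null(mags)) {
        mags <- sp$magnitude
        freq <- sp$frequency_hz
      } else {
        mags <- mags + sp$magnitude
      }
      n_spec <- n_spec + 1L
    }
  }
  avg <- mags / n_spec
  tibble::tibble(
    frequency_hz = freq,
    magnitude_db = moving_average(20 * log10(avg + eps), smooth_window)
  )
}

#' Attenuation between a reference and a test spectrum
#'
#' The attenuation achieved by the enclosure is read as the dB difference
#' between the reference (doors open) spectrum and the test (doors closed)
#' spectrum at every frequency, plus mean attenuation over summary bands.
#'
#' @param reference,test spectra as returned by [scenario_spectrum()]
#'   (identical frequency grids).
#' @param bands list of `c(f_lo, f_hi)` Hz pairs to summarize (default
#'   1-8 kHz).
#' @return a list with `spectrum` (tibble: `frequency_hz`,
#'   `attenuation_db`) and `bands` (tibble: `f_lo_hz`, `f_hi_hz`,
#'   `mean_attenuation_db`).
#' @export
attenuation_spectrum <- function(reference, test,
                                 bands = list(c(1000, 8000))) {
  stopifnot(is.data.frame(reference), is.data.frame(test))
  if (nrow(reference) != nrow(test) ||
      max(abs(reference$frequency_hz - test$frequency_hz)) > 1e-9) {
    stop("reference and test spectra must share one frequency grid",
         call. = FALSE)
  }
  diff_db <- reference$magnitude_db - test$magnitude_db
  spectrum <- tibble::tibble(frequency_hz = reference$frequency_hz,
                             attenuation_db = diff_db)
  band_rows <- purrr::map(bands, function(b) {
    sel <- spectrum$frequency_hz >= b[1] & spectrum$frequency_hz <= b[2]
    tibble::tibble(f_lo_hz = b[1], f_hi_hz = b[2],
                   mean_attenuation_db = mean(diff_db[sel]))
  })
  list(spectrum = spectrum, bands = dplyr::bind_rows(band_rows))
}

#' Noise-floor estimate of a measured spectrum
#'
#' In a closed-box sweep measurement the smooth stretches of the spectrum
#' show the measurement chain's noise floor rather than leaked signal.
#' This estimator reports the median dB level of the flattest decile of
#' the spectrum, where flatness is the smoothed absolute bin-to-bin
#' variation. The floor is reported, not corrected for.
#'
#' @param spectrum a [scenario_spectrum()] tibble.
#' @param roughness_window smoothing window for the local variation.
#' @return estimated noise floor in dB.
#' @export
spectrum_noise_floor <- function(spectrum, roughness_window = 51L) {
  stopifnot(is.data.frame(spectrum))
  db <- spectrum$magnitude_db
  if (length(db) < 20L) stop("spectrum too short", call. = FALSE)
  rough <- moving_average(c(abs(diff(db)), 0), roughness_window)
  flattest <- which(rough <= stats::quantile(rough, 0.1))
  stats::median(db[flattest])
}
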