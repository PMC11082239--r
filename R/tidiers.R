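#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an extraction report
#'
#' `tidy()` returns one row per emitted clip (its offset on the 16 kHz
#' timeline); `glance()` returns the one-row run summary.
#'
#' @param x an `extraction_report` from [extract_clips()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy extraction_report
#' @export
tidy.extraction_report <- function(x, ...) {
  tibble::tibble(
    source_id = x$source_id,
    clip = seq_along(x$clip_offsets),
    start_offset = x$clip_offsets
  )
}

#' @rdname tidy.extraction_report
#' @method glance extraction_report
#' @export
glance.extraction_report <- function(x, ...) {
  tibble::tibble(
    source_id = x$source_id,
    n_windows = x$n_windows,
    energy_threshold = x$energy_threshold,
    n_raw_intervals = x$n_raw_intervals,
    n_pruned_intervals = x$n_pruned_intervals,
    n_clips = x$n_clips
  )
}

#' @rdname tidy.extraction_report
#' @method tidy energy_profile
#' @export
tidy.energy_profile <- function(x, ...) {
  starts <- (seq_along(x$energies) - 1L) * x$hop
  tibble::tibble(
    window = seq_along(x$energies),
    start = starts,
    end = pmin(starts + x$window_len, x$n_samples),
    energy = x$energies
  )
}
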