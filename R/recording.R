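#' Multichannel recording and clip containers
#'
#' A recording holds multichannel audio as a numeric matrix with one column
#' per channel, together with its sample rate and provenance metadata
#' (recording date, species, source identifier). A clip is a fixed-length
#' excerpt of a recording on the post-resampling timeline; the dataset
#' convention is 2500 ms, 4 channels, 16 kHz, 32-bit float.
#'
#' @param samples numeric matrix (samples x channels) or a vector for a
#'   single channel; amplitudes in full-scale units, nominally in \[-1, 1\].
#' @param rate sample rate in Hz.
#' @param date recording date (`Date` or ISO "YYYY-MM-DD" string).
#' @param species scientific species name ("" when unlabeled).
#' @param source_id identifier of the originating file or scene.
#' @return `recording()` returns an object of class `insect_recording`;
#'   `clip()` returns an `insect_clip`, which is also an `insect_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(8000), ncol = 2), rate = 16000,
#'                  date = "2022-06-14", species = "Bombus terrestris")
#' n_samples(rec)
#' @export
recording <- function(samples, rate, date = NA, species = "",
                      source_id = "") {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (samples x channels)",
         call. = FALSE)
  }
  if (ncol(samples) < 1L || nrow(samples) < 1L) {
    stop("recording must have at least one channel and one sample",
         call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("recording amplitudes must be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = unname(samples), rate = as.numeric(rate),
         date = as_iso_date(date), species = as.character(species),
         source_id = as.character(source_id)),
    class = "insect_recording"
  )
}

#' @rdname recording
#' @param start_offset 0-based sample index of the clip start within its
#'   parent recording (post-resampling timeline).
#' @param index running integer of the clip within an extraction run.
#' @export
clip <- function(samples, rate, start_offset = 0L, date = NA, species = "",
                 index = 0L, source_id = "") {
  rec <- recording(samples, rate, date = date, species = species,
                   source_id = source_id)
  rec$start_offset <- as.integer(start_offset)
  rec$index <- as.integer(index)
  class(rec) <- c("insect_clip", class(rec))
  rec
}

#' @rdname recording
#' @param x an `insect_recording` or `insect_clip`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname recording
#' @export
n_channels <- function(x) ncol(x$samples)

#' @rdname recording
#' @export
duration_s <- function(x) nrow(x$samples) / x$rate

#' @export
print.insect_recording <- function(x, ...) {
  kind <- if (inherits(x, "insect_clip")) "<insect_clip>" else
    "<insect_recording>"
  cat(sprintf("%s %d channel(s), %d samples @ %g Hz (%.3f s)\n",
              kind, n_channels(x), n_samples(x), x$rate, duration_s(x)))
  if (!is.na(x$date)) cat("  date:    ", format(x$date), "\n", sep = "")
  if (nzchar(x$species)) cat("  species: ", x$species, "\n", sep = "")
  if (!is.null(x$start_offset)) {
    cat(sprintf("  offset:   %d samples (index %d)\n",
                x$start_offset, x$index))
  }
  invisible(x)
}

# Parse a date-ish input to Date, NA allowed.
as_iso_date <- function(date) {
  if (length(date) != 1L || (is.na(date) && !is.character(date))) {
    if (length(date) == 1L && is.na(date)) return(as.Date(NA))
  }
  if (inherits(date, "Date")) return(date)
  if (is.na(date)) return(as.Date(NA))
  out <- tryCatch(as.Date(as.character(date), format = "%Y-%m-%d"),
                  error = function(e) as.Date(NA))
  if (is.na(out)) {
    stop("`date` must be an ISO date (YYYY-MM-DD), got: ", date,
         call. = FALSE)
  }
  out
}

# Internal validator for clips destined for disk: equal-length channels is
# structural (matrix), but the length/rate contract is checked here.
validate_clip <- function(x, clip_ms = NULL) {
  stopifnot(inherits(x, "insect_recording"))
  if (!all(is.finite(x$samples))) {
    stop("clip contains non-finite samples", call. = FALSE)
  }
  if (!is.null(clip_ms)) {
    expect_len <- round(clip_ms / 1000 * x$rate)
    if (nrow(x$samples) != expect_len) {
      stop(sprintf("clip length %d != round(%g ms x %g Hz) = %d samples",
                   nrow(x$samples), clip_ms, x$rate, expect_len),
           call. = FALSE)
    }
  }
  invisible(x)
}
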