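#' Extraction pipeline parameters
#'
#' Bundles every tunable of the clip-extraction program with the defaults
#' of the dataset's production run: downsampling to 16 kHz; prefiltering of
#' the loudest channel with a 4th-order 1500 Hz Butterworth low-pass and a
#' 30th-order 180 Hz Butterworth high-pass; signal energy over
#' 3279-sample windows hopped by 1024 samples; an activity threshold of
#' 1.6 times the mean window energy of the whole file; 2500 ms clips; and
#' the noise-pruning rule that drops active segments shorter than 1 s with
#' no neighboring activity within 2500 ms.
#'
#' @param target_rate_hz working sample rate after downsampling (Hz).
#' @param lp_cutoff_hz,lp_order prefilter low-pass cutoff (Hz) and order.
#' @param hp_cutoff_hz,hp_order prefilter high-pass cutoff (Hz) and order.
#' @param window_len,hop energy window length and hop (samples at
#'   `target_rate_hz`).
#' @param threshold_factor activity threshold as a multiple of the mean
#'   window energy.
#' @param clip_ms emitted clip length (ms).
#' @param min_isolated_ms,neighbor_range_ms pruning rule: an active segment
#'   shorter than `min_isolated_ms` is discarded as noise unless another
#'   active segment lies within `neighbor_range_ms` before or after it.
#' @return a `pipeline_params` list.
#' @export
pipeline_params <- function(target_rate_hz = 16000,
                            lp_cutoff_hz = 1500, lp_order = 4L,
                            hp_cutoff_hz = 180, hp_order = 30L,
                            window_len = 3279L, hop = 1024L,
                            threshold_factor = 1.6,
                            clip_ms = 2500,
                            min_isolated_ms = 1000,
                            neighbor_range_ms = 2500) {
  p <- list(target_rate_hz = target_rate_hz,
            lp_cutoff_hz = lp_cutoff_hz, lp_order = as.integer(lp_order),
            hp_cutoff_hz = hp_cutoff_hz, hp_order = as.integer(hp_order),
            window_len = as.integer(window_len), hop = as.integer(hop),
            threshold_factor = threshold_factor,
            clip_ms = clip_ms,
            min_isolated_ms = min_isolated_ms,
            neighbor_range_ms = neighbor_range_ms)
  if (any(vapply(p, function(v) !is.finite(v) || v <= 0, logical(1)))) {
    stop("all pipeline parameters must be positive and finite",
         call. = FALSE)
  }
  if (p$clip_ms < p$min_isolated_ms) {
    stop("clip_ms must be >= min_isolated_ms", call. = FALSE)
  }
  structure(p, class = "pipeline_params")
}

#' Select the loudest channel of a recording
#'
#' Returns the index of the channel with the largest total squared signal
#' sum; ties go to the lowest index. Reducing detection to a single channel
#' is what makes the downstream filtering and energy scan cheap.
#'
#' @param rec a [recording()].
#' @return 1-based channel index.
#' @export
select_loudest_channel <- function(rec) {
  stopifnot(inherits(rec, "insect_recording"))
  if (n_samples(rec) == 0L) stop("empty recording", call. = FALSE)
  sums <- colSums(rec$samples^2)
  which.max(sums)  # which.max returns the first (lowest-index) maximum
}

#' Threshold an energy profile into activity intervals
#'
#' Windows whose energy strictly exceeds `threshold_factor` times the mean
#' window energy of the profile are active. Each active window is mapped
#' back to its sample range and overlapping or abutting ranges are merged
#' into activity intervals. With the default hop (1024) smaller than the
#' window (3279), adjacent active windows always merge. A constant-energy
#' profile can never exceed 1.6 times its own mean, so it yields no
#' activity — the threshold is relative by design.
#'
#' @param profile an [windowed_energy()] profile.
#' @param threshold_factor multiple of the mean window energy.
#' @return a list with `threshold` (absolute energy) and `intervals`, a
#'   tibble of half-open 0-based sample ranges (`start`, `end`).
#' @export
detect_activity <- function(profile, threshold_factor = 1.6) {
  stopifnot(inherits(profile, "energy_profile"))
  if (length(profile$energies) == 0L) {
    stop("empty energy profile", call. = FALSE)
  }
  threshold <- threshold_factor * mean(profile$energies)
  active <- which(profile$energies > threshold)
  starts <- (active - 1L) * profile$hop
  ends <- pmin(starts + profile$window_len, profile$n_samples)
  list(threshold = threshold,
       intervals = merge_intervals(starts, ends))
}

# Merge overlapping or abutting half-open intervals; inputs sorted by start.
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  tibble::tibble(start = as.integer(c(out_s, ms)),
                 end = as.integer(c(out_e, me)))
}

#' Discard short isolated activity intervals as noise
#'
#' An interval is removed if and only if it is shorter than
#' `min_isolated_ms` *and* the silent gap to both its predecessor and its
#' successor exceeds `neighbor_range_ms` (a missing neighbor counts as an
#' infinite gap). Short bursts embedded in a cluster of activity are kept;
#' lone blips are treated as noise.
#'
#' @param intervals tibble of sorted, non-overlapping `start`/`end` sample
#'   ranges.
#' @param min_isolated_ms,neighbor_range_ms rule parameters (ms).
#' @param rate_hz sample rate of the interval timeline.
#' @return the pruned intervals tibble.
#' @export
prune_isolated <- function(intervals, min_isolated_ms = 1000,
                           neighbor_range_ms = 2500, rate_hz = 16000) {
  check_intervals(intervals)
  n <- nrow(intervals)
  if (n == 0L) return(intervals)
  min_len <- min_isolated_ms / 1000 * rate_hz
  range_s <- neighbor_range_ms / 1000 * rate_hz
  dur <- intervals$end - intervals$start
  gap_prev <- c(Inf, intervals$start[-1] - intervals$end[-n])
  gap_next <- c(intervals$start[-1] - intervals$end[-n], Inf)
  drop <- dur < min_len & gap_prev > range_s & gap_next > range_s
  intervals[!drop, , drop = FALSE]
}

check_intervals <- function(intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) return(invisible(intervals))
  if (any(intervals$end <= intervals$start)) {
    stop("intervals must satisfy start < end", call. = FALSE)
  }
  if (is.unsorted(intervals$start, strictly = TRUE) ||
      any(intervals$start[-1] < intervals$end[-nrow(intervals)])) {
    stop("intervals must be sorted and non-overlapping", call. = FALSE)
  }
  invisible(intervals)
}

#' Place non-overlapping fixed-length clip windows over activity
#'
#' Greedy left-to-right placement: open a clip window at the start of the
#' first interval not yet covered (shifted left if it would overrun the
#' end of the file); every interval fully covered by that window is
#' consumed; an interval extending past the window's end makes the next
#' clip start exactly at that window's end (back-to-back coverage of long
#' activity); otherwise the next window opens at the next uncovered
#' interval's start. The result is deterministic, windows never overlap,
#' and every interval is overlapped by at least one window whenever the
#' file is long enough to allow it.
#'
#' @param intervals pruned, sorted, non-overlapping activity intervals
#'   (0-based sample ranges).
#' @param clip_len_samples clip window length in samples.
#' @param n_total_samples total length of the signal in samples.
#' @return integer vector of 0-based clip start offsets.
#' @export
segment_clips <- function(intervals, clip_len_samples, n_total_samples) {
  check_intervals(intervals)
  clip_len <- as.integer(clip_len_samples)
  n_total <- as.integer(n_total_samples)
  if (nrow(intervals) == 0L) return(integer(0))
  if (any(intervals$end > n_total) || any(intervals$start < 0)) {
    stop("intervals must lie within [0, n_total)", call. = FALSE)
  }
  if (n_total < clip_len) {
    warning("signal (", n_total, " samples) shorter than one clip (",
            clip_len, "); no clips emitted")
    return(integer(0))
  }
  offsets <- integer(0)
  covered_end <- 0L  # end of the last placed window (0 = nothing placed)
  k <- 1L
  n <- nrow(intervals)
  while (k <= n) {
    if (intervals$end[k] <= covered_end && length(offsets) > 0L) {
      k <- k + 1L
      next
    }
    win_start <- if (length(offsets) > 0L &&
                     intervals$start[k] < covered_end) {
      covered_end                      # long interval: continue back-to-back
    } else {
      intervals$start[k]
    }
    win_start <- min(win_start, n_total - clip_len)  # keep inside the file
    if (length(offsets) > 0L && win_start < covered_end) {
      warning("activity near the end of the file could not be covered ",
              "without overlapping clips; ", n - k + 1L,
              " interval(s) left uncovered")
      break
    }
    offsets <- c(offsets, as.integer(win_start))
    covered_end <- as.integer(win_start) + clip_len
  }
  offsets
}

#' Run the full clip-extraction program on one recording
#'
#' The eight processing steps: (1) take the loaded multichannel recording;
#' (2) downsample every channel to the working rate; (3) select the
#' loudest channel by total squared signal sum; (4) prefilter that channel
#' (low-pass, then high-pass); (5) compute windowed signal energies;
#' (6) threshold them at `threshold_factor` times their mean and merge the
#' active windows into activity intervals; (7) prune short isolated
#' intervals and place non-overlapping fixed-length clip windows over the
#' remaining activity; (8) cut the clips from the *original, unfiltered,
#' resampled multichannel* signal. Filtering only ever affects detection,
#' never the emitted audio.
#'
#' @param rec a [recording()].
#' @param params a [pipeline_params()] bundle.
#' @param index_start running index given to the first emitted clip.
#' @return a list with `clips` (list of [clip()] objects) and `report`
#'   (an `extraction_report`).
#' @export
extract_clips <- function(rec, params = pipeline_params(),
                          index_start = 0L) {
  stopifnot(inherits(rec, "insect_recording"),
            inherits(params, "pipeline_params"))
  rec16 <- resample_recording(rec, params$target_rate_hz)
  clip_len <- as.integer(round(params$clip_ms / 1000 * params$target_rate_hz))

  empty_report <- function(thr = NA_real_, n_win = 0L, n_raw = 0L,
                           n_kept = 0L) {
    new_extraction_report(rec$source_id, n_win, thr, n_raw, n_kept,
                          integer(0))
  }
  if (n_samples(rec16) < clip_len) {
    warning("recording shorter than one clip after resampling; no clips")
    return(list(clips = list(), report = empty_report()))
  }

  ch <- select_loudest_channel(rec16)
  lp <- design_butterworth("low_pass", params$lp_order, params$lp_cutoff_hz,
                           params$target_rate_hz)
  hp <- design_butterworth("high_pass", params$hp_order, params$hp_cutoff_hz,
                           params$target_rate_hz)
  filtered <- apply_filter(hp, apply_filter(lp, rec16$samples[, ch]))

  profile <- windowed_energy(filtered, params$window_len, params$hop)
  det <- detect_activity(profile, params$threshold_factor)
  pruned <- prune_isolated(det$intervals, params$min_isolated_ms,
                           params$neighbor_range_ms, params$target_rate_hz)
  offsets <- segment_clips(pruned, clip_len, n_samples(rec16))

  clips <- purrr::imap(as.list(offsets), function(off, i) {
    clip(rec16$samples[(off + 1L):(off + clip_len), , drop = FALSE],
         rate = params$target_rate_hz, start_offset = off,
         date = rec16$date, species = rec16$species,
         index = index_start + i - 1L, source_id = rec16$source_id)
  })
  report <- new_extraction_report(
    rec$source_id, length(profile$energies), det$threshold,
    nrow(det$intervals), nrow(pruned), offsets)
  list(clips = clips, report = report)
}

new_extraction_report <- function(source_id, n_windows, threshold,
                                  n_raw, n_pruned, offsets) {
  structure(
    list(source_id = source_id, n_windows = as.integer(n_windows),
         energy_threshold = threshold,
         n_raw_intervals = as.integer(n_raw),
         n_pruned_intervals = as.integer(n_pruned),
         clip_offsets = as.integer(offsets),
         n_clips = length(offsets)),
    class = "extraction_report")
}

#' @export
print.extraction_report <- function(x, ...) {
  cat("<extraction_report> ", x$source_id, "\n", sep = "")
  cat(sprintf("  %d windows, threshold %.4g\n", x$n_windows,
              x$energy_threshold))
  cat(sprintf("  %d raw -> %d pruned activity intervals -> %d clips\n",
              x$n_raw_intervals, x$n_pruned_intervals, x$n_clips))
  invisible(x)
}
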