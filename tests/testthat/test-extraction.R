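test_that("loudest-channel selection is argmax of squared sums", {
  rec <- recording(cbind(numeric(1000),
                         sin(2 * pi * 100 * (0:999) / 16000)), 16000)
  expect_identical(select_loudest_channel(rec), 2L)
  same <- recording(matrix(0.1, 500, 3), 16000)
  expect_identical(select_loudest_channel(same), 1L)  # tie -> lowest index
  rec4 <- random_recording(n = 20000, channels = 4, seed = 11)
  expect_identical(select_loudest_channel(rec4),
                   unname(which.max(colSums(rec4$samples^2))))
})

test_that("activity thresholding follows the 1.6x-mean rule", {
  prof <- manual_profile(c(1, 1, 1, 1, 6))
  det <- detect_activity(prof, 1.6)
  expect_equal(det$threshold, 3.2)
  expect_equal(nrow(det$intervals), 1)
  expect_equal(det$intervals$start, 4L * 1024L)
  expect_equal(det$intervals$end, 4L * 1024L + 3279L)

  # constant energies can never exceed 1.6x their own mean
  flat <- detect_activity(manual_profile(rep(7, 50)), 1.6)
  expect_equal(nrow(flat$intervals), 0)

  # adjacent active windows merge into one interval of window + hop
  merged <- detect_activity(manual_profile(c(1, 9, 9, 1, 1, 1, 1, 1)), 1.6)
  expect_equal(nrow(merged$intervals), 1)
  expect_equal(merged$intervals$end - merged$intervals$start, 3279L + 1024L)
})

test_that("raising the threshold factor never adds active windows", {
  prof <- windowed_energy(
    withr::with_seed(12, stats::rnorm(80000) *
                       (1 + 5 * (sin(2 * pi * (1:80000) / 30000) > 0.9))),
    3279, 1024)
  active_set <- function(tf) {
    which(prof$energies > tf * mean(prof$energies))
  }
  factors <- c(0.5, 1, 1.3, 1.6, 2, 3, 5)
  for (i in seq_along(factors)[-1]) {
    expect_true(all(active_set(factors[i]) %in% active_set(factors[i - 1])))
  }
})

test_that("the pruning rule drops lone short blips and keeps the rest", {
  rate <- 16000
  # 500 ms interval with nothing around it -> noise, removed
  lone <- iv(16000, 16000 + 8000)
  expect_equal(nrow(prune_isolated(lone, rate_hz = rate)), 0)
  # 1200 ms interval -> long enough on its own, kept
  long <- iv(16000, 16000 + 19200)
  expect_equal(nrow(prune_isolated(long, rate_hz = rate)), 1)
  # two 500 ms intervals 1000 ms apart -> each has a neighbor, both kept
  pair <- iv(0, 8000, 24000, 32000)
  expect_equal(nrow(prune_isolated(pair, rate_hz = rate)), 2)
  # rejects disordered input
  expect_error(prune_isolated(iv(100, 200, 50, 80), rate_hz = rate),
               "sorted")
})

test_that("greedy segmentation traces match the hand-worked cases", {
  rate <- 16000; clip_len <- 40000L
  # one 1200 ms interval at 10 s in a 60 s file -> one clip at 10 s
  off <- segment_clips(iv(160000, 160000 + 19200), clip_len, 60 * rate)
  expect_identical(off, 160000L)
  # two 500 ms intervals at 10.0 and 11.5 s -> one clip covers both
  off2 <- segment_clips(iv(160000, 168000, 184000, 192000), clip_len,
                        60 * rate)
  expect_identical(off2, 160000L)
  # one 4 s interval -> two back-to-back clips
  off3 <- segment_clips(iv(160000, 160000 + 64000), clip_len, 60 * rate)
  expect_identical(off3, c(160000L, 200000L))
  # interval near the file end -> clip shifted left to fit
  off4 <- segment_clips(iv(950000, 959000), clip_len, 60 * rate)
  expect_identical(off4, 60L * 16000L - 40000L)
  # file shorter than one clip -> no clips, with a warning
  expect_warning(
    none <- segment_clips(iv(100, 1600), clip_len, 20000),
    "shorter")
  expect_length(none, 0)
})

test_that("segmentation output always covers activity without overlap", {
  rate <- 16000; clip_len <- 40000L; n_total <- 120L * rate
  withr::with_seed(13, {
    for (rep in 1:20) {
      k <- sample(1:8, 1)
      starts <- sort(sample(seq(0, n_total - 50000, by = 400), k))
      ends <- pmin(starts + sample(c(2000, 8000, 20000, 70000), k,
                                   replace = TRUE), n_total)
      sel <- 1L
      for (i in seq_len(k)[-1]) {
        if (starts[i] > ends[sel[length(sel)]]) sel <- c(sel, i)
      }
      ivs <- tibble::tibble(start = as.integer(starts[sel]),
                            end = as.integer(ends[sel]))
      # the file-end warn path (activity not fully consumable without
      # overlap) is a documented outcome for random layouts
      offs <- suppressWarnings(segment_clips(ivs, clip_len, n_total))
      if (length(offs) > 1) expect_true(all(diff(offs) >= clip_len))
      expect_true(all(offs >= 0 & offs + clip_len <= n_total))
      # every interval overlapped by >= 1 window; every window by >= 1 interval
      for (i in seq_len(nrow(ivs))) {
        expect_true(any(offs < ivs$end[i] & offs + clip_len > ivs$start[i]))
      }
      for (o in offs) {
        expect_true(any(ivs$start < o + clip_len & ivs$end > o))
      }
    }
  })
})

test_that("a constant recording yields zero clips at any level", {
  for (level in c(1e-4, 0.5)) {
    rec <- recording(matrix(level, 16000 * 45, 2), 16000,
                     date = "2022-06-14", species = "Bombus terrestris")
    res <- extract_clips(rec)
    expect_equal(res$report$n_clips, 0)
    expect_length(res$clips, 0)
  }
})

test_that("extraction recovers synthetic events and cuts unfiltered audio", {
  fx <- make_extraction_fixture(3, snr_db = 20, seed = 21, duration_s = 60)
  res <- extract_clips(fx$recording)
  expect_equal(res$report$n_clips, length(res$clips))

  offs <- res$report$clip_offsets
  clip_len <- 40000L
  if (length(offs) > 1) expect_true(all(diff(offs) >= clip_len))

  # every ground-truth midpoint falls inside some clip
  mid16 <- (fx$ground_truth$t_start_s + fx$ground_truth$duration_s / 2) *
    16000
  expect_true(all(vapply(mid16, function(m) {
    any(m >= offs & m < offs + clip_len)
  }, logical(1))))

  # clips are bit-identical to the resampled *unfiltered* multichannel audio
  rec16 <- resample_recording(fx$recording)
  for (cl in res$clips) {
    o <- cl$start_offset
    expect_identical(cl$samples, rec16$samples[(o + 1):(o + clip_len), ])
    expect_equal(n_channels(cl), 4)
    expect_equal(n_samples(cl), clip_len)
    expect_equal(cl$rate, 16000)
  }

  # determinism: identical input and params -> identical output
  res2 <- extract_clips(fx$recording)
  expect_identical(res2$report$clip_offsets, res$report$clip_offsets)
  expect_identical(res2$clips[[1]]$samples, res$clips[[1]]$samples)

  # report bookkeeping
  g <- glance(res$report)
  expect_equal(g$n_clips, res$report$n_clips)
  expect_equal(nrow(tidy(res$report)), res$report$n_clips)
})

test_that("too-short recordings yield zero clips with a warning", {
  rec <- recording(matrix(stats::rnorm(16000), ncol = 1), 16000)
  expect_warning(res <- extract_clips(rec), "shorter")
  expect_equal(res$report$n_clips, 0)
})
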