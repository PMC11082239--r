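test_that("a single-harmonic event is a pure sine of the right RMS", {
  spec <- event_spec(0, 2, 100, n_harmonics = 1L, amplitude = 0.2,
                     envelope = "rectangular")
  x <- withr::with_seed(1, render_event(spec, 16000))
  expect_length(x, 32000)
  expect_equal(sqrt(mean(x^2)), 0.2 / sqrt(2), tolerance = 1e-3)
  sp <- magnitude_spectrum_db(x, 16000)
  expect_equal(sp$frequency_hz[which.max(sp$magnitude)], 100,
               tolerance = 1)
})

test_that("harmonic stacks peak at multiples of the wingbeat fundamental", {
  spec <- event_spec(0, 2, 77, n_harmonics = 8L, amplitude = 0.1,
                     envelope = "rectangular")
  x <- withr::with_seed(2, render_event(spec, 48000))
  sp <- magnitude_spectrum_db(x, 48000)
  for (k in 1:8) {
    near <- abs(sp$frequency_hz - k * 77) < 2
    far <- sp$frequency_hz > (k - 0.5) * 77 & sp$frequency_hz <
      (k + 0.5) * 77 & abs(sp$frequency_hz - k * 77) > 10
    expect_gt(max(sp$magnitude[near]), 10 * max(sp$magnitude[far]))
  }
  expect_error(render_event(event_spec(0, 1, 1200), 2000), "Nyquist")
  expect_error(event_spec(0, 1, 10), "plausible")
})

test_that("scene rendering is bit-deterministic under a fixed seed", {
  sc <- scene_spec(5, 48000,
                   list(event_spec(1, 1.5, 120, amplitude = 0.01)),
                   seed = 5L)
  a <- render_scene(sc)
  b <- render_scene(sc)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("propagation respects symmetry and the 1/r level law", {
  arr <- star_array()
  # the center mic is at the origin; outer mics 1 and 2 are symmetric
  # about the y axis? Use a position equidistant from outer2 and outer3.
  pos_eq <- c(0, 0, 0.25)           # on the array axis: equidistant from all
  sc <- scene_spec(4, 48000,
                   list(event_spec(1, 1.5, 150, amplitude = 0.02,
                                   position_m = pos_eq)),
                   noise_floor_db = -200, seed = 6L)
  out <- render_scene(sc)
  s <- out$recording$samples
  gt <- out$ground_truth
  seg <- s[(gt$start[1] + 1):gt$end[1], ]
  # outer channels are equidistant -> identical arrival: peak x-corr at lag 0
  best_lag <- function(a, b) {
    lags <- -10:10
    v <- vapply(lags, function(k) {
      n <- length(a)
      sum(a[100:(n - 100)] * b[100:(n - 100) + k])
    }, numeric(1))
    lags[which.max(v)]
  }
  expect_identical(best_lag(seg[, 2], seg[, 3]), 0L)
  expect_identical(best_lag(seg[, 2], seg[, 4]), 0L)

  # doubling the distance drops the level by 6.02 dB on the center channel
  lvl <- function(dist) {
    sc <- scene_spec(4, 48000,
                     list(event_spec(1, 1.5, 150, amplitude = 0.02,
                                     position_m = c(0, 0, dist))),
                     noise_floor_db = -200, seed = 7L)
    out <- render_scene(sc)
    seg <- out$recording$samples[(out$ground_truth$start[1] + 1):
                                   out$ground_truth$end[1], 1]
    10 * log10(mean(seg^2))
  }
  expect_equal(lvl(0.1) - lvl(0.2), 20 * log10(2), tolerance = 0.1)
})

test_that("inter-channel delays match the array geometry within a sample", {
  arr <- star_array()
  pos <- c(0.08, -0.03, 0.25)
  sc <- scene_spec(4, 48000,
                   list(event_spec(1, 1.5, 140, amplitude = 0.02,
                                   position_m = pos)),
                   noise_floor_db = -200, seed = 8L)
  out <- render_scene(sc)
  gt <- out$ground_truth
  seg <- out$recording$samples[(gt$start[1] + 1):gt$end[1], ]
  d <- sqrt(colSums((t(arr$positions) - pos)^2))
  expected <- (d - d[1]) / 343 * 48000
  lags <- -10:10
  for (ch in 2:4) {
    v <- vapply(lags, function(k) {
      n <- nrow(seg)
      sum(seg[100:(n - 100), 1] * seg[100:(n - 100) + k, ch])
    }, numeric(1))
    measured <- lags[which.max(v)]   # b delayed by tau peaks at k = tau
    expect_lt(abs(measured - expected[ch]), 1)
  }
})

test_that("events are reported, ground truth is bookkept, clipping warns", {
  sc <- scene_spec(10, 48000, purrr::map(1:5, function(i) {
    event_spec(2 * i - 1.5, 1.2, 100 + 10 * i, amplitude = 0.005)
  }), seed = 9L)
  out <- render_scene(sc)
  expect_equal(nrow(out$ground_truth), 5)
  expect_equal(out$ground_truth$start,
               as.integer(round((2 * (1:5) - 1.5) * 48000)))
  expect_error(scene_spec(10, 48000, list(event_spec(9.5, 1, 100))),
               "fit inside")
  loud <- scene_spec(4, 48000,
                     list(event_spec(1, 1.5, 150, amplitude = 10,
                                     position_m = c(0, 0, 0.05))),
                     seed = 10L)
  expect_warning(render_scene(loud), "full scale")
})

test_that("fixtures hit the requested in-band SNR within 1 dB", {
  fx <- make_extraction_fixture(3, snr_db = 20, seed = 23, duration_s = 60)
  sig <- fx$recording$samples[, 1]
  gt <- fx$ground_truth
  noise_ref <- sig[1:(2 * 48000)]          # margin region: noise only
  nb <- insectclip:::band_rms(noise_ref, 48000, c(180, 1500))
  for (i in seq_len(nrow(gt))) {
    seg <- sig[(gt$start[i] + 1):gt$end[i]]
    snr <- 20 * log10(insectclip:::band_rms(seg, 48000, c(180, 1500)) / nb)
    expect_equal(snr, 20, tolerance = 1)
  }
  # same seed twice -> bit-identical
  fx2 <- make_extraction_fixture(3, snr_db = 20, seed = 23, duration_s = 60)
  expect_identical(fx2$recording$samples, fx$recording$samples)
  expect_error(make_extraction_fixture(50, duration_s = 60), "pack")
})

test_that("a pure-noise fixture produces no clips", {
  fx <- make_extraction_fixture(0, seed = 24, duration_s = 45)
  expect_equal(nrow(fx$ground_truth), 0)
  res <- extract_clips(fx$recording)
  expect_equal(res$report$n_clips, 0)
})
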