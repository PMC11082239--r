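test_that("Butterworth designs hit -3.01 dB at the cutoff", {
  cases <- expand.grid(kind = c("low_pass", "high_pass"),
                       order = c(2L, 4L, 30L),
                       cutoff = c(180, 1500),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    spec <- design_butterworth(cases$kind[i], cases$order[i],
                               cases$cutoff[i], 16000)
    expect_equal(filter_gain_db(spec, cases$cutoff[i]), -3.0103,
                 tolerance = 0.1 / 3, ignore_attr = TRUE)
  }
})

test_that("the order-30 high-pass crushes 50 Hz and stays stable", {
  hp <- design_butterworth("high_pass", 30, 180, 16000)
  # analog closed form: 10*log10(1/(1+(180/50)^60)) ~ -334 dB; the digital
  # design must at least reach a -100 dB bound there
  expect_lt(filter_gain_db(hp, 50), -100)
  expect_true(all(Mod(filter_poles(hp)) < 1))
  # passband essentially unity
  expect_equal(filter_gain_db(hp, 1000), 0, tolerance = 0.01)
})

test_that("low-order design matches the signal package's butter()", {
  lp <- design_butterworth("low_pass", 4, 1500, 16000)
  bt <- signal::butter(4, 1500 / 8000)
  x <- withr::with_seed(1, stats::rnorm(5000))
  expect_equal(apply_filter(lp, x),
               as.numeric(signal::filter(bt, x)), tolerance = 1e-10)
})

test_that("filtering is causal, linear and length-preserving", {
  hp <- design_butterworth("high_pass", 30, 180, 16000)
  expect_identical(apply_filter(hp, numeric(100)), numeric(100))
  x <- withr::with_seed(2, stats::rnorm(3000))
  y <- apply_filter(hp, x)
  expect_length(y, 3000)
  expect_equal(apply_filter(hp, 2.5 * x), 2.5 * y, tolerance = 1e-12)
  # time invariance: shifted input -> shifted output (causal interior)
  shift <- 100L
  y_shift <- apply_filter(hp, c(numeric(shift), x))
  expect_equal(y_shift[(shift + 1):(shift + 2000)], y[1:2000],
               tolerance = 1e-12)
  expect_error(apply_filter(hp, x, rate_hz = 48000), "match")
})

test_that("a 1 kHz tone passes the detection prefilter at unit gain", {
  hp <- design_butterworth("high_pass", 30, 180, 16000)
  x <- sin(2 * pi * 1000 * (0:15999) / 16000)
  y <- apply_filter(hp, x)
  steady <- y[4000:16000]
  expect_equal(sqrt(2 * mean(steady^2)), 1, tolerance = 0.01)
})

test_that("windowed energy matches its closed form and counts windows", {
  a <- 0.3
  prof <- windowed_energy(rep(a, 3279), 3279, 1024)
  expect_equal(prof$energies, 3279 * a^2)
  prof2 <- windowed_energy(numeric(3279 + 1024), 3279, 1024)
  expect_length(prof2$energies, 2)
  expect_error(windowed_energy(numeric(3278), 3279, 1024), "shorter")
})

test_that("windowed energy equals the brute-force double loop", {
  x <- withr::with_seed(3, stats::rnorm(50000))
  prof <- windowed_energy(x, 3279, 1024)
  n_win <- (50000 - 3279) %/% 1024 + 1
  brute <- vapply(seq_len(n_win), function(k) {
    s <- 0
    for (i in ((k - 1) * 1024 + 1):((k - 1) * 1024 + 3279)) s <- s + x[i]^2
    s
  }, numeric(1))
  expect_equal(prof$energies, brute, tolerance = 1e-10)
})

test_that("moving average: identity, constants, impulse plateau, edges", {
  expect_equal(moving_average(1:10, 1), as.numeric(1:10))
  expect_equal(moving_average(rep(2.5, 200), 51), rep(2.5, 200))
  x <- numeric(301); x[151] <- 1
  y <- moving_average(x, 51)
  # direct convolution oracle for the interior
  expect_equal(y[126:176], rep(1 / 51, 51))
  expect_equal(sum(y[c(1:100, 200:301)]), 0)
  expect_error(moving_average(1:10, 50), "odd")
  expect_error(moving_average(1:10, -3), "odd")
  # edges shrink symmetrically: first element is its own window
  z <- moving_average(c(10, 0, 0, 0, 0), 5)
  expect_equal(z[1], 10)            # window {x1}
  expect_equal(z[2], 10 / 3)        # window {x1,x2,x3}
  expect_equal(z[3], 2)             # full window
})

test_that("moving average preserves the mean of a stationary sequence", {
  x <- withr::with_seed(4, stats::rnorm(20000, mean = 3))
  expect_equal(mean(moving_average(x, 51)), mean(x), tolerance = 1e-3)
})

test_that("magnitude spectrum peaks at the tone bin and obeys Parseval", {
  n <- 4096; rate <- 16000
  f <- 32 * rate / n                     # exact bin
  x <- sin(2 * pi * f * (0:(n - 1)) / rate)
  sp <- magnitude_spectrum_db(x, rate)
  expect_equal(sp$frequency_hz[which.max(sp$magnitude)], f)
  # Parseval: sum x^2 == sum |X|^2 / n, reassembled from the one-sided form
  two_sided <- sp$magnitude^2 * n
  two_sided[2:(n / 2)] <- 2 * two_sided[2:(n / 2)]
  expect_equal(sum(two_sided), sum(x^2), tolerance = 1e-6)
  # zero signal sits at the eps floor
  sp0 <- magnitude_spectrum_db(numeric(256), rate)
  expect_true(all(sp0$magnitude_db == 20 * log10(1e-12)))
  expect_error(magnitude_spectrum_db(numeric(0), rate), "empty")
})

test_that("resampling 48 kHz to 16 kHz preserves DC and passband tones", {
  n <- 48000
  y <- resample_to_16k(rep(0.3, n), 48000)
  expect_length(y, 16000)
  expect_equal(y[1000:15000], rep(0.3, 14001), tolerance = 1e-6)

  t <- (0:(n - 1)) / 48000
  y100 <- resample_to_16k(sin(2 * pi * 100 * t), 48000)
  # sinusoid-fit oracle on the interior
  tt <- (1000:15000) / 16000
  fit <- stats::lm(y100[1000:15000 + 1] ~ sin(2 * pi * 100 * tt) +
                     cos(2 * pi * 100 * tt) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  expect_equal(amp, 1, tolerance = 0.01)
})

test_that("the resampler's anti-aliasing filter has a sharp 8 kHz edge", {
  n <- 96000
  t <- (0:(n - 1)) / 48000
  interior_rms <- function(y) {
    yi <- y[3000:(length(y) - 3000)]
    sqrt(2 * mean(yi^2))
  }
  expect_gt(interior_rms(resample_to_16k(sin(2 * pi * 7900 * t), 48000)),
            0.9)
  supp <- 20 * log10(interior_rms(
    resample_to_16k(sin(2 * pi * 8100 * t), 48000)))
  expect_lt(supp, -40)
})

test_that("resampling preserves in-band energy and rejects odd ratios", {
  x <- withr::with_seed(5, {
    lp <- design_butterworth("low_pass", 8, 6500, 48000)
    apply_filter(lp, stats::rnorm(96000))
  })
  y <- resample_to_16k(x, 48000)
  p_in <- mean(x[10000:90000]^2)
  p_out <- mean(y[4000:28000]^2)
  expect_equal(p_out / p_in, 1, tolerance = 0.02)
  expect_error(resample_to_16k(numeric(100), 48000 * pi), "ratio")
})
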