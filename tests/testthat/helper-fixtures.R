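# Shared fixture builders. Everything is generated in code; no binary
# fixtures live in the repository.

# A clip holding the same sine on every channel.
sine_clip <- function(freq = 1000, rate = 16000, ms = 2500, channels = 4,
                      amp = 1, date = "2022-06-14",
                      species = "Bombus terrestris", index = 0L) {
  n <- round(ms / 1000 * rate)
  s <- amp * sin(2 * pi * freq * (0:(n - 1)) / rate)
  clip(matrix(rep(s, channels), ncol = channels), rate,
       date = date, species = species, index = index)
}

# A random multichannel recording with finite amplitudes.
random_recording <- function(n = 48000, channels = 4, rate = 48000,
                             seed = 1) {
  withr::with_seed(seed, {
    recording(matrix(stats::runif(n * channels, -0.5, 0.5), ncol = channels),
              rate, date = "2022-06-14", species = "Bombus terrestris",
              source_id = "random_fixture")
  })
}

# A random clip manifest: n_species species, each with dates drawn from a
# pool and a random number of clips per (species, date).
random_manifest <- function(seed, n_species = 3, max_dates = 6,
                            max_clips = 20) {
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_species)) {
      n_dates <- sample(1:max_dates, 1)
      dates <- as.Date("2022-06-01") + sample(0:60, n_dates)
      for (d in dates) {
        k <- sample(1:max_clips, 1)
        rows[[length(rows) + 1]] <- tibble::tibble(
          path = sprintf("sp%d_%s_%03d.wav", s, as.Date(d), seq_len(k)),
          species = sprintf("Genus species%d", s),
          date = as.Date(d), duration_ms = 2500,
          spl_db = NA_real_, split = NA_character_)
      }
    }
    dplyr::bind_rows(rows)
  })
}

# Minimum L1 clip-count imbalance over all split assignments of date
# groups that use each of the three splits at least once (exhaustive
# search; feasible for <= 8 groups).
exhaustive_best_imbalance <- function(group_counts, fractions) {
  k <- length(group_counts)
  total <- sum(group_counts)
  target <- fractions * total
  best <- Inf
  for (code in 0:(3^k - 1)) {
    a <- integer(k)
    c0 <- code
    for (i in seq_len(k)) { a[i] <- c0 %% 3; c0 <- c0 %/% 3 }
    if (length(unique(a)) < 3) next
    got <- c(sum(group_counts[a == 0]), sum(group_counts[a == 1]),
             sum(group_counts[a == 2]))
    best <- min(best, sum(abs(got - target)))
  }
  best
}

# Imbalance of a labelled manifest for one species.
achieved_imbalance <- function(manifest, fractions) {
  counts <- c(train = sum(manifest$split == "train"),
              val = sum(manifest$split == "val"),
              test = sum(manifest$split == "test"))
  sum(abs(counts - fractions * nrow(manifest)))
}

# Hand-built energy profile (for threshold-rule unit tests).
manual_profile <- function(energies, window_len = 3279L, hop = 1024L) {
  structure(list(energies = as.numeric(energies),
                 window_len = as.integer(window_len), hop = as.integer(hop),
                 n_samples = (length(energies) - 1L) * hop + window_len),
            class = "energy_profile")
}

# Intervals tibble shorthand (0-based sample indices).
iv <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Sine-sweep multichannel segment (for enclosure tests).
sweep_segment <- function(dur_s = 2, rate = 8000, channels = 2,
                          f0 = 100, f1 = 3000, amp = 0.1, seed = 1) {
  n <- round(dur_s * rate)
  t <- (0:(n - 1)) / rate
  sweep <- amp * sin(2 * pi * (f0 * t + (f1 - f0) / (2 * dur_s) * t^2))
  withr::with_seed(seed, {
    matrix(rep(sweep, channels), ncol = channels) +
      matrix(stats::rnorm(n * channels, sd = 1e-4), ncol = channels)
  })
}

# Write a minimal 16-bit PCM WAVE file by hand (independent of the
# package's writer) holding a constant value on every channel.
write_pcm16_wave <- function(path, value_int, n = 1000, channels = 1,
                             rate = 16000, fmt_tag = 1L) {
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- n * channels * 2L
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                              endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                              endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(fmt_tag); w16(channels); w32(rate)
  w32(rate * channels * 2L); w16(channels * 2L); w16(16L)
  writeChar("data", con, eos = NULL); w32(data_size)
  writeBin(rep(as.integer(value_int), n * channels), con, size = 2L,
           endian = "little")
  invisible(path)
}

# Read the 'data' chunk payload size of a WAVE file (header oracle).
wave_data_chunk_size <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little")
  readChar(con, 4, useBytes = TRUE)
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "data")) return(size)
    seek(con, size + size %% 2, origin = "current")
  }
}
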