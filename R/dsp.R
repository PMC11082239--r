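#' Design a Butterworth filter as second-order sections
#'
#' Designs digital low- or high-pass Butterworth filters by bilinear
#' transform of the analog prototype with frequency pre-warping, returned
#' as a cascade of second-order sections (SOS). The SOS realization is
#' essential here: the activity-detection prefilter uses an order-30
#' high-pass whose single transfer-function polynomial would be numerically
#' unusable, while its biquad sections are well conditioned and provably
#' stable.
#'
#' @param kind `"low_pass"` or `"high_pass"`.
#' @param order filter order (>= 1).
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param rate_hz sample rate in Hz; `cutoff_hz` must be below `rate_hz/2`.
#' @return an object of class `butter_filter` with fields `kind`, `order`,
#'   `cutoff_hz`, `rate_hz` and `sos`, a `n_sections x 6` matrix of
#'   `(b0, b1, b2, a0 = 1, a1, a2)` coefficients.
#' @examples
#' hp <- design_butterworth("high_pass", 30, 180, 16000)
#' filter_gain_db(hp, 50)   # deep in the stopband
#' @export
design_butterworth <- function(kind = c("low_pass", "high_pass"), order,
                               cutoff_hz, rate_hz) {
  kind <- match.arg(kind)
  order <- as.integer(order)
  if (is.na(order) || order < 1L) {
    stop("`order` must be a positive integer", call. = FALSE)
  }
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    stop("`cutoff_hz` must lie strictly between 0 and rate_hz/2",
         call. = FALSE)
  }
  # pre-warped analog cutoff so the digital -3 dB point lands on cutoff_hz
  K <- 2 * rate_hz
  wc <- K * tan(pi * cutoff_hz / rate_hz)

  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  poles <- complex(modulus = 1, argument = theta)

  # conjugate pairs (+ one real pole for odd order)
  n_pairs <- order %/% 2L
  sos <- matrix(0, nrow = n_pairs + (order %% 2L), ncol = 6L)
  row <- 1L
  for (j in seq_len(n_pairs)) {
    re2 <- -2 * Re(poles[j])           # > 0 for stable prototype pair
    if (kind == "low_pass") {
      # wc^2 / (s^2 + re2*wc*s + wc^2)
      sec <- bilinear_sos(c(0, 0, wc^2), c(1, re2 * wc, wc^2), K)
    } else {
      # s^2 / (s^2 + re2*wc*s + wc^2)  (poles at wc/p)
      sec <- bilinear_sos(c(1, 0, 0), c(1, re2 * wc, wc^2), K)
    }
    sos[row, ] <- sec
    row <- row + 1L
  }
  if (order %% 2L == 1L) {
    if (kind == "low_pass") {
      sec <- bilinear_sos(c(0, 0, wc), c(0, 1, wc), K)
    } else {
      sec <- bilinear_sos(c(0, 1, 0), c(0, 1, wc), K)
    }
    sos[row, ] <- sec
  }
  structure(list(kind = kind, order = order, cutoff_hz = cutoff_hz,
                 rate_hz = rate_hz, sos = sos),
            class = "butter_filter")
}

# Bilinear transform of one analog section b(s)/a(s) (descending powers,
# quadratic or linear) to digital (b0,b1,b2,1,a1,a2).
bilinear_sos <- function(b, a, K) {
  B0 <- b[1] * K^2 + b[2] * K + b[3]
  B1 <- 2 * b[3] - 2 * b[1] * K^2
  B2 <- b[1] * K^2 - b[2] * K + b[3]
  A0 <- a[1] * K^2 + a[2] * K + a[3]
  A1 <- 2 * a[3] - 2 * a[1] * K^2
  A2 <- a[1] * K^2 - a[2] * K + a[3]
  c(B0 / A0, B1 / A0, B2 / A0, 1, A1 / A0, A2 / A0)
}

#' @rdname design_butterworth
#' @param spec a `butter_filter`.
#' @param f frequency (Hz), vectorized.
#' @return `filter_gain_db()`: gain of the digital cascade at `f`, in dB.
#' @export
filter_gain_db <- function(spec, f) {
  stopifnot(inherits(spec, "butter_filter"))
  w <- 2 * pi * f / spec$rate_hz
  z1 <- exp(-1i * w)
  g <- rep(1 + 0i, length(w))
  for (s in seq_len(nrow(spec$sos))) {
    co <- spec$sos[s, ]
    g <- g * (co[1] + co[2] * z1 + co[3] * z1^2) /
      (1 + co[5] * z1 + co[6] * z1^2)
  }
  20 * log10(abs(g))
}

#' @rdname design_butterworth
#' @return `filter_poles()`: complex poles of every section (all strictly
#'   inside the unit circle for a valid design).
#' @export
filter_poles <- function(spec) {
  stopifnot(inherits(spec, "butter_filter"))
  unlist(lapply(seq_len(nrow(spec$sos)), function(s) {
    a <- spec$sos[s, 4:6]
    if (a[3] == 0 && a[2] == 0) return(complex(0))
    polyroot(rev(a))
  }))
}

#' Apply an IIR filter causally
#'
#' Runs the signal through the section cascade in direct form, forward
#' only (no zero-phase/bidirectional filtering): output length equals input
#' length and the filter is causal, so detection thresholds computed from
#' the output are reproducible sample-for-sample in a streaming setting.
#'
#' @param spec a [design_butterworth()] filter.
#' @param x numeric vector, or matrix with one column per channel.
#' @param rate_hz optional rate of `x` in Hz; must equal the design rate.
#' @return filtered signal, same shape as `x`.
#' @export
apply_filter <- function(spec, x, rate_hz = NULL) {
  stopifnot(inherits(spec, "butter_filter"))
  if (!is.null(rate_hz) && !isTRUE(all.equal(rate_hz, spec$rate_hz))) {
    stop("signal rate ", rate_hz, " Hz does not match filter design rate ",
         spec$rate_hz, " Hz", call. = FALSE)
  }
  one <- function(v) {
    for (s in seq_len(nrow(spec$sos))) {
      co <- spec$sos[s, ]
      v <- as.numeric(signal::filter(co[1:3], c(1, co[5], co[6]), v))
    }
    v
  }
  if (is.matrix(x)) apply(x, 2L, one) else one(as.numeric(x))
}

#' Windowed signal energy
#'
#' Slides a rectangular window of `window_len` samples in steps of `hop`
#' samples and records the energy (sum of squared samples) of each window.
#' A trailing window that would extend past the end of the signal is
#' dropped rather than zero-padded, so the mean energy used for activity
#' thresholding is not biased downward. The defaults are the activity
#' detector's: 3279-sample windows hopped by 1024 on the 16 kHz timeline.
#'
#' @param x numeric signal vector, at least `window_len` samples.
#' @param window_len window length in samples.
#' @param hop hop between window starts in samples.
#' @return an `energy_profile` object: `energies` (one per window),
#'   `window_len`, `hop`, `n_samples`. Window `k` (1-based) covers the
#'   0-based sample range `[(k-1)*hop, (k-1)*hop + window_len)`.
#' @export
windowed_energy <- function(x, window_len = 3279L, hop = 1024L) {
  x <- as.numeric(x)
  window_len <- as.integer(window_len)
  hop <- as.integer(hop)
  stopifnot(window_len >= 1L, hop >= 1L)
  n <- length(x)
  if (n < window_len) {
    stop("signal (", n, " samples) is shorter than one window (",
         window_len, ")", call. = FALSE)
  }
  n_win <- (n - window_len) %/% hop + 1L
  cs <- c(0, cumsum(x^2))
  starts <- (seq_len(n_win) - 1L) * hop
  energies <- cs[starts + window_len + 1L] - cs[starts + 1L]
  energies <- pmax(energies, 0)  # guard cumsum rounding
  structure(list(energies = energies, window_len = window_len, hop = hop,
                 n_samples = n),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf(
    "<energy_profile> %d windows (len %d, hop %d) over %d samples\n",
    length(x$energies), x$window_len, x$hop, x$n_samples))
  invisible(x)
}

#' Centered moving-average smoothing
#'
#' Centered mean over an odd-length window; at the edges the window
#' shrinks symmetrically to the available points, so the output has the
#' same length as the input and no samples are invented. Window 51 is the
#' smoothing used for attenuation spectra.
#'
#' @param x numeric vector.
#' @param window odd positive window length in samples.
#' @return smoothed vector, `length(x)`.
#' @export
moving_average <- function(x, window = 51L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) return(x)
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  hw <- pmin(h, i - 1L, n - i)
  cs <- c(0, cumsum(x))
  (cs[i + hw + 1L] - cs[i - hw]) / (2 * hw + 1)
}

#' One-sided magnitude spectrum in dB
#'
#' Amplitude-normalized DFT magnitude (`|X(f)| / n`) on the one-sided
#' frequency grid `0, rate/n, ..., floor(n/2) * rate/n`. Decibel values are
#' `20 * log10(magnitude + eps)` with a small floor `eps` so silent bins
#' stay finite; the default floor of 1e-12 full scale sits far below any
#' physical noise floor.
#'
#' @param x numeric signal vector (non-empty).
#' @param rate_hz sample rate in Hz.
#' @param eps magnitude floor in full-scale units.
#' @return a tibble with columns `frequency_hz`, `magnitude`,
#'   `magnitude_db`.
#' @export
magnitude_spectrum_db <- function(x, rate_hz, eps = 1e-12) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  n <- length(x)
  X <- stats::fft(x)
  nf <- n %/% 2L + 1L
  mag <- Mod(X[seq_len(nf)]) / n
  tibble::tibble(
    frequency_hz = (seq_len(nf) - 1L) * rate_hz / n,
    magnitude = mag,
    magnitude_db = 20 * log10(mag + eps)
  )
}
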