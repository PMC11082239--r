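#' Star microphone array geometry
#'
#' The recording array is a planar star: one microphone at the center and
#' three on a circle of given radius, 120 degrees apart. The geometry
#' fixes two characteristic spacings — the radius itself (center to outer)
#' and the outer-pair spacing `radius * sqrt(3)` — which in turn set the
#' usable delay-and-sum beamforming band through the spatial-aliasing rule
#' `0.25 < d / lambda < 0.5`.
#'
#' @param radius_m center-to-outer distance in meters (recording rig:
#'   0.055 m).
#' @param speed_of_sound_mps speed of sound in m/s (343, air at 20 C).
#' @return a `star_array` with `radius_m`, `speed_of_sound_mps` and
#'   `positions`, a 4 x 3 matrix of microphone coordinates in meters
#'   (center first, array plane z = 0).
#' @examples
#' arr <- star_array(0.055)
#' outer_pair_spacing(arr) * 1000  # 95.26 mm
#' beamforming_range(arr)          # c(900, 3118) Hz
#' @export
star_array <- function(radius_m = 0.055, speed_of_sound_mps = 343) {
  if (!is.finite(radius_m) || radius_m <= 0) {
    stop("`radius_m` must be positive", call. = FALSE)
  }
  ang <- c(90, 210, 330) * pi / 180
  positions <- rbind(c(0, 0, 0),
                     cbind(radius_m * cos(ang), radius_m * sin(ang), 0))
  rownames(positions) <- c("center", "outer1", "outer2", "outer3")
  colnames(positions) <- c("x", "y", "z")
  structure(list(radius_m = radius_m,
                 speed_of_sound_mps = speed_of_sound_mps,
                 positions = positions),
            class = "star_array")
}

#' @rdname star_array
#' @param array a `star_array`.
#' @return `outer_pair_spacing()`: the distance between any two outer
#'   microphones in meters (`radius * sqrt(3)`).
#' @export
outer_pair_spacing <- function(array) {
  stopifnot(inherits(array, "star_array"))
  array$radius_m * sqrt(3)
}

#' Delay-and-sum beamforming design frequency range
#'
#' Basic delay-and-sum beamforming works well while the element spacing
#' `d` satisfies `0.25 < d / lambda < 0.5`: below that the phase
#' differences are too small to steer, above it spatial aliasing sets in.
#' For the star array the lower bound is set by the *largest* spacing (the
#' outer pair, `r * sqrt(3)`) and the upper bound by the *smallest* (the
#' radius), giving `f_low = 0.25 c / (r sqrt(3))` and
#' `f_high = 0.5 c / r`. With the 55 mm recording rig and c = 343 m/s this
#' is 900 Hz to 3118 Hz — above insect wingbeat fundamentals but covering
#' most of their harmonics.
#'
#' @param array a [star_array()].
#' @return named numeric `c(f_low_hz, f_high_hz)`, rounded to whole Hz.
#' @export
beamforming_range <- function(array) {
  stopifnot(inherits(array, "star_array"))
  c_s <- array$speed_of_sound_mps
  f_low <- 0.25 * c_s / outer_pair_spacing(array)
  f_high <- 0.5 * c_s / array$radius_m
  c(f_low_hz = round(f_low), f_high_hz = round(f_high))
}

#' @export
print.star_array <- function(x, ...) {
  rng <- beamforming_range(x)
  cat(sprintf(
    "<star_array> radius %.1f mm, outer pair %.2f mm, c = %g m/s\n",
    1000 * x$radius_m, 1000 * outer_pair_spacing(x),
    x$speed_of_sound_mps))
  cat(sprintf("  delay-and-sum design range: %d-%d Hz\n",
              rng[1], rng[2]))
  invisible(x)
}
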