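---
title: "From quiet recordings to labelled clips: the insectclip methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From quiet recordings to labelled clips: the insectclip methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Most insects have no vocal organ. The sounds that give them away are an
involuntary byproduct of moving their body parts — mostly their wings — so
an insect's acoustic signature is a harmonic stack on a wingbeat
fundamental, typically between roughly 77 Hz (lady beetles) and 180 Hz
(small flies), with a hard neuromuscular ceiling near 1 kHz. These sounds
are extremely quiet; recording them means hours of near-silence inside a
sound-isolated enclosure, captured by a sensitive multichannel microphone
array, with insect activity occupying a tiny fraction of the timeline.

`insectclip` turns such long, mostly silent multichannel recordings into a
dataset of fixed-length labelled sound clips, and provides the
surrounding tooling a dataset builder needs: per-clip level statistics,
leakage-safe dataset splits, enclosure attenuation spectra, the
microphone-array design rule, and a seeded synthetic scene generator that
makes every stage testable without any real recordings.

## The extraction program

`extract_clips()` implements an eight-step program. Its defaults are the
parameter set used to produce a large published insect-sound dataset with
this method; they are the package's reference conditions, not knobs to
re-tune per run.

1. **Load** a multichannel WAVE recording (`read_wave()`).
2. **Downsample** every channel to 16 kHz. Insect sound is concentrated at
   low frequencies, so 16 kHz — resolving content to 8 kHz by
   Nyquist — retains the information while cutting data volume threefold
   from a 48 kHz acquisition.
3. **Select the loudest channel** by total squared signal sum. Detection
   then runs on one channel only, which makes the remaining steps cheap.
   Ties go to the lowest channel index.
4. **Prefilter** that channel with a 4th-order Butterworth low-pass at
   1500 Hz and a 30th-order Butterworth high-pass at 180 Hz. The
   aggressive high-pass suppresses the low-frequency environmental noise
   that penetrates enclosure walls most easily; the low-pass bounds the
   detection band from above.
5. **Windowed energy**: the sum of squared samples over 3279-sample
   windows hopped by 1024 samples. A trailing partial window is dropped,
   not zero-padded — padded windows would bias the mean energy (and hence
   the threshold) downward.
6. **Threshold**: windows whose energy strictly exceeds 1.6 times the mean
   window energy of the file are active. The threshold is *relative*, so a
   constant recording — whatever its level — produces no activity. The mean
   is computed over whatever the input file's duration is; for files of
   the original production length (about 14 minutes) this is exactly the
   original rule, and it generalizes unchanged to other durations. Active
   windows are mapped back to sample ranges and merged where they overlap
   or abut; merging happens *before* the pruning rule below, one of two
   possible orderings the original description leaves open.
7. **Prune and segment**: active segments shorter than 1 s with no other
   activity within 2500 ms before or after are discarded as noise (lone
   blips; a missing neighbor counts as an infinitely distant one). Then
   non-overlapping 2500 ms clip windows are placed over the remaining
   activity. The placement is a greedy left-to-right walk: a window opens
   at the start of the first uncovered interval (shifted left if it would
   overrun the file end); intervals fully covered are consumed; an
   interval running past the window's end makes the next window start
   exactly at that end (long activity is covered back-to-back); otherwise
   the next window opens at the next uncovered interval's start. The
   original description ("a cascade of if-else cases") fixes the
   constraints — non-overlap, equal length, every clip contains
   activity — but not the algorithm; the greedy walk is one deterministic
   realization of those constraints, and the one this package commits to.
8. **Emit**: clips are cut from the *resampled but unfiltered* multichannel
   signal — filtering only ever influences detection, never the audio that
   reaches disk — and written as four-channel 16 kHz float32 WAVE files of
   exactly 40000 samples (an audio payload of 4 × 40000 × 4 bytes =
   625 KiB per clip).

```{r}
library(insectclip)
rec <- read_wave("night_recording.wav")
res <- extract_clips(rec, pipeline_params())
glance(res$report)
```

Boundary behavior the original description never addresses is fixed as:
clips near the file end shift left to fit; recordings shorter than one
clip produce zero clips and a warning.

### Numerical choices

Filtering is causal and forward-only (no zero-phase passes): the original
processing gives no indication of bidirectional filtering, and a causal
contract keeps the detection threshold semantics reproducible in a
streaming setting. The order-30 high-pass is designed and applied as a
cascade of second-order sections; a single direct-form polynomial of
order 30 is numerically unusable, while the biquad cascade keeps all pole
moduli below 1 (verified in the tests, along with a closed-form stopband
check: the analog magnitude at 50 Hz is about −334 dB; the digital design
is required to beat −100 dB).

The resampler is a Kaiser-windowed-sinc polyphase decimator (60 dB
stopband, transition band 2.5% of the cutoff) applied by overlap-save FFT
convolution with the group delay compensated. For 48 kHz input this
passes 7.9 kHz essentially untouched and suppresses 8.1 kHz by more than
40 dB. An installed general-purpose resampler was evaluated for this role
and measured at only ~5 dB suppression past Nyquist with a visible
passband droop, which fails the anti-aliasing contract; hence the
in-package implementation.

## The level statistic

`clip_spl()` computes one dB value per clip: per channel, subtract the
channel mean (offset correction), apply a 50 Hz 4th-order Butterworth
high-pass, and take the mean square; pool (average) the mean squares
across channels; report `10 log10(pooled / ref²)`. Pooling mean squares
rather than averaging per-channel dB values is deliberate: it keeps the
scaling law exact (scaling all samples by *a* shifts the level by exactly
`20 log10 a`), which dB-averaging breaks. The default reference is
digital full scale (dBFS). Absolute SPL re 20 µPa is available by
supplying a calibration factor in Pa per full-scale unit — absolute
values published for the original dataset depend on that rig's
calibration and are not reproducible without it.

## Leakage-safe splitting

Classifiers can learn to recognize the *recording session* rather than
the insect: per-night background structure below human perception leaks
the label when clips from one date land on both sides of a split.
`split_by_date()` therefore assigns whole date-groups of clips, per
species, to train/validation/test. The assignment is greedy: groups
sorted largest first (ties shuffled by the seed) go to whichever split is
furthest below its target clip count, with a reservation that every split
receives at least one date. Default fractions are 70/15/15 — the method's
source gives none, and 70/15/15 is the common machine-learning default.
The greedy choice trades exact optimality for determinism and scale; the
tests verify it lands within one date-group's worth of clips of the
exhaustive optimum for up to 8 dates (moving a single group changes the
L1 imbalance by at most twice that group's size, which is the bound
used). Species with fewer than three distinct dates cannot be split
date-disjointly into three parts and go entirely to train, with a
warning. `verify_split()` independently audits any labelled manifest.

Splitting by *individual insect* would be the stricter guard but is
impossible here by construction: individuals were not documented in the
recording protocol this package mirrors.

## Enclosure validation

`scenario_spectrum()` reproduces the enclosure attenuation measurement:
per sweep segment and channel a one-sided amplitude spectrum, averaged in
the linear magnitude domain across all segments and channels, converted
to dB, and smoothed with a centered 51-point moving average. Linear-domain
averaging (the measurement's description says only "averaged") is the
standard spectral estimator and makes a constructed attenuation step
recover exactly: the tests build a test scenario scaled by −50 dB above
1 kHz and require recovery within 0.1 dB. `attenuation_spectrum()` is the
dB difference reference − test, antisymmetric by construction.
`spectrum_noise_floor()` reports (not corrects) the floor visible in the
flattest stretches of a closed-box spectrum, as the median level of the
flattest decile.

The sweep segments are used whole (20 s sweep plus trailing silence);
whether the silence should be windowed out before the FFT is left open by
the original method, and including it only adds a constant noise-floor
contribution common to all scenarios.

## Array geometry

The recording array is a star: one center microphone and three on a
55 mm radius, 120° apart, giving an outer-pair spacing of
`r_outer = 0.055 * sqrt(3)` ≈ 95.26 mm. Basic delay-and-sum beamforming
works well for `0.25 < d/λ < 0.5`; `beamforming_range()` applies the
lower bound to the *largest* spacing (outer pair) and the upper bound to
the *smallest* (the radius), the only reading consistent with both
printed design numbers (900 Hz and 3118 Hz), and fixes the speed of sound
at 343 m/s (air at 20 °C; the only value reproducing both bounds). This
band sits above wingbeat fundamentals but covers most of their harmonics.

## The synthetic scene generator

`render_scene()` emulates what the recording rig sees, with known ground
truth:

* **Events** are harmonic stacks `Σ (A/k) sin(2π k f0 t + φ_k)` with
  seeded random phases, a rectangular or Hann-tapered envelope (5%
  raised-cosine ramps), and harmonics above Nyquist dropped.
* **Propagation**: each event is mixed into every channel with
  1/distance amplitude scaling (reference 1 m) and its exact propagation
  delay applied as a frequency-domain phase shift. Array delays at
  48 kHz span only a few samples, so rounding to whole samples would
  erase the geometry; fractional delays are essential.
* **Noise floor**: stationary white or pink noise at a stated dBFS RMS.
  Pink noise — the character of everyday ambient sound — is synthesized by
  1/√f spectral shaping of white Gaussian noise; long signals are shaped
  block-wise under 50%-overlapping power-complementary sine windows,
  which keeps the synthesis stationary in its second-order statistics at
  a small fraction of the cost of one giant FFT. The default floor is
  −60 dBFS, a plausible hiss level for a low-noise measurement chain at
  high gain.
* **Clipping** is never silent: scenes whose mix exceeds full scale warn.

`make_extraction_fixture()` wraps this for pipeline testing: events of
1.5 s (safely above the 1 s pruning rule) separated by more than the
2500 ms neighbor range, fundamentals drawn uniformly from 77–180 Hz,
positions jittered 25–35 cm in front of the array, and amplitudes solved
in closed form so the in-band (180–1500 Hz) SNR between event and noise
floor on the nearest-microphone channel hits the request; the tests
verify the realized SNR within ±1 dB and use 5-minute scenes with 20 dB
events as the reference recovery condition (recall and precision at
least 0.95).

What the generator does *not* emulate: real wingbeat frequency modulation
and amplitude flutter, insect motion during an event (Doppler and
time-varying level differences), reverberation (the enclosure is
near-anechoic by design), non-flight sounds (footsteps, scratching), and
overlapping simultaneous insects. Passing recovery tests on these
fixtures therefore demonstrates the *detector's* correctness under the
stated SNR and isolation conditions, not classification-grade realism.

## File conventions

Clips are IEEE float32 WAVE files named
`<YYYY-MM-DD>_<Genus>_<species>_<NNNNNN>.wav`: recording date, full
scientific species name, and a zero-padded six-digit running index. The
index is this package's own convention — some unique suffix is needed for
well-defined filenames, and a sortable fixed-width integer is the
simplest parseable choice. The raw-input boundary is WAVE: vendor
acquisition formats are expected to be converted externally (a one-line
job with the vendor's own tooling), since they are orthogonal to the
method. Manifests are CSV with header
`path,species,date,duration_ms,spl_db,split`.

## Problem sizes in the tests

The test-suite uses 30–60 s scenes for unit-level checks and one
5-minute, 12-event scene for the end-to-end recovery check; the
windowed-energy brute-force comparison runs on 100 random signals of up
to 12000 samples. These sizes were chosen to exercise every code path —
including multi-clip segmentation and pruning — at desk scale; the
production conditions they emulate (14-minute files, hours of material)
differ only in length, which enters the method solely through the mean
energy of the threshold rule.

## Known limitations

* The extraction program's segmentation is *a* deterministic realization
  of the published constraints, not a bit-level reimplementation of the
  original script; counts on real archives may differ at activity edge
  cases.
* dBFS levels are only comparable across rigs after calibration.
* The synthetic generator's realism limits are listed above.
* Only uncompressed WAVE input is supported (PCM 16/24/32 and float32).
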