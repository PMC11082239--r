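Package: insectclip
Title: Extraction and Analysis of Insect Sound Clips from Long Quiet
    Multichannel Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning long, mostly silent multichannel audio
    recordings of insects into fixed-length labelled sound clips. Implements
    energy-based acoustic activity detection on a Butterworth-prefiltered
    channel, anti-aliased downsampling to 16 kHz, non-overlapping 2500 ms
    clip segmentation, per-clip sound pressure level statistics, leakage-safe
    recording-date-disjoint dataset splitting, enclosure attenuation spectra
    from sine-sweep measurements, star microphone-array geometry with the
    delay-and-sum spatial-aliasing design rule, and a seeded synthetic
    multichannel scene generator with ground-truth event times for testing
    every pipeline stage without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
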