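#' Run clip extraction over a set of WAVE files
#'
#' Batch front end over [extract_clips()]: each input file is read,
#' processed with the same parameters, and its clips are written to
#' `out_dir` named by the clip grammar; a JSON extraction report is
#' written per input and an aggregate manifest over all emitted clips is
#' returned (and written as CSV). A corrupt or unreadable input is
#' reported and skipped; the remaining files are still processed.
#'
#' @param inputs character vector of WAVE paths.
#' @param out_dir output directory for clips, reports and the manifest
#'   (created if missing).
#' @param params a [pipeline_params()].
#' @param species,date optional provenance overrides applied to every
#'   input (otherwise recovered from each filename when possible).
#' @return a list with `manifest` (tibble over all written clips),
#'   `reports` (list of `extraction_report`s) and `failures` (tibble of
#'   failed inputs and their error messages).
#' @export
run_extract <- function(inputs, out_dir, params = pipeline_params(),
                        species = NULL, date = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (length(inputs) == 0L) {
    warning("no input files given; writing an empty manifest")
  }
  reports <- list()
  failures <- list()
  rows <- list()
  next_index <- 0L
  for (path in inputs) {
    res <- tryCatch({
      rec <- read_wave(path, species = species, date = date)
      extract_clips(rec, params, index_start = next_index)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(path = path, error = conditionMessage(res))
      next
    }
    message(sprintf("%s: threshold %.4g, %d clip(s)", basename(path),
                    res$report$energy_threshold, res$report$n_clips))
    reports[[length(reports) + 1L]] <- res$report
    report_path <- file.path(
      out_dir, paste0(tools::file_path_sans_ext(basename(path)),
                      "_report.json"))
    jsonlite::write_json(unclass(res$report), report_path,
                         auto_unbox = TRUE, digits = NA)
    for (cl in res$clips) {
      p <- write_clip(cl, out_dir, clip_ms = params$clip_ms)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        path = p, species = cl$species, date = cl$date,
        duration_ms = 1000 * n_samples(cl) / cl$rate)
      next_index <- next_index + 1L
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0L) {
    manifest <- tibble::tibble(path = character(), species = character(),
                               date = as.Date(character()),
                               duration_ms = numeric())
  }
  manifest$spl_db <- rep(NA_real_, nrow(manifest))
  manifest$split <- rep(NA_character_, nrow(manifest))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  list(manifest = manifest, reports = reports,
       failures = dplyr::bind_rows(failures))
}

#' Compute per-clip levels for a manifest on disk
#'
#' @param manifest_path manifest CSV path; rewritten with `spl_db` filled.
#' @param cfg a [level_config()].
#' @return the updated manifest tibble.
#' @export
run_spl <- function(manifest_path, cfg = level_config()) {
  manifest <- add_levels(read_manifest(manifest_path), cfg)
  write_manifest(manifest, manifest_path)
  manifest
}

#' Split a manifest on disk by recording date
#'
#' @param manifest_path manifest CSV path; rewritten with `split` filled.
#' @param spec a [split_spec()].
#' @return the updated manifest tibble.
#' @export
run_split <- function(manifest_path, spec = split_spec()) {
  manifest <- split_by_date(read_manifest(manifest_path), spec)
  violations <- verify_split(manifest)
  if (nrow(violations) > 0L) {
    stop("internal error: split is not date-disjoint", call. = FALSE)
  }
  write_manifest(manifest, manifest_path)
  manifest
}

#' Compute enclosure attenuation spectra from a scenario config
#'
#' The configuration (a list, typically read from YAML) names one WAVE
#' recording and its sweep timestamps per scenario plus the reference
#' scenario. Per-scenario smoothed spectra and per-scenario attenuation
#' against the reference are written as CSV (`frequency_hz,value_db`).
#'
#' @param config list with elements `scenarios` (list of
#'   `list(name, path, timestamps)`), `reference` (scenario name),
#'   optional `seg_s` (default 21) and `smooth_window` (default 51).
#' @param out_dir directory for CSV outputs (created if missing).
#' @return a list with `spectra` (named list of tibbles) and
#'   `attenuation` (named list of [attenuation_spectrum()] results).
#' @export
run_attenuation <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seg_s <- config$seg_s %||% 21
  smooth <- config$smooth_window %||% 51L
  spectra <- list()
  for (sc in config$scenarios) {
    rec <- read_wave(sc$path)
    segs <- extract_sweep_segments(rec, as.numeric(sc$timestamps), seg_s)
    scen <- sweep_scenario(sc$name, segs, rec$rate)
    sp <- scenario_spectrum(scen, smooth_window = smooth)
    spectra[[sc$name]] <- sp
    readr::write_csv(
      tibble::tibble(frequency_hz = sp$frequency_hz,
                     value_db = sp$magnitude_db),
      file.path(out_dir, paste0("spectrum_", sc$name, ".csv")))
  }
  ref_name <- config$reference %||% names(spectra)[1]
  if (!ref_name %in% names(spectra)) {
    stop("reference scenario '", ref_name, "' not among scenarios",
         call. = FALSE)
  }
  attenuation <- list()
  for (nm in setdiff(names(spectra), ref_name)) {
    att <- attenuation_spectrum(spectra[[ref_name]], spectra[[nm]])
    attenuation[[nm]] <- att
    readr::write_csv(
      tibble::tibble(frequency_hz = att$spectrum$frequency_hz,
                     value_db = att$spectrum$attenuation_db),
      file.path(out_dir, paste0("attenuation_", nm, ".csv")))
  }
  list(spectra = spectra, attenuation = attenuation)
}

#' Array geometry report
#'
#' @param radius_m star-array radius in meters.
#' @param speed_of_sound_mps speed of sound in m/s.
#' @return a list with `positions_m`, `outer_pair_spacing_m` and
#'   `beamforming_range_hz`, ready for JSON serialization.
#' @export
run_geometry <- function(radius_m = 0.055, speed_of_sound_mps = 343) {
  arr <- star_array(radius_m, speed_of_sound_mps)
  rng <- beamforming_range(arr)
  list(radius_m = arr$radius_m,
       speed_of_sound_mps = arr$speed_of_sound_mps,
       positions_m = apply(arr$positions, 1L, as.numeric,
                           simplify = FALSE),
       outer_pair_spacing_m = outer_pair_spacing(arr),
       beamforming_range_hz = list(f_low = unname(rng[1]),
                                   f_high = unname(rng[2])))
}

#' Render a synthetic fixture scene to disk
#'
#' Writes the rendered multichannel scene as a float32 WAVE plus the
#' ground-truth event table as CSV (`t_start_s,duration_s,f0_hz`).
#'
#' @param out_dir output directory (created if missing).
#' @param n_events,snr_db,seed,duration_s,rate_hz passed to
#'   [make_extraction_fixture()].
#' @return list with `wave_path`, `truth_path` and the fixture itself.
#' @export
run_simulate <- function(out_dir, n_events = 5L, snr_db = 20, seed = 1L,
                         duration_s = 300, rate_hz = 48000) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fx <- make_extraction_fixture(n_events, snr_db = snr_db, seed = seed,
                                duration_s = duration_s, rate_hz = rate_hz)
  wave_path <- file.path(out_dir,
                         sprintf("synthetic_scene_seed%d.wav", seed))
  write_wave(fx$recording, wave_path)
  truth_path <- file.path(out_dir,
                          sprintf("synthetic_scene_seed%d_truth.csv", seed))
  readr::write_csv(fx$ground_truth[, c("t_start_s", "duration_s", "f0_hz")],
                   truth_path)
  list(wave_path = wave_path, truth_path = truth_path, fixture = fx)
}
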