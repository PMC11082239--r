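#' Clip filename grammar
#'
#' Clip files are named `<YYYY-MM-DD>_<Genus>_<species>_<NNNNNN>.wav`: the
#' recording date, the full scientific species name with spaces replaced by
#' underscores, and a zero-padded six-digit running index that guarantees
#' uniqueness within an extraction run. `format_clip_name()` and
#' `parse_clip_name()` are exact inverses on valid inputs.
#'
#' @param date recording date (`Date` or ISO string).
#' @param species scientific species name, e.g. `"Bombus terrestris"`.
#' @param index non-negative integer < 1e6.
#' @return `format_clip_name()`: the filename string. `parse_clip_name()`:
#'   a list with elements `date` (`Date`), `species` (string, underscores
#'   restored to spaces) and `index` (integer).
#' @examples
#' format_clip_name("2022-06-14", "Bombus terrestris", 31)
#' parse_clip_name("2022-06-14_Bombus_terrestris_000031.wav")
#' @export
format_clip_name <- function(date, species, index) {
  date <- as_iso_date(date)
  if (is.na(date)) stop("clip filename needs a valid date", call. = FALSE)
  species <- trimws(as.character(species))
  if (!nzchar(species)) {
    stop("clip filename needs a non-empty species name", call. = FALSE)
  }
  index <- as.integer(index)
  if (is.na(index) || index < 0L || index > 999999L) {
    stop("clip index must be an integer in [0, 999999]", call. = FALSE)
  }
  sprintf("%s_%s_%06d.wav", format(date, "%Y-%m-%d"),
          gsub(" ", "_", species), index)
}

#' @rdname format_clip_name
#' @param filename a clip filename (basename, with `.wav` extension).
#' @export
parse_clip_name <- function(filename) {
  if (!grepl("\\.wav$", filename, ignore.case = TRUE)) {
    stop("cannot parse clip name '", filename, "': missing .wav extension",
         call. = FALSE)
  }
  stem <- sub("\\.wav$", "", filename, ignore.case = TRUE)
  m <- regmatches(stem,
                  regexec("^(\\d{4}-\\d{2}-\\d{2})_(.+)_(\\d{6})$", stem))[[1]]
  if (length(m) != 4L) {
    if (!grepl("^\\d{4}-\\d{2}-\\d{2}_", stem)) {
      stop("cannot parse clip name '", filename,
           "': expected leading ISO date", call. = FALSE)
    }
    if (!grepl("_\\d{6}$", stem)) {
      stop("cannot parse clip name '", filename,
           "': expected trailing 6-digit index", call. = FALSE)
    }
    stop("cannot parse clip name '", filename,
         "': expected species name between date and index", call. = FALSE)
  }
  date <- tryCatch(as_iso_date(m[2]), error = function(e) as.Date(NA))
  if (is.na(date)) {
    stop("cannot parse clip name '", filename, "': invalid date '",
         m[2], "'", call. = FALSE)
  }
  list(date = date, species = gsub("_", " ", m[3]),
       index = as.integer(m[4]))
}

#' Build, read and write clip manifests
#'
#' A manifest is the tabular index of a clip collection: one row per `.wav`
#' file with its path, species, recording date, duration, optional sound
#' pressure level and optional split label. It drives dataset summaries and
#' the date-disjoint splitting.
#'
#' @param dir directory to scan (non-recursive) for `.wav` files named by
#'   the clip grammar.
#' @return a tibble with columns `path`, `species`, `date`, `duration_ms`,
#'   `spl_db`, `split`.
#' @export
build_manifest <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.wav$", full.names = TRUE))
  rows <- purrr::map(files, function(f) {
    meta <- parse_clip_name(basename(f))
    rec <- read_wave(f)
    tibble::tibble(path = f, species = meta$species, date = meta$date,
                   duration_ms = 1000 * n_samples(rec) / rec$rate)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(path = character(), species = character(),
                          date = as.Date(character()),
                          duration_ms = numeric())
  }
  out$spl_db <- rep(NA_real_, nrow(out))
  out$split <- rep(NA_character_, nrow(out))
  out
}

#' @rdname build_manifest
#' @param manifest a manifest tibble.
#' @param path CSV path; the header is
#'   `path,species,date,duration_ms,spl_db,split`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(is.data.frame(manifest))
  readr::write_csv(manifest, path, na = "")
  invisible(path)
}

#' @rdname build_manifest
#' @export
read_manifest <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      path = readr::col_character(),
      species = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d"),
      duration_ms = readr::col_double(),
      spl_db = readr::col_double(),
      split = readr::col_character()
    )
  )
  tibble::as_tibble(out)
}
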