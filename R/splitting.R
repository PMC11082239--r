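#' Date-disjoint train/validation/test splitting
#'
#' Powerful classifiers can learn to recognize the *recording session*
#' rather than the insect: subtle per-night background structure leaks the
#' label if clips from the same date appear on both sides of a split. The
#' remedy is to split by recording date, so models are validated and
#' tested exclusively on days never seen in training. Within each species,
#' whole date-groups of clips are assigned greedily (largest group first,
#' ties shuffled by the seed) to whichever split is furthest below its
#' target clip count. Species with fewer than `min_dates_per_species`
#' distinct dates cannot be split date-disjointly into three parts; they
#' are assigned entirely to train, with a warning.
#'
#' @param fractions named or unnamed length-3 numeric `(train, val, test)`
#'   summing to 1.
#' @param seed integer seed controlling tie-breaking.
#' @param min_dates_per_species minimum distinct dates a species needs to
#'   be split (default 3, one per subset).
#' @return a `split_spec` list.
#' @export
split_spec <- function(fractions = c(train = 0.70, val = 0.15, test = 0.15),
                       seed = 1L, min_dates_per_species = 3L) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be three positive numbers summing to 1",
         call. = FALSE)
  }
  structure(list(fractions = stats::setNames(fractions,
                                             c("train", "val", "test")),
                 seed = as.integer(seed),
                 min_dates_per_species = as.integer(min_dates_per_species)),
            class = "split_spec")
}

#' @rdname split_spec
#' @param manifest a manifest tibble with `species` and `date` columns.
#' @param spec a `split_spec`.
#' @return `split_by_date()`: the manifest with the `split` column set to
#'   `"train"`, `"val"` or `"test"`.
#' @export
split_by_date <- function(manifest, spec = split_spec()) {
  stopifnot(is.data.frame(manifest), inherits(spec, "split_spec"))
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  if (any(is.na(manifest$date))) {
    stop("every manifest row needs a parseable date", call. = FALSE)
  }
  manifest$split <- NA_character_
  withr::with_seed(spec$seed, {
    for (sp in unique(manifest$species)) {
      idx <- which(manifest$species == sp)
      dates <- manifest$date[idx]
      groups <- table(as.character(dates))
      if (length(groups) < spec$min_dates_per_species) {
        warning("species '", sp, "' has only ", length(groups),
                " distinct recording date(s); assigning all clips to train")
        manifest$split[idx] <- "train"
        next
      }
      assign <- assign_date_groups(groups, spec$fractions)
      manifest$split[idx] <- assign[as.character(dates)]
    }
  })
  manifest
}

# Greedy largest-first assignment of date groups (named counts) to splits,
# balancing clip counts toward the target fractions. Seeded tie shuffling
# comes from the caller's RNG state. Every split is guaranteed at least one
# date-group (feasible because length(groups) >= 3).
assign_date_groups <- function(groups, fractions) {
  counts <- as.numeric(groups)
  names(counts) <- names(groups)
  counts <- counts[sample(length(counts))]     # seeded tie shuffle
  counts <- counts[order(-counts)]             # stable: keeps shuffle order
  total <- sum(counts)
  target <- fractions * total
  got <- c(train = 0, val = 0, test = 0)
  n_groups <- c(train = 0L, val = 0L, test = 0L)
  assign <- character(length(counts))
  names(assign) <- names(counts)
  for (i in seq_along(counts)) {
    deficit <- target - got
    # reserve: every split must end up with >= 1 group
    remaining <- length(counts) - i + 1L
    need <- sum(n_groups == 0L)
    cand <- if (remaining <= need) names(which(n_groups == 0L)) else
      names(deficit)
    pick <- cand[which.max(deficit[cand])]
    assign[i] <- pick
    got[pick] <- got[pick] + counts[i]
    n_groups[pick] <- n_groups[pick] + 1L
  }
  assign
}

#' @rdname split_spec
#' @return `verify_split()`: a tibble listing every `(species, date)` pair
#'   that appears in more than one split; zero rows means the split is
#'   leakage-safe.
#' @export
verify_split <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) == 0L) {
    return(tibble::tibble(species = character(), date = as.Date(character()),
                          splits = character()))
  }
  manifest |>
    dplyr::filter(!is.na(.data$split)) |>
    dplyr::distinct(.data$species, .data$date, .data$split) |>
    dplyr::group_by(.data$species, .data$date) |>
    dplyr::summarise(splits = paste(sort(.data$split), collapse = ","),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::select("species", "date", "splits")
}

# L1 deviation of achieved clip counts from target fractions; used to
# compare the greedy assignment against exhaustive search in tests.
split_imbalance <- function(counts_by_split, fractions, total) {
  sum(abs(counts_by_split - fractions * total))
}
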