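# Shared data model: trial-level and colony-level tables, CSV interchange,
# validation, and derived production components.

TRIAL_REQUIRED <- c("colony_id", "individual_id", "habitat", "assay",
                    "repeat_index", "raw_value")
COLONY_REQUIRED <- c("colony_id", "habitat", "colony_size")
PRODUCTION_COMPONENTS <- c("n_larvae", "pupae_worker", "pupae_male",
                           "pupae_gyne", "winged_gynes", "winged_males")

#' Recompute derived production components
#'
#' `total_production` is all brood plus winged sexuals; `new_workers` is
#' larvae plus worker pupae (all larvae are treated as worker larvae);
#' `new_gynes` is gyne pupae plus winged gynes; `new_males` is male pupae
#' plus winged males. Identities hold exactly (integer arithmetic).
#'
#' @param colonies colony table holding the six brood-count columns.
#' @return `colonies` with the four derived columns replaced.
#' @export
derive_production <- function(colonies) {
  miss <- setdiff(PRODUCTION_COMPONENTS, names(colonies))
  if (length(miss))
    stop_invariant(paste("missing brood-count columns:", paste(miss, collapse = ", ")))
  colonies$total_production <- with(colonies, n_larvae + pupae_worker +
    pupae_male + pupae_gyne + winged_gynes + winged_males)
  colonies$new_workers <- with(colonies, n_larvae + pupae_worker)
  colonies$new_gynes <- with(colonies, pupae_gyne + winged_gynes)
  colonies$new_males <- with(colonies, pupae_male + winged_males)
  colonies
}

fail_row <- function(rows, col, rule) {
  stop_invariant(sprintf("invalid %s in row(s) %s: %s", col,
                         paste(utils::head(rows, 5), collapse = ", "), rule))
}

#' Validate a trial table
#'
#' Checks the trial-table invariants: required columns present, repeat index
#' in 1..3 (or the design's repeat count), non-negative locomotion and
#' exploration values, aggression scores within \[0, 3\], uniqueness of
#' (individual, assay, repeat), and a single colony per individual.
#'
#' @param trials trial table.
#' @param n_repeats repeats per assay in the design (default 3).
#' @return `trials` invisibly if valid; otherwise an error naming the row
#'   and the violated rule.
#' @export
validate_trial_table <- function(trials, n_repeats = 3L) {
  miss <- setdiff(TRIAL_REQUIRED, names(trials))
  if (length(miss))
    stop_invariant(paste("trial table missing column(s):", paste(miss, collapse = ", ")))
  bad <- which(!trials$repeat_index %in% seq_len(n_repeats))
  if (length(bad)) fail_row(bad, "repeat_index", sprintf("repeat_index must be in 1..%d", n_repeats))
  bad <- which(!trials$assay %in% c(TRAITS, "displacement"))
  if (length(bad)) fail_row(bad, "assay", "unknown assay name")
  bad <- which(!trials$habitat %in% c("seminatural", "invaded"))
  if (length(bad)) fail_row(bad, "habitat", "habitat must be seminatural or invaded")
  nonneg <- trials$assay %in% c("activity", "meandering", "exploration")
  bad <- which(nonneg & trials$raw_value < 0)
  if (length(bad)) fail_row(bad, "raw_value", "activity, meandering, exploration must be >= 0")
  agg <- trials$assay == "aggression"
  bad <- which(agg & (trials$raw_value < 0 | trials$raw_value > 3))
  if (length(bad)) fail_row(bad, "raw_value", "aggression must lie in [0,3]")
  key <- paste(trials$individual_id, trials$assay, trials$repeat_index)
  bad <- which(duplicated(key))
  if (length(bad)) fail_row(bad, "key", "(individual_id, assay, repeat_index) must be unique")
  map <- unique(trials[c("individual_id", "colony_id")])
  dup <- map$individual_id[duplicated(map$individual_id)]
  if (length(dup))
    stop_invariant(paste("individual(s) mapped to multiple colonies:",
                         paste(utils::head(dup, 5), collapse = ", ")))
  invisible(trials)
}

#' Validate a colony table
#'
#' Checks non-negative counts, positive displacement times (when present),
#' and the exact derived production identities (when brood counts present).
#'
#' @param colonies colony table.
#' @return `colonies` invisibly if valid.
#' @export
validate_colony_table <- function(colonies) {
  miss <- setdiff(COLONY_REQUIRED, names(colonies))
  if (length(miss))
    stop_invariant(paste("colony table missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(colonies$colony_id))
    stop_invariant("duplicate colony_id")
  count_cols <- intersect(c("colony_size", "n_queens", "myrmica_nests",
                            "allo_nests", PRODUCTION_COMPONENTS), names(colonies))
  for (col in count_cols) {
    bad <- which(colonies[[col]] < 0)
    if (length(bad)) fail_row(bad, col, "counts must be >= 0")
  }
  tcols <- intersect(paste0("displacement_t", 1:3), names(colonies))
  for (col in tcols) {
    bad <- which(colonies[[col]] <= 0)
    if (length(bad)) fail_row(bad, col, "displacement times must be > 0")
  }
  if (all(PRODUCTION_COMPONENTS %in% names(colonies)) &&
      all(c("total_production", "new_workers") %in% names(colonies))) {
    chk <- derive_production(colonies)
    for (col in c("total_production", "new_workers", "new_gynes", "new_males")) {
      bad <- which(chk[[col]] != colonies[[col]])
      if (length(bad)) fail_row(bad, col, "derived production identity violated")
    }
  }
  invisible(colonies)
}

#' Read / write the CSV interchange tables
#'
#' Plain comma-separated files with a header row, `.` decimal separator and
#' no index column. Reading validates all table invariants and preserves
#' row order.
#'
#' @param path file path.
#' @return the validated table.
#' @export
read_trial_table <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trial_table(trials)
  trials
}

#' @rdname read_trial_table
#' @export
read_colony_table <- function(path) {
  colonies <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_colony_table(colonies)
  colonies
}

#' @rdname read_trial_table
#' @param table table to write.
#' @export
write_trial_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_trial_table
#' @export
write_colony_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
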