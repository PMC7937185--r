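# Preprocessing: trait transformations, standardization, complete-case
# filtering, and the collinearity screen for colony covariates.

DEFAULT_TRAIT_POLICY <- c(activity = "identity", meandering = "log1p",
                          exploration = "identity", aggression = "log1p",
                          displacement = "log1p")

#' Transform and standardize trial values
#'
#' Applies the trait transformation policy — natural log of (1 + x) for
#' aggression, meandering and nest displacement (aggression scores include
#' zero, so a plain log is undefined; one consistent rule covers all three),
#' identity for activity and exploration — then standardizes the transformed
#' values to mean 0 and SD 1 within each assay over the rows supplied. The
#' standardization statistics are stored in `attr(, "standardization")` so
#' the scaling set is explicit.
#'
#' @param trials trial table.
#' @param trait_policy named character vector mapping assay name to
#'   `"identity"` or `"log1p"`.
#' @return `trials` with `transformed_value` and `z_value` replaced.
#' @export
transform_and_standardize <- function(trials, trait_policy = DEFAULT_TRAIT_POLICY) {
  if (nrow(trials) == 0L) stop_invariant("empty trial table")
  if (any(!is.finite(trials$raw_value))) stop_invariant("non-finite raw values")
  trials$transformed_value <- trials$raw_value
  stats_tab <- list()
  for (assay in unique(trials$assay)) {
    sel <- trials$assay == assay
    pol <- trait_policy[[assay]] %||% "identity"
    tv <- if (pol == "log1p") log1p(trials$raw_value[sel]) else trials$raw_value[sel]
    m <- mean(tv); s <- stats::sd(tv)
    if (!is.finite(s) || s == 0)
      stop_invariant(sprintf("standardization undefined for %s: zero variance", assay))
    trials$transformed_value[sel] <- tv
    trials$z_value[sel] <- (tv - m) / s
    stats_tab[[assay]] <- c(mean = m, sd = s)
  }
  attr(trials, "standardization") <- stats_tab
  trials
}

#' Standardize continuous colony covariates onto trial rows
#'
#' Centers and scales the continuous covariates (worker size, colony size,
#' nest counts, repeat index) over the rows supplied, and codes habitat as
#' 0 = seminatural, 1 = invaded. One distinct covariate vector per
#' individual-trial is used for scaling, so assays (which share covariates)
#' do not triple-count rows.
#'
#' @param trials trial table carrying `worker_size` per individual or
#'   already-joined covariate columns.
#' @param colonies colony table with `colony_size`, `myrmica_nests`,
#'   `allo_nests`.
#' @param worker_size named vector of head widths by `individual_id`
#'   (optional if `trials$worker_size` exists).
#' @return `trials` with standardized covariate columns `worker_size`,
#'   `colony_size`, `myrmica_nests`, `allo_nests`, `habitat`, `repeat_index`.
#' @export
standardize_covariates <- function(trials, colonies, worker_size = NULL) {
  if (!is.null(worker_size)) trials$worker_size <- worker_size[trials$individual_id]
  if (is.null(trials$worker_size)) stop_invariant("worker_size not available")
  idx <- match(trials$colony_id, colonies$colony_id)
  if (anyNA(idx)) stop_invariant("trial rows reference unknown colonies")
  base <- !duplicated(paste(trials$individual_id, trials$repeat_index))
  zs <- function(x) {
    m <- mean(x[base]); s <- stats::sd(x[base])
    if (s == 0) stop_invariant("standardization undefined: zero-variance covariate")
    (x - m) / s
  }
  trials$colony_size <- zs(colonies$colony_size[idx])
  trials$myrmica_nests <- zs(colonies$myrmica_nests[idx])
  trials$allo_nests <- zs(colonies$allo_nests[idx])
  trials$worker_size <- zs(trials$worker_size)
  trials$repeat_index_z <- zs(trials$repeat_index)
  trials$habitat_code <- as.numeric(trials$habitat == "invaded")
  trials
}

#' Keep only individuals tested in every assay and repeat
#'
#' Retains individuals with exactly `n_repeats` trials in each of the four
#' individual-level assays (the nine-trial rule with three assays scored
#' from locomotion tracking counted as activity + meandering + exploration
#' plus aggression). Individuals missing any trial are dropped whole.
#'
#' @param trials trial table.
#' @param n_repeats repeats required per assay.
#' @return filtered table; counts of retained/dropped individuals per
#'   habitat in `attr(, "retention")`. Warns when nothing survives.
#' @export
filter_complete_cases <- function(trials, n_repeats = 3L) {
  assays <- intersect(TRAITS, unique(trials$assay))
  tab <- table(trials$individual_id, trials$assay)
  complete_ids <- rownames(tab)[apply(tab[, assays, drop = FALSE] == n_repeats, 1, all) &
                                  rowSums(tab) == n_repeats * length(assays)]
  keep <- trials$individual_id %in% complete_ids
  out <- trials[keep, , drop = FALSE]
  hab_by_id <- tapply(trials$habitat, trials$individual_id, function(x) x[1])
  retention <- data.frame(
    habitat = c("seminatural", "invaded"),
    retained = sapply(c("seminatural", "invaded"), function(h)
      sum(hab_by_id[complete_ids] == h)),
    dropped = sapply(c("seminatural", "invaded"), function(h)
      sum(hab_by_id[setdiff(names(hab_by_id), complete_ids)] == h))
  )
  rownames(retention) <- NULL
  if (nrow(out) == 0L) warning("no complete-case individuals remain")
  attr(out, "retention") <- retention
  out
}

#' Spearman collinearity screen for colony covariates
#'
#' Computes all pairwise Spearman rank correlations among the named
#' colony-level variables (average ranks for ties; p-values from the t
#' approximation), flags pairs whose |rho| exceeds the threshold, and
#' recommends retaining a single representative (colony size by
#' convention) for the flagged group.
#'
#' @param colonies colony table (>= 3 rows).
#' @param variables character vector of column names to screen.
#' @param rho_threshold absolute-correlation flag threshold.
#' @return data frame with one row per pair: `rho`, `S` statistic
#'   (`S = (n^3 - n)(1 - rho)/6` without ties), `p`, `flagged`; the
#'   recommendation string is in `attr(, "recommendation")`.
#' @export
collinearity_screen <- function(colonies, variables, rho_threshold = 0.45) {
  if (nrow(colonies) < 3L) stop_invariant("need >= 3 colonies for the screen")
  miss <- setdiff(variables, names(colonies))
  if (length(miss)) stop_invariant(paste("unknown variable(s):", paste(miss, collapse = ", ")))
  pairs <- utils::combn(variables, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- colonies[[pr[1]]]; y <- colonies[[pr[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(c(rho = NA_real_, S = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    c(rho = unname(ct$estimate), S = unname(ct$statistic), p = ct$p.value)
  })
  out <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ], t(res))
  out$flagged <- !is.na(out$rho) & abs(out$rho) > rho_threshold
  flagged_vars <- unique(c(out$var1[out$flagged], out$var2[out$flagged]))
  attr(out, "recommendation") <- if (length(flagged_vars)) {
    keep <- if ("colony_size" %in% flagged_vars) "colony_size" else flagged_vars[1]
    sprintf("correlated group {%s}: retain %s",
            paste(flagged_vars, collapse = ", "), keep)
  } else "no collinearity above threshold"
  out
}
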