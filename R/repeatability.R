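# LMM-based repeatability (intraclass correlation) with parametric
# bootstrap confidence intervals and randomization-test p-values.

quiet_lmer <- function(formula, data) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            check.conv.hess = "ignore",
                            calc.derivs = FALSE)
  suppressWarnings(suppressMessages(lme4::lmer(formula, data = data,
                                               REML = FALSE, control = ctrl)))
}

icc_from_fit <- function(fit) {
  vc <- lme4::VarCorr(fit)
  var_g <- as.numeric(vc[[1]])
  var_e <- attr(vc, "sc")^2
  if (var_g + var_e <= 0) return(0)
  var_g / (var_g + var_e)
}

refit_icc <- function(fit, y) {
  icc_from_fit(suppressWarnings(suppressMessages(lme4::refit(fit, y))))
}

#' Estimate repeatability of a behavioral trait
#'
#' Fits a Gaussian random-intercept LMM by maximum likelihood with the
#' level's grouping factor (colony groups all trials of its workers;
#' individual groups its own repeats) and returns the intraclass
#' correlation `R = sigma2_group / (sigma2_group + sigma2_residual)`.
#' The confidence interval comes from `n_bootstrap` parametric simulations
#' refit under the fitted model (2.5/97.5 percentiles); the p-value from a
#' randomization test permuting group labels, `p = (1 + #\{R_perm >=
#' R_obs\}) / (1 + n_permutations)`. Deterministic given `seed`.
#'
#' @param trials trial table.
#' @param trait assay name to analyse (`z_value` is the response).
#' @param level `"colony"` or `"individual"`.
#' @param n_bootstrap parametric bootstrap replicates (0 skips the CI).
#' @param n_permutations randomization replicates (0 skips the p-value).
#' @param seed integer seed.
#' @param scheme `"observation"` permutes group labels across single
#'   observations; `"block"` permutes colony assignment of whole
#'   individuals (only meaningful for colony-level repeatability).
#' @return object of class `repeatability_estimate`: `trait`, `level`, `R`,
#'   `ci`, `p`, `n_bootstrap`, `n_permutations`, `truncated` (TRUE when a
#'   variance collapsed to the zero boundary).
#' @export
estimate_repeatability <- function(trials, trait, level = c("individual", "colony"),
                                   n_bootstrap = 1000L, n_permutations = 1000L,
                                   seed = 1L, scheme = c("observation", "block")) {
  level <- match.arg(level)
  scheme <- match.arg(scheme)
  data <- trials[trials$assay == trait, , drop = FALSE]
  if (nrow(data) == 0L) stop_invariant(paste("no rows for trait", trait))
  grp <- if (level == "colony") data$colony_id else data$individual_id
  sizes <- table(grp)
  if (all(sizes < 2L)) stop_invariant("degenerate grouping: all groups are singletons")
  if (length(sizes) < 2L) stop_invariant("need >= 2 groups")
  data$.grp <- grp
  fit <- quiet_lmer(z_value ~ 1 + (1 | .grp), data)
  R_obs <- icc_from_fit(fit)
  truncated <- as.numeric(lme4::VarCorr(fit)[[1]]) < 1e-10 ||
    attr(lme4::VarCorr(fit), "sc")^2 < 1e-10

  set.seed(stage_seed(seed, "repeatability"))
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0) {
    sims <- stats::simulate(fit, nsim = n_bootstrap)
    R_boot <- vapply(sims, function(y) refit_icc(fit, y), 0)
    ci <- stats::quantile(R_boot, c(0.025, 0.975), names = FALSE)
  }
  p <- NA_real_
  if (n_permutations > 0) {
    y <- data$z_value
    R_perm <- vapply(seq_len(n_permutations), function(i) {
      yp <- if (scheme == "observation") sample(y) else {
        # permute colony assignment of whole individuals
        ids <- unique(data$individual_id)
        newcol <- sample(tapply(as.character(grp), data$individual_id,
                                function(x) x[1]))
        names(newcol) <- ids
        ord <- order(newcol[data$individual_id])
        y[ord]
      }
      refit_icc(fit, yp)
    }, 0)
    p <- (1 + sum(R_perm >= R_obs)) / (1 + n_permutations)
  }
  structure(list(trait = trait, level = level, R = R_obs,
                 ci = c(lower = ci[1], upper = ci[2]), p = p,
                 n_bootstrap = n_bootstrap, n_permutations = n_permutations,
                 truncated = truncated),
            class = "repeatability_estimate")
}

#' Repeatability for several traits, levels and optional strata
#'
#' @param trials trial table.
#' @param traits assay names.
#' @param levels grouping levels to estimate.
#' @param by optional stratification column (e.g. `"habitat"`).
#' @inheritParams estimate_repeatability
#' @return data frame with one row per trait x level (x stratum).
#' @export
repeatability_table <- function(trials, traits = TRAITS,
                                levels = c("colony", "individual"),
                                by = NULL, n_bootstrap = 1000L,
                                n_permutations = 1000L, seed = 1L) {
  strata <- if (is.null(by)) list(all = trials)
            else split(trials, trials[[by]])
  rows <- list()
  for (s in names(strata)) for (tr in traits) for (lev in levels) {
    est <- estimate_repeatability(strata[[s]], tr, lev,
                                  n_bootstrap = n_bootstrap,
                                  n_permutations = n_permutations, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = s, trait = tr, level = lev, R = est$R,
      ci_lower = est$ci[["lower"]], ci_upper = est$ci[["upper"]], p = est$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
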