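# Fitness-consequence regressions: colony-level negative-binomial GLMs of
# production on behavioral trait means/SDs, individual-level NB GLMMs with
# Gaussian LMM fallback, and information-criterion model selection.

RESPONSE_COLUMNS <- c(total = "total_production", workers = "new_workers",
                      gynes = "new_gynes", males = "new_males")

#' AICc: small-sample corrected Akaike information criterion
#' @param fit fitted model with `logLik` method.
#' @return `AIC + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Colony-level behavioral trait summaries
#'
#' Per-colony mean and SD of each behavioral trait (model-scale values),
#' plus mean and SD of log nest-displacement time when available, each
#' standardized across colonies.
#'
#' @param trials trial table.
#' @param colonies colony table.
#' @return data frame keyed by `colony_id` with columns `mean_<trait>` and
#'   `sd_<trait>`, standardized, plus `habitat`.
#' @export
colony_trait_summaries <- function(trials, colonies) {
  n_ind <- tapply(trials$individual_id, trials$colony_id,
                  function(x) length(unique(x)))
  if (any(n_ind < 2))
    stop_invariant("each colony needs >= 2 individuals so trait SDs are defined")
  out <- data.frame(colony_id = colonies$colony_id, habitat = colonies$habitat,
                    stringsAsFactors = FALSE)
  for (tr in intersect(TRAITS, unique(trials$assay))) {
    sel <- trials$assay == tr
    mns <- tapply(trials$z_value[sel], trials$colony_id[sel], mean)
    sds <- tapply(trials$z_value[sel], trials$colony_id[sel], stats::sd)
    out[[paste0("mean_", tr)]] <- zscore(as.numeric(mns[out$colony_id]))
    out[[paste0("sd_", tr)]] <- zscore(as.numeric(sds[out$colony_id]))
  }
  if (all(paste0("displacement_t", 1:3) %in% names(colonies))) {
    dmat <- log1p(as.matrix(colonies[paste0("displacement_t", 1:3)]))
    out$mean_displacement <- zscore(rowMeans(dmat))
    out$sd_displacement <- zscore(apply(dmat, 1, stats::sd))
  }
  out
}

coef_table <- function(est, se, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(est), estimate = est, se = se,
             lower = est - zq * se, upper = est + zq * se,
             z = est / se,
             p = 2 * stats::pnorm(-abs(est / se)),
             supported = (est - zq * se) > 0 | (est + zq * se) < 0,
             row.names = NULL)
}

pearson_dispersion <- function(fit) {
  sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
}

#' Colony-level production regression
#'
#' Regresses a production component on habitat plus the standardized
#' colony-level means and SDs of the behavioral traits. A Poisson GLM is
#' fitted first; when its Pearson dispersion statistic exceeds
#' `overdispersion_threshold` the model is refitted with a negative-binomial
#' error (ML). Optional bidirectional stepwise AIC selection. The males
#' component is skipped (with a message) when fewer than `min_nonzero`
#' colonies produced males.
#'
#' @param colonies colony table with production counts.
#' @param trials trial table for the behavioral summaries.
#' @param response one of `"total"`, `"workers"`, `"gynes"`, `"males"`.
#' @param selection `"none"` or `"stepwise"`.
#' @param overdispersion_threshold Pearson-dispersion cutoff above which the
#'   negative-binomial family replaces the Poisson.
#' @param min_nonzero minimum colonies with nonzero counts for the males
#'   model.
#' @return object of class `productivity_fit` (or `NULL` for a skipped
#'   males model).
#' @export
fit_colony_production_model <- function(colonies, trials,
                                        response = c("total", "workers", "gynes", "males"),
                                        selection = c("none", "stepwise"),
                                        overdispersion_threshold = 1.5,
                                        min_nonzero = 5L) {
  response <- match.arg(response)
  selection <- match.arg(selection)
  if (nrow(colonies) < 12L) stop_invariant("need >= 12 colonies")
  ycol <- RESPONSE_COLUMNS[[response]]
  if (!ycol %in% names(colonies)) stop_invariant(paste("missing column", ycol))
  if (response == "males" && sum(colonies[[ycol]] > 0) < min_nonzero) {
    message(sprintf("males model skipped: only %d colonies with nonzero males",
                    sum(colonies[[ycol]] > 0)))
    return(NULL)
  }
  dat <- colony_trait_summaries(trials, colonies)
  dat$.y <- colonies[[ycol]][match(dat$colony_id, colonies$colony_id)]
  dat$habitat_code <- as.numeric(dat$habitat == "invaded")
  terms <- c("habitat_code", grep("^(mean|sd)_", names(dat), value = TRUE))
  f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))

  pois <- stats::glm(f, family = stats::poisson(), data = dat)
  overdispersed <- pearson_dispersion(pois) > overdispersion_threshold
  fit <- if (overdispersed) MASS::glm.nb(f, data = dat) else pois
  family <- if (overdispersed) "negative_binomial" else "poisson"

  path <- NULL
  if (selection == "stepwise") {
    sel_fit <- MASS::stepAIC(fit, trace = 0,
                             scope = list(lower = ~habitat_code, upper = f))
    path <- sel_fit$anova
    fit <- sel_fit
  }
  sm <- summary(fit)
  ct <- coef_table(sm$coefficients[, 1], sm$coefficients[, 2])
  structure(list(response = response, scope = "colony", habitat_subset = "all",
                 coefficients = ct, family = family,
                 dispersion = if (family == "negative_binomial") fit$theta else Inf,
                 selection_path = path, model = fit),
            class = "productivity_fit")
}

#' Individual-level production regression
#'
#' Joins the colony's production count to each of its workers'
#' (individual, repeat) rows and regresses it on the trial-level
#' standardized behavioral traits with a random intercept per individual:
#' a negative-binomial GLMM (log link, Laplace-approximation ML). When the
#' NB fit fails to converge the model falls back, with a message, to a
#' Gaussian LMM on the same design.
#'
#' @param trials complete-case trial table.
#' @param colonies colony table with production counts.
#' @param response production component, as in
#'   [fit_colony_production_model()].
#' @param habitat_subset `"all"`, `"seminatural"` or `"invaded"`.
#' @param selection `"none"` or `"all_subsets"` (AICc over fixed-effect
#'   subsets; the random intercept is always retained).
#' @param response_col optional column of `trials` holding a per-(individual,
#'   repeat) count to use as the response instead of a colony production
#'   component (used in recovery checks with [generate_individual_counts()]).
#' @return object of class `productivity_fit`.
#' @export
fit_individual_production_model <- function(trials, colonies = NULL,
                                            response = c("total", "workers", "gynes", "males"),
                                            habitat_subset = c("all", "seminatural", "invaded"),
                                            selection = c("none", "all_subsets"),
                                            response_col = NULL) {
  response <- match.arg(response)
  habitat_subset <- match.arg(habitat_subset)
  selection <- match.arg(selection)
  wide <- multitrait_wide(trials, TRAITS)
  if (habitat_subset != "all") wide <- wide[wide$habitat == habitat_subset, ]
  if (length(unique(wide$individual_id)) < 2L) stop_invariant("need >= 2 individuals")
  if (is.null(response_col)) {
    ycol <- RESPONSE_COLUMNS[[response]]
    if (is.null(colonies) || !ycol %in% names(colonies))
      stop_invariant(paste("missing column", ycol))
    wide$.y <- colonies[[ycol]][match(wide$colony_id, colonies$colony_id)]
  } else {
    if (!response_col %in% names(trials))
      stop_invariant(paste("missing column", response_col))
    val <- stats::setNames(trials[[response_col]],
                           paste(trials$individual_id, trials$repeat_index))
    wide$.y <- val[paste(wide$individual_id, wide$repeat_index)]
  }
  if (stats::var(wide$.y) == 0)
    stop_invariant("degenerate fit: response identical for all rows")
  f <- stats::as.formula(paste(".y ~", paste(TRAITS, collapse = " + "),
                               "+ (1 | individual_id)"))
  fit <- NULL; family <- "negative_binomial"
  fit <- tryCatch({
    m <- glmmTMB::glmmTMB(f, data = wide, family = glmmTMB::nbinom2())
    if (!isTRUE(m$sdr$pdHess)) stop("non-positive-definite Hessian")
    m
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    message("negative-binomial GLMM did not converge; falling back to Gaussian LMM")
    family <- "gaussian"
    fit <- quiet_lmer(f, wide)
  }
  path <- NULL
  if (selection == "all_subsets") {
    sel <- select_by_information_criterion(fit, data = wide, strategy = "all_subsets")
    path <- sel$path
    fit <- sel$model
  }
  ct <- if (family == "gaussian") {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    coef_table(est, se)
  } else {
    sm <- summary(fit)$coefficients$cond
    coef_table(sm[, 1], sm[, 2])
  }
  theta <- if (family == "negative_binomial") glmmTMB::sigma(fit) else Inf
  structure(list(response = response, scope = "individual",
                 habitat_subset = habitat_subset, coefficients = ct,
                 family = family, dispersion = theta, selection_path = path,
                 model = fit),
            class = "productivity_fit")
}

model_fixed_terms <- function(fit) {
  f <- stats::formula(fit)
  tl <- attr(stats::terms(lme4::nobars(f)), "term.labels")
  tl
}

rebuild_formula <- function(fit, terms) {
  f <- stats::formula(fit)
  bars <- lme4::findbars(f)
  rhs <- c(if (length(terms)) terms else "1",
           vapply(bars, function(b) paste0("(", deparse(b), ")"), ""))
  stats::reformulate(rhs, response = as.character(f[[2]]))
}

#' Information-criterion model selection over fixed effects
#'
#' `strategy = "all_subsets"` enumerates every subset of the fitted model's
#' fixed-effect terms (random effects always retained), ranks them by AICc
#' and returns the best (ties broken by fewer parameters);
#' `strategy = "stepwise"` performs bidirectional AIC steps from the full
#' model. The full path of visited models is logged.
#'
#' @param fit fitted full model (`glm`, `glm.nb`, `glmmTMB` or `merMod`).
#' @param data the model data (needed to refit subsets).
#' @param strategy `"all_subsets"` or `"stepwise"`.
#' @param forced terms never dropped (e.g. `"habitat_code"`).
#' @param max_terms refuse all-subsets enumeration above this many
#'   candidate terms unless `force = TRUE`.
#' @param force override the combinatorial guard.
#' @return list: `model` (selected fit), `path` (data frame of visited
#'   models with criterion values), `criterion`.
#' @export
select_by_information_criterion <- function(fit, data = NULL,
                                            strategy = c("all_subsets", "stepwise"),
                                            forced = character(),
                                            max_terms = 20L, force = FALSE) {
  strategy <- match.arg(strategy)
  if (strategy == "stepwise") {
    sel <- MASS::stepAIC(fit, trace = 0)
    return(list(model = sel, path = sel$anova, criterion = "AIC"))
  }
  terms <- model_fixed_terms(fit)
  cand <- setdiff(terms, forced)
  if (length(cand) > max_terms && !force)
    stop_invariant(sprintf("all-subsets over %d terms refused; set force = TRUE",
                           length(cand)))
  if (is.null(data)) data <- stats::model.frame(fit)
  subsets <- lapply(0:(2^length(cand) - 1), function(mask) {
    cand[bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0]
  })
  rows <- list(); fits <- list()
  for (i in seq_along(subsets)) {
    terms_i <- c(forced, subsets[[i]])
    f_i <- rebuild_formula(fit, terms_i)
    fit_i <- tryCatch(
      suppressWarnings(suppressMessages(stats::update(fit, formula = f_i, data = data))),
      error = function(e) NULL)
    if (is.null(fit_i)) next
    fits[[length(fits) + 1L]] <- fit_i
    rows[[length(rows) + 1L]] <- data.frame(
      model = if (length(terms_i)) paste(sort(terms_i), collapse = " + ") else "(intercept)",
      k = attr(stats::logLik(fit_i), "df"),
      aicc = aicc(fit_i))
  }
  path <- do.call(rbind, rows)
  ord <- order(path$aicc, path$k)
  path <- path[ord, ]
  rownames(path) <- NULL
  list(model = fits[[ord[1]]], path = path, criterion = "AICc")
}
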