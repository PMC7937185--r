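# Double hierarchical Gaussian mixed model, fitted by MCMC.
#
# Mean submodel:        y_i = x_i' beta + u_{j(i)} + v_{k(i)} + e_i
# Dispersion submodel:  log sd(e_i) = z_i' gamma + w_{j(i)}
# (u_j, w_j) ~ bivariate Normal(0, Omega); v_k ~ Normal(0, sigma_v^2).
#
# Conjugate Gibbs draws for beta, u, v; adaptive random-walk Metropolis for
# gamma, w and the variance/correlation parameters. Priors: Normal(0, 10^2)
# on beta and gamma, half-Normal(0, 1) on all random-effect SDs, Uniform(-1,
# 1) on the Omega correlation.

#' Specify a double hierarchical model
#'
#' @param response assay name to model (`"activity"`, `"meandering"`,
#'   `"exploration"`, `"aggression"`, or `"displacement"` with
#'   `grouping = "colony_only"`).
#' @param mean_covariates covariate names for the mean submodel.
#' @param dispersion_covariates covariate names for the log-residual-SD
#'   submodel (the trial-number covariate enters the mean model only).
#' @param grouping `"individual_within_colony"` fits individual intercepts on
#'   both submodels plus a colony intercept on the mean; `"colony_only"`
#'   (for the colony-level displacement trait) fits colony intercepts on
#'   both submodels.
#' @param individual_dispersion set `FALSE` to drop the random intercept on
#'   the log residual SD (homogeneous-within-group variance; used for the
#'   LMM-limit check).
#' @param mcmc list: `chains` (>= 2), `iterations`, `burn_in`, `thinning`,
#'   `seed`.
#' @return object of class `dhglm_spec`.
#' @export
dhglm_spec <- function(response,
                       mean_covariates = c("worker_size", "colony_size",
                                           "myrmica_nests", "allo_nests",
                                           "habitat", "repeat_index"),
                       dispersion_covariates = setdiff(mean_covariates, "repeat_index"),
                       grouping = c("individual_within_colony", "colony_only"),
                       individual_dispersion = TRUE,
                       mcmc = list()) {
  grouping <- match.arg(grouping)
  mcmc_def <- list(chains = 4L, iterations = 10000L, burn_in = 5000L,
                   thinning = 5L, seed = 1L)
  mcmc <- utils::modifyList(mcmc_def, mcmc)
  if (mcmc$chains < 2L) stop_invariant("mcmc$chains must be >= 2")
  if (mcmc$burn_in >= mcmc$iterations)
    stop_invariant("mcmc$burn_in must be < mcmc$iterations")
  structure(list(response = response, mean_covariates = mean_covariates,
                 dispersion_covariates = dispersion_covariates,
                 grouping = grouping,
                 individual_dispersion = isTRUE(individual_dispersion),
                 mcmc = mcmc),
            class = "dhglm_spec")
}

resolve_covariate <- function(name) {
  switch(name, habitat = "habitat_code", repeat_index = "repeat_index_z", name)
}

check_standardized <- function(M, names, tol = 0.01) {
  for (nm in names) {
    x <- M[, nm]
    if (all(x %in% c(0, 1))) next  # binary factor codes are exempt
    if (abs(mean(x)) > tol || abs(stats::sd(x) - 1) > tol)
      stop_invariant(sprintf(
        "covariate %s is not standardized (|mean| %.3f, sd %.3f)", nm,
        abs(mean(x)), stats::sd(x)))
  }
}

build_design <- function(data, covariates) {
  cols <- vapply(covariates, resolve_covariate, "")
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop_invariant(paste("missing covariate column(s):",
                                         paste(miss, collapse = ", ")))
  X <- cbind(intercept = 1, as.matrix(data[cols]))
  colnames(X) <- c("intercept", covariates)
  if (qr(X)$rank < ncol(X)) stop_invariant("singular design matrix")
  check_standardized(X, covariates)
  X
}

#' Fit a double hierarchical Gaussian mixed model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler for the mean and
#' dispersion submodels with correlated group intercepts. Identical seeds
#' give identical draws; rows may be supplied in any order.
#'
#' @param trials trial table with standardized covariate columns (see
#'   [standardize_covariates()]) and the model-scale response in `z_value`.
#' @param colonies optional colony table (unused when covariates are already
#'   joined onto `trials`).
#' @param spec a [dhglm_spec()].
#' @return object of class `dhglm_fit`: per-chain draw matrices for all
#'   fixed effects, variance components, the intercept covariance and the
#'   mean/rIIV correlation `r_int_riiv`, plus split R-hat and effective
#'   sample size per parameter.
#' @export
fit_dhglm <- function(trials, colonies = NULL, spec) {
  stopifnot(inherits(spec, "dhglm_spec"))
  data <- trials[trials$assay == spec$response, , drop = FALSE]
  if (nrow(data) == 0L) stop_invariant(paste("no rows for assay", spec$response))
  # stable internal order so results do not depend on input row order
  ord <- order(data$individual_id, data$repeat_index)
  data <- data[ord, , drop = FALSE]

  X <- build_design(data, spec$mean_covariates)
  Z <- build_design(data, spec$dispersion_covariates)
  y <- data$z_value

  if (spec$grouping == "individual_within_colony") {
    g_lab <- sort(unique(data$individual_id))
    g <- match(data$individual_id, g_lab)
    g2_lab <- sort(unique(data$colony_id))
    g2 <- match(data$colony_id, g2_lab)
  } else {
    g_lab <- sort(unique(data$colony_id))
    g <- match(data$colony_id, g_lab)
    g2 <- NULL
  }
  if (min(tabulate(g)) < 2L)
    stop_invariant("every group needs >= 2 repeated observations")

  chains <- lapply(seq_len(spec$mcmc$chains), function(ch) {
    dhglm_chain(y, X, Z, g, g2, mcmc = spec$mcmc,
                include_w = spec$individual_dispersion,
                chain_seed = stage_seed(spec$mcmc$seed, "chain") + 7919L * ch)
  })
  params <- colnames(chains[[1]])
  diag <- data.frame(
    parameter = params,
    rhat = vapply(params, function(p)
      split_rhat(sapply(chains, function(m) m[, p])), 0),
    ess = vapply(params, function(p)
      ess_basic(sapply(chains, function(m) m[, p])), 0),
    row.names = NULL
  )
  structure(list(chains = chains, diagnostics = diag, spec = spec,
                 n = length(y), n_groups = length(g_lab),
                 n_groups2 = if (is.null(g2)) 0L else max(g2),
                 group_labels = g_lab),
            class = "dhglm_fit")
}

# One MCMC chain. Returns a draws matrix (kept iterations x parameters).
dhglm_chain <- function(y, X, Z, g, g2, mcmc, include_w, chain_seed) {
  set.seed(chain_seed %% .Machine$integer.max)
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  J <- max(g); K <- if (is.null(g2)) 0L else max(g2)

  beta <- stats::coef(stats::lm.fit(X, y)) + stats::rnorm(p, 0, 0.05)
  res0 <- y - drop(X %*% beta)
  gamma <- c(log(stats::sd(res0)), rep(0, q - 1)) + stats::rnorm(q, 0, 0.05)
  u <- rep(0, J); w <- rep(0, J)
  v <- if (K) rep(0, K) else NULL
  su <- abs(stats::rnorm(1, 0.4, 0.1)); sw <- abs(stats::rnorm(1, 0.4, 0.1))
  sv <- abs(stats::rnorm(1, 0.4, 0.1)); rho <- 0

  # covariate values per group, where the covariate is group-constant; used
  # by the interweaving translation moves that decouple group-level fixed
  # effects from the random intercepts
  first_g <- match(seq_len(J), g)
  first_g2 <- if (K) match(seq_len(K), g2) else NULL
  const_within <- function(M, grp, firsts) {
    apply(M, 2, function(x) {
      if (all(abs(x - x[firsts][grp]) < 1e-12)) x[firsts] else NULL
    }, simplify = FALSE)
  }
  Xg <- const_within(X, g, first_g)
  Zg <- const_within(Z, g, first_g)
  Xk <- if (K) const_within(X, g2, first_g2) else vector("list", p)

  sc_w <- rep(0.4, J); sc_g <- rep(0.1, q); sc_om <- c(0.2, 0.2, 0.3); sc_v <- 0.2
  sc_txu <- rep(0.3, p); sc_txv <- rep(0.3, p); sc_txw <- rep(0.3, q)
  prior_prec_fix <- 1 / 100
  adapt <- 0.05

  n_iter <- mcmc$iterations; burn <- mcmc$burn_in; thin <- mcmc$thinning
  kept <- floor((n_iter - burn) / thin)
  pn <- c(paste0("beta_", colnames(X)), paste0("gamma_", colnames(Z)),
          "sigma2_id_mu", "sigma2_id_sigma", "cov_mu_sigma", "r_int_riiv",
          if (K) "sigma2_colony")
  draws <- matrix(NA_real_, kept, length(pn), dimnames = list(NULL, pn))
  keep_i <- 0L

  ll_omega <- function(su_, sw_, rho_) {
    q1 <- u / su_; q2 <- w / sw_
    -J * (log(su_) + log(sw_) + 0.5 * log1p(-rho_^2)) -
      sum(q1^2 - 2 * rho_ * q1 * q2 + q2^2) / (2 * (1 - rho_^2))
  }

  for (it in seq_len(n_iter)) {
    in_burn <- it <= burn
    eta <- drop(Z %*% gamma) + if (include_w) w[g] else 0
    W <- exp(-2 * eta)

    # beta | rest (conjugate Gaussian)
    off <- u[g] + if (K) v[g2] else 0
    A <- crossprod(X * W, X); diag(A) <- diag(A) + prior_prec_fix
    b <- crossprod(X * W, y - off)
    L <- chol(A)
    beta <- drop(backsolve(L, backsolve(L, b, transpose = TRUE) + stats::rnorm(p)))
    xb <- drop(X %*% beta)

    # colony intercepts v | rest
    if (K) {
      r <- y - xb - u[g]
      s1 <- as.numeric(rowsum(W * r, g2)); s0 <- as.numeric(rowsum(W, g2))
      prec <- s0 + 1 / sv^2
      v <- s1 / prec + stats::rnorm(K) / sqrt(prec)
    }

    # individual mean intercepts u | rest
    r <- y - xb - if (K) v[g2] else 0
    pv <- if (include_w) su^2 * (1 - rho^2) else su^2
    pm <- if (include_w) rho * (su / sw) * w else 0
    s1 <- as.numeric(rowsum(W * r, g)); s0 <- as.numeric(rowsum(W, g))
    prec <- s0 + 1 / pv
    u <- (s1 + pm / pv) / prec + stats::rnorm(J) / sqrt(prec)

    resid <- r - u[g]
    eta0 <- drop(Z %*% gamma)

    # individual log-SD intercepts w | rest (vectorized random-walk MH)
    if (include_w) {
      ll_cur <- as.numeric(rowsum(stats::dnorm(resid, 0, exp(eta0 + w[g]), log = TRUE), g))
      wp <- w + stats::rnorm(J) * sc_w
      ll_prop <- as.numeric(rowsum(stats::dnorm(resid, 0, exp(eta0 + wp[g]), log = TRUE), g))
      pmw <- rho * (sw / su) * u
      pvw <- sw^2 * (1 - rho^2)
      lpr_cur <- stats::dnorm(w, pmw, sqrt(pvw), log = TRUE)
      lpr_prop <- stats::dnorm(wp, pmw, sqrt(pvw), log = TRUE)
      acc <- log(stats::runif(J)) < (ll_prop - ll_cur + lpr_prop - lpr_cur)
      w[acc] <- wp[acc]
      if (in_burn) sc_w <- pmin(pmax(sc_w * exp(adapt * (acc - 0.44)), 0.01), 5)
    }

    # gamma | rest (componentwise random-walk MH)
    eta <- eta0 + if (include_w) w[g] else 0
    ll_cur <- sum(stats::dnorm(resid, 0, exp(eta), log = TRUE))
    for (l in seq_len(q)) {
      delta <- stats::rnorm(1) * sc_g[l]
      eta_p <- eta + Z[, l] * delta
      ll_p <- sum(stats::dnorm(resid, 0, exp(eta_p), log = TRUE))
      lr <- ll_p - ll_cur +
        stats::dnorm(gamma[l] + delta, 0, 10, log = TRUE) -
        stats::dnorm(gamma[l], 0, 10, log = TRUE)
      acc <- log(stats::runif(1)) < lr
      if (acc) { gamma[l] <- gamma[l] + delta; eta <- eta_p; ll_cur <- ll_p }
      if (in_burn) sc_g[l] <- min(max(sc_g[l] * exp(adapt * ((acc) - 0.44)), 1e-3), 5)
    }

    # Omega: SDs and correlation of the individual intercepts
    if (include_w) {
      # log sigma_u
      lsu_p <- log(su) + stats::rnorm(1) * sc_om[1]
      lr <- ll_omega(exp(lsu_p), sw, rho) - ll_omega(su, sw, rho) +
        stats::dnorm(exp(lsu_p), 0, 1, log = TRUE) - stats::dnorm(su, 0, 1, log = TRUE) +
        lsu_p - log(su)
      acc <- log(stats::runif(1)) < lr
      if (acc) su <- exp(lsu_p)
      if (in_burn) sc_om[1] <- min(max(sc_om[1] * exp(adapt * ((acc) - 0.44)), 1e-3), 3)
      # log sigma_w
      lsw_p <- log(sw) + stats::rnorm(1) * sc_om[2]
      lr <- ll_omega(su, exp(lsw_p), rho) - ll_omega(su, sw, rho) +
        stats::dnorm(exp(lsw_p), 0, 1, log = TRUE) - stats::dnorm(sw, 0, 1, log = TRUE) +
        lsw_p - log(sw)
      acc <- log(stats::runif(1)) < lr
      if (acc) sw <- exp(lsw_p)
      if (in_burn) sc_om[2] <- min(max(sc_om[2] * exp(adapt * ((acc) - 0.44)), 1e-3), 3)
      # atanh rho (uniform prior on rho; Jacobian 1 - rho^2)
      zr_p <- atanh(rho) + stats::rnorm(1) * sc_om[3]
      rho_p <- tanh(zr_p)
      lr <- ll_omega(su, sw, rho_p) - ll_omega(su, sw, rho) +
        log1p(-rho_p^2) - log1p(-rho^2)
      acc <- log(stats::runif(1)) < lr
      if (acc) rho <- rho_p
      if (in_burn) sc_om[3] <- min(max(sc_om[3] * exp(adapt * ((acc) - 0.44)), 1e-3), 3)
    } else {
      lsu_p <- log(su) + stats::rnorm(1) * sc_om[1]
      su_p <- exp(lsu_p)
      lr <- sum(stats::dnorm(u, 0, su_p, log = TRUE)) -
        sum(stats::dnorm(u, 0, su, log = TRUE)) +
        stats::dnorm(su_p, 0, 1, log = TRUE) - stats::dnorm(su, 0, 1, log = TRUE) +
        lsu_p - log(su)
      acc <- log(stats::runif(1)) < lr
      if (acc) su <- su_p
      if (in_burn) sc_om[1] <- min(max(sc_om[1] * exp(adapt * ((acc) - 0.44)), 1e-3), 3)
    }

    # interweaving translation moves: shift a fixed effect and subtract the
    # shift from the group intercepts (likelihood-invariant; Metropolis
    # ratio involves only the priors), which breaks the posterior coupling
    # between group-constant covariates and the random intercepts
    pv_u <- if (include_w) su^2 * (1 - rho^2) else su^2
    pm_u <- if (include_w) rho * (su / sw) * w else 0
    for (l in seq_len(p)) {
      if (!is.null(Xg[[l]])) {
        delta <- stats::rnorm(1) * sc_txu[l]
        lr <- sum(stats::dnorm(u - delta * Xg[[l]], pm_u, sqrt(pv_u), log = TRUE)) -
          sum(stats::dnorm(u, pm_u, sqrt(pv_u), log = TRUE)) +
          stats::dnorm(beta[l] + delta, 0, 10, log = TRUE) -
          stats::dnorm(beta[l], 0, 10, log = TRUE)
        acc <- log(stats::runif(1)) < lr
        if (acc) { beta[l] <- beta[l] + delta; u <- u - delta * Xg[[l]] }
        if (in_burn) sc_txu[l] <- min(max(sc_txu[l] * exp(adapt * ((acc) - 0.44)), 1e-3), 5)
      }
      if (K && !is.null(Xk[[l]])) {
        delta <- stats::rnorm(1) * sc_txv[l]
        lr <- sum(stats::dnorm(v - delta * Xk[[l]], 0, sv, log = TRUE)) -
          sum(stats::dnorm(v, 0, sv, log = TRUE)) +
          stats::dnorm(beta[l] + delta, 0, 10, log = TRUE) -
          stats::dnorm(beta[l], 0, 10, log = TRUE)
        acc <- log(stats::runif(1)) < lr
        if (acc) { beta[l] <- beta[l] + delta; v <- v - delta * Xk[[l]] }
        if (in_burn) sc_txv[l] <- min(max(sc_txv[l] * exp(adapt * ((acc) - 0.44)), 1e-3), 5)
      }
    }
    if (include_w) {
      pv_w <- sw^2 * (1 - rho^2)
      pm_w <- rho * (sw / su) * u
      for (l in seq_len(q)) {
        if (is.null(Zg[[l]])) next
        delta <- stats::rnorm(1) * sc_txw[l]
        lr <- sum(stats::dnorm(w - delta * Zg[[l]], pm_w, sqrt(pv_w), log = TRUE)) -
          sum(stats::dnorm(w, pm_w, sqrt(pv_w), log = TRUE)) +
          stats::dnorm(gamma[l] + delta, 0, 10, log = TRUE) -
          stats::dnorm(gamma[l], 0, 10, log = TRUE)
        acc <- log(stats::runif(1)) < lr
        if (acc) { gamma[l] <- gamma[l] + delta; w <- w - delta * Zg[[l]] }
        if (in_burn) sc_txw[l] <- min(max(sc_txw[l] * exp(adapt * ((acc) - 0.44)), 1e-3), 5)
      }
    }

    # sigma_v
    if (K) {
      lsv_p <- log(sv) + stats::rnorm(1) * sc_v
      sv_p <- exp(lsv_p)
      lr <- sum(stats::dnorm(v, 0, sv_p, log = TRUE)) -
        sum(stats::dnorm(v, 0, sv, log = TRUE)) +
        stats::dnorm(sv_p, 0, 1, log = TRUE) - stats::dnorm(sv, 0, 1, log = TRUE) +
        lsv_p - log(sv)
      acc <- log(stats::runif(1)) < lr
      if (acc) sv <- sv_p
      if (in_burn) sc_v <- min(max(sc_v * exp(adapt * ((acc) - 0.44)), 1e-3), 3)
    }

    if (!in_burn && (it - burn) %% thin == 0L) {
      keep_i <- keep_i + 1L
      draws[keep_i, ] <- c(beta, gamma, su^2,
                           if (include_w) sw^2 else 0,
                           if (include_w) rho * su * sw else 0,
                           if (include_w) rho else 0,
                           if (K) sv^2)
    }
  }
  draws[seq_len(keep_i), , drop = FALSE]
}

#' Pool posterior draws across chains
#' @param fit a `dhglm_fit`.
#' @return matrix of pooled draws.
#' @export
pooled_draws <- function(fit) do.call(rbind, fit$chains)

#' Summarize a DHGLM fit
#'
#' Posterior means, equal-tailed credible intervals, and a support flag per
#' parameter: for location/dispersion effects the CrI excludes zero; for
#' variance components the lower CrI bound exceeds `variance_floor`.
#' Warns (refusing a clean bill) when any split R-hat exceeds 1.1 or any
#' effective sample size is below 200, unless `force = TRUE`.
#'
#' @param fit a `dhglm_fit`.
#' @param level credible level (default 0.95).
#' @param variance_floor support threshold for variance components.
#' @param force skip the diagnostics gate.
#' @return data frame: parameter, mean, lower, upper, supported.
#' @export
summarize_fit <- function(fit, level = 0.95, variance_floor = 0.01, force = FALSE) {
  draws <- pooled_draws(fit)
  if (nrow(draws) == 0L) stop_invariant("empty sample store")
  if (!force) {
    bad <- fit$diagnostics$rhat > 1.1 | fit$diagnostics$ess < 200
    if (any(bad, na.rm = TRUE))
      warning(sprintf("convergence diagnostics failed for: %s",
                      paste(fit$diagnostics$parameter[which(bad)], collapse = ", ")))
  }
  is_var <- grepl("^sigma2_", colnames(draws))
  out <- data.frame(parameter = colnames(draws), t(apply(draws, 2, post_summary, level)))
  names(out)[2:4] <- c("mean", "lower", "upper")
  out$supported <- ifelse(is_var, out$lower > variance_floor,
                          out$lower > 0 | out$upper < 0)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test for a random intercept
#'
#' Fits the homogeneous-residual Gaussian LMM by maximum likelihood with and
#' without the named random intercept and compares them by likelihood ratio.
#' The null value of a variance sits on the boundary of the parameter space,
#' so the p-value uses the 50:50 mixture of a point mass at zero and a
#' chi-squared with 1 df.
#'
#' @param trials trial table with standardized covariates.
#' @param spec a [dhglm_spec()] (mean covariates and response are used).
#' @param term `"individual"` or `"colony"`.
#' @return list with `chi2`, `df`, `p`.
#' @export
random_intercept_lrt <- function(trials, spec, term = c("individual", "colony")) {
  term <- match.arg(term)
  if (spec$grouping == "colony_only" && term == "individual")
    stop_invariant("individual term is not in the colony-only model")
  data <- trials[trials$assay == spec$response, , drop = FALSE]
  cols <- vapply(spec$mean_covariates, resolve_covariate, "")
  fx <- if (length(cols)) paste(cols, collapse = " + ") else "1"
  re_full <- if (spec$grouping == "colony_only") "(1 | colony_id)"
             else "(1 | individual_id) + (1 | colony_id)"
  drop_re <- switch(term, individual = "(1 | individual_id)", colony = "(1 | colony_id)")
  if (!grepl(drop_re, re_full, fixed = TRUE))
    stop_invariant(sprintf("term %s is not in the model", term))
  re_red <- setdiff(strsplit(re_full, " \\+ ")[[1]], drop_re)
  f_full <- stats::as.formula(paste("z_value ~", fx, "+", re_full))
  m_full <- lme4::lmer(f_full, data = data, REML = FALSE)
  ll_full <- as.numeric(stats::logLik(m_full))
  if (length(re_red)) {
    f_red <- stats::as.formula(paste("z_value ~", fx, "+", paste(re_red, collapse = " + ")))
    m_red <- lme4::lmer(f_red, data = data, REML = FALSE)
  } else {
    f_red <- stats::as.formula(paste("z_value ~", fx))
    m_red <- stats::lm(f_red, data = data)
  }
  chi2 <- max(0, 2 * (ll_full - as.numeric(stats::logLik(m_red))))
  p <- 0.5 * stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, df = 1, p = p)
}
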