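# Multivariate Gaussian mixed models over behavioral traits, with
# decomposition of trait-trait covariance into among-colony,
# among-individual and residual correlation matrices (behavioral syndromes).
#
# Conjugate Gibbs sampler: matrix-normal draws for fixed effects and random
# effect matrices, inverse-Wishart draws for each covariance matrix with
# prior IW(p + 1, I), whose implied marginal distribution on every
# correlation is uniform on (-1, 1).

riwish <- function(nu, S) {
  W <- stats::rWishart(1, df = nu, Sigma = solve(S))[, , 1]
  solve(W)
}

# Reshape a long trial table into one multivariate row per (individual,
# repeat); optionally appends colony-level displacement rows (other traits
# missing) built from the displacement columns of the colony table.
multitrait_wide <- function(trials, traits, colonies = NULL,
                            include_displacement = FALSE) {
  base_traits <- setdiff(traits, "displacement")
  sub <- trials[trials$assay %in% base_traits, ]
  key <- unique(sub[c("individual_id", "colony_id", "habitat", "repeat_index")])
  Y <- matrix(NA_real_, nrow(key), length(traits), dimnames = list(NULL, traits))
  for (tr in base_traits) {
    s <- sub[sub$assay == tr, ]
    idx <- match(paste(key$individual_id, key$repeat_index),
                 paste(s$individual_id, s$repeat_index))
    Y[, tr] <- s$z_value[idx]
  }
  wide <- data.frame(key, Y, check.names = FALSE)
  if (include_displacement) {
    if (is.null(colonies) || !all(paste0("displacement_t", 1:3) %in% names(colonies)))
      stop_invariant("displacement columns missing from colony table")
    dmat <- log1p(as.matrix(colonies[paste0("displacement_t", 1:3)]))
    dz <- (dmat - mean(dmat)) / stats::sd(dmat)
    drows <- data.frame(
      individual_id = paste0(rep(colonies$colony_id, 3), "_disp"),
      colony_id = rep(colonies$colony_id, 3),
      habitat = rep(colonies$habitat, 3),
      repeat_index = rep(1:3, each = nrow(colonies))
    )
    Yd <- matrix(NA_real_, nrow(drows), length(traits), dimnames = list(NULL, traits))
    Yd[, "displacement"] <- as.numeric(dz)
    wide <- rbind(wide, data.frame(drows, Yd, check.names = FALSE))
  }
  wide
}

#' Fit a multivariate mixed model over behavioral traits
#'
#' Traits are stacked as a multivariate Gaussian response per
#' (individual, repeat) row, with habitat as the fixed explanatory factor
#' and random intercept vectors for colony and (optionally) individual,
#' each with its own unstructured covariance matrix, plus a residual
#' covariance matrix. Supports the four-trait model (colony + individual
#' random effects, complete rows required) and the five-trait model
#' (colony random effect only, with colony-level nest-displacement rows
#' carrying missing values for the individual traits; missing entries are
#' imputed by data augmentation within the Gibbs sampler).
#'
#' @param trials trial table (standardized, complete cases for the
#'   four-trait form).
#' @param colonies colony table; required when `"displacement"` is among
#'   `traits`.
#' @param traits character vector (>= 2) of trait names.
#' @param random_levels `c("colony", "individual")` or `"colony"`.
#' @param mcmc list: `chains`, `iterations`, `burn_in`, `thinning`, `seed`.
#' @return object of class `syndrome_fit` with per-level covariance draw
#'   arrays (`iterations x p x p`), fixed-effect draws (habitat effect per
#'   trait), and convergence diagnostics for every covariance element.
#' @export
fit_multitrait_model <- function(trials, colonies = NULL, traits = TRAITS,
                                 random_levels = c("colony", "individual"),
                                 mcmc = list()) {
  if (length(traits) < 2L) stop_invariant("need at least 2 traits")
  mcmc_def <- list(chains = 2L, iterations = 20000L, burn_in = 5000L,
                   thinning = 10L, seed = 1L)
  mcmc <- utils::modifyList(mcmc_def, mcmc)
  use_ind <- "individual" %in% random_levels
  wide <- multitrait_wide(trials, traits, colonies,
                          include_displacement = "displacement" %in% traits)
  Y <- as.matrix(wide[traits])
  if (use_ind && anyNA(Y))
    stop_invariant(paste("unbalanced trait availability: some individuals miss",
                         "a trait; run filter_complete_cases() first"))
  X <- cbind(intercept = 1, habitat = as.numeric(wide$habitat == "invaded"))
  col_lab <- sort(unique(wide$colony_id))
  kcol <- match(wide$colony_id, col_lab)
  ind_lab <- sort(unique(wide$individual_id))
  jind <- match(wide$individual_id, ind_lab)

  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    syndrome_chain(Y, X, kcol, if (use_ind) jind else NULL, mcmc,
                   chain_seed = stage_seed(mcmc$seed, "syndrome") + 104729L * ch)
  })

  levels_present <- c("colony", if (use_ind) "individual", "residual")
  combine <- function(name) {
    arrs <- lapply(chains, `[[`, name)
    do.call(abind_first, arrs)
  }
  out <- list(
    traits = traits,
    levels = stats::setNames(lapply(paste0("Sigma_", levels_present), combine),
                             levels_present),
    fixed = do.call(rbind, lapply(chains, `[[`, "B_habitat")),
    chains = length(chains),
    diagnostics = NULL
  )
  # split R-hat / ESS on each distinct covariance element, per level
  diags <- list()
  for (lev in levels_present) {
    arrs <- lapply(chains, `[[`, paste0("Sigma_", lev))
    p <- length(traits)
    for (a in seq_len(p)) for (b in seq_len(a)) {
      cols <- sapply(arrs, function(x) x[, a, b])
      diags[[length(diags) + 1L]] <- data.frame(
        parameter = sprintf("%s:%s-%s", lev, traits[a], traits[b]),
        rhat = split_rhat(cols), ess = ess_basic(cols))
    }
  }
  out$diagnostics <- do.call(rbind, diags)
  class(out) <- "syndrome_fit"
  out
}

abind_first <- function(...) {
  arrs <- list(...)
  p <- dim(arrs[[1]])[2]
  total <- sum(sapply(arrs, function(a) dim(a)[1]))
  out <- array(NA_real_, c(total, p, p), dimnames = dimnames(arrs[[1]]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

syndrome_chain <- function(Y, X, kcol, jind, mcmc, chain_seed) {
  set.seed(chain_seed %% .Machine$integer.max)
  n <- nrow(Y); p <- ncol(Y); px <- ncol(X)
  K <- max(kcol); J <- if (is.null(jind)) 0L else max(jind)
  nu0 <- p + 1
  miss <- is.na(Y)
  patterns <- if (any(miss)) {
    pat_id <- apply(miss, 1, function(m) paste(as.integer(m), collapse = ""))
    split(seq_len(n), pat_id)
  } else NULL
  Y[miss] <- 0

  B <- matrix(0, px, p)
  C <- matrix(0, K, p)
  U <- if (J) matrix(0, J, p) else NULL
  Sc <- Su <- Se <- diag(p)
  XtX <- crossprod(X)
  nk <- tabulate(kcol, K)
  nj <- if (J) tabulate(jind, J) else NULL

  n_iter <- mcmc$iterations; burn <- mcmc$burn_in; thin <- mcmc$thinning
  kept <- floor((n_iter - burn) / thin)
  dn <- list(NULL, colnames(Y), colnames(Y))
  store <- list(Sigma_colony = array(NA_real_, c(kept, p, p), dn),
                Sigma_residual = array(NA_real_, c(kept, p, p), dn),
                B_habitat = matrix(NA_real_, kept, p,
                                   dimnames = list(NULL, colnames(Y))))
  if (J) store$Sigma_individual <- array(NA_real_, c(kept, p, p), dn)
  keep_i <- 0L

  draw_effects <- function(R, grp, ngrp, counts, Sprior_inv, Se_inv) {
    # Conjugate multivariate-normal draws for a block of random intercepts.
    sums <- rowsum(R, grp)
    out <- matrix(0, ngrp, p)
    for (cnt in unique(counts)) {
      prec <- cnt * Se_inv + Sprior_inv
      ch <- chol(prec)
      rows <- which(counts == cnt)
      mu <- t(backsolve(ch, backsolve(ch, t(sums[rows, , drop = FALSE] %*% Se_inv),
                                      transpose = TRUE)))
      z <- matrix(stats::rnorm(length(rows) * p), length(rows), p)
      out[rows, ] <- mu + t(backsolve(ch, t(z)))
    }
    out
  }

  for (it in seq_len(n_iter)) {
    mu_fix <- X %*% B
    mu_all <- mu_fix + C[kcol, , drop = FALSE] +
      if (J) U[jind, , drop = FALSE] else 0

    # impute missing responses from their conditional normal
    if (!is.null(patterns)) {
      for (pid in names(patterns)) {
        m <- as.logical(as.integer(strsplit(pid, "")[[1]]))
        if (!any(m)) next
        rows <- patterns[[pid]]
        if (all(m)) {
          Y[rows, ] <- mu_all[rows, ] +
            matrix(stats::rnorm(length(rows) * p), ncol = p) %*% chol(Se)
          next
        }
        Soo <- Se[!m, !m, drop = FALSE]; Smo <- Se[m, !m, drop = FALSE]
        Smm <- Se[m, m, drop = FALSE]
        A <- Smo %*% solve(Soo)
        Schur <- Smm - A %*% t(Smo)
        dev <- Y[rows, !m, drop = FALSE] - mu_all[rows, !m, drop = FALSE]
        cond_mu <- mu_all[rows, m, drop = FALSE] + dev %*% t(A)
        Y[rows, m] <- cond_mu +
          matrix(stats::rnorm(length(rows) * sum(m)), ncol = sum(m)) %*%
            chol(Schur)
      }
    }

    Se_inv <- solve(Se)
    # fixed effects
    R <- Y - C[kcol, , drop = FALSE] - if (J) U[jind, , drop = FALSE] else 0
    A <- kronecker(Se_inv, XtX)
    diag(A) <- diag(A) + 1 / 100
    b <- as.numeric(crossprod(X, R) %*% Se_inv)
    ch <- chol(A)
    vb <- backsolve(ch, backsolve(ch, b, transpose = TRUE) +
                      stats::rnorm(px * p))
    B <- matrix(vb, px, p)
    mu_fix <- X %*% B

    # colony intercepts
    R <- Y - mu_fix - if (J) U[jind, , drop = FALSE] else 0
    C <- draw_effects(R, kcol, K, nk, solve(Sc), Se_inv)
    # individual intercepts
    if (J) {
      R <- Y - mu_fix - C[kcol, , drop = FALSE]
      U <- draw_effects(R, jind, J, nj, solve(Su), Se_inv)
    }

    # covariance matrices
    Sc <- riwish(nu0 + K, diag(p) + crossprod(C))
    if (J) Su <- riwish(nu0 + J, diag(p) + crossprod(U))
    E <- Y - mu_fix - C[kcol, , drop = FALSE] - if (J) U[jind, , drop = FALSE] else 0
    Se <- riwish(nu0 + n, diag(p) + crossprod(E))

    if (it > burn && (it - burn) %% thin == 0L) {
      keep_i <- keep_i + 1L
      store$Sigma_colony[keep_i, , ] <- Sc
      if (J) store$Sigma_individual[keep_i, , ] <- Su
      store$Sigma_residual[keep_i, , ] <- Se
      store$B_habitat[keep_i, ] <- B[2, ]
    }
  }
  store
}

#' Decompose covariance draws into correlation summaries
#'
#' Converts each posterior covariance draw to a correlation matrix
#' (`cov / sqrt(var * var)`), then summarizes per trait pair: posterior
#' mean, equal-tailed credible interval, and a support flag (CrI excludes
#' zero). Draws with a zero variance are dropped and counted.
#'
#' @param cov_draws array of draws, `iterations x p x p`.
#' @param level credible level.
#' @return list of class `level_correlations`: `matrix` (posterior-mean
#'   correlations), `cri` (per-pair bounds), `supported`, `n_dropped`.
#' @export
decompose_correlations <- function(cov_draws, level = 0.95) {
  p <- dim(cov_draws)[2]
  traits <- dimnames(cov_draws)[[2]] %||% paste0("trait", seq_len(p))
  vars <- sapply(seq_len(p), function(a) cov_draws[, a, a])
  vars <- matrix(vars, ncol = p)
  ok <- rowSums(vars <= 0) == 0
  n_dropped <- sum(!ok)
  draws <- cov_draws[ok, , , drop = FALSE]
  nd <- dim(draws)[1]
  if (nd == 0L) stop_invariant("no usable covariance draws")
  corr_mean <- matrix(1, p, p, dimnames = list(traits, traits))
  cri <- list(); supported <- matrix(FALSE, p, p, dimnames = list(traits, traits))
  for (a in seq_len(p)) for (b in seq_len(p)) {
    if (a == b) next
    r <- draws[, a, b] / sqrt(draws[, a, a] * draws[, b, b])
    s <- post_summary(r, level)
    corr_mean[a, b] <- s["mean"]
    supported[a, b] <- s["lower"] > 0 || s["upper"] < 0
    if (a > b)
      cri[[paste(traits[b], traits[a], sep = "-")]] <-
        c(mean = unname(s["mean"]), lower = unname(s["lower"]),
          upper = unname(s["upper"]))
  }
  structure(list(matrix = corr_mean, cri = cri, supported = supported,
                 n_dropped = n_dropped, level = level),
            class = "level_correlations")
}

#' Correlation decomposition for every level of a syndrome fit
#' @param fit a `syndrome_fit`.
#' @param level credible level.
#' @return named list of [decompose_correlations()] results.
#' @export
syndrome_correlations <- function(fit, level = 0.95) {
  lapply(fit$levels, decompose_correlations, level = level)
}

#' Posterior sign probability (pMCMC) for a fixed effect
#'
#' `pMCMC = 2 * min(P(draw > 0), P(draw < 0))`, capped at 1 and bounded
#' below by `2 / (n + 1)` so an effect never gets an exact zero p-value
#' from a finite sample.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param level credible level for the interval.
#' @return list: `effect` (posterior mean), `cri`, `pmcmc`.
#' @export
fixed_effect_pmcmc <- function(draws, level = 0.95) {
  if (length(draws) == 0L) stop_invariant("empty draws")
  if (length(draws) < 100L) stop_invariant("need >= 100 draws for pMCMC")
  n <- length(draws)
  tail_p <- max(min(mean(draws > 0), mean(draws < 0)), 1 / (n + 1))
  s <- post_summary(draws, level)
  list(effect = unname(s["mean"]),
       cri = c(lower = unname(s["lower"]), upper = unname(s["upper"])),
       pmcmc = min(1, 2 * tail_p))
}
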