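# Hierarchical synthetic-data generator: colonies -> focal workers ->
# repeated behavioral trials, plus colony-level nest displacement and
# negative-binomial productivity outcomes. Every random-effect draw is kept
# in a truth side-table so estimators can be checked by parameter recovery.

rtrunc_pois <- function(n, lambda, range) {
  x <- stats::rpois(n, lambda)
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- stats::rpois(sum(bad), lambda)
    bad <- x < range[1] | x > range[2]
  }
  x
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop_invariant("standardization undefined: zero-variance column")
  (x - mean(x)) / s
}

to_raw <- function(z_latent, scale) {
  tr <- z_latent * scale$sd + scale$mean
  raw <- if (scale$transform == "log1p") expm1(tr) else tr
  pmax(raw, 0)
}

# Draw correlated per-trait individual intercepts on the mean (u) and
# log-residual-SD (w) scale. u vectors follow the individual-level trait
# correlation matrix; each w_t is built from its own trait's u_t with the
# configured within-trait correlation plus independent innovation, which
# keeps the joint distribution positive definite by construction.
draw_individual_effects <- function(n, cfg) {
  p <- length(TRAITS)
  sd_u <- sqrt(cfg$sigma2_id_mu)
  sd_w <- sqrt(cfg$sigma2_id_sigma)
  r <- ifelse(sd_u * sd_w > 0, cfg$cov_mu_sigma / (sd_u * sd_w), 0)
  R <- cfg$level_correlation_matrices$individual
  Su <- diag(sd_u, p) %*% R %*% diag(sd_u, p)
  u <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Su)
  eps <- matrix(stats::rnorm(n * p), n, p)
  w <- matrix(0, n, p)
  for (t in seq_len(p)) {
    w[, t] <- if (sd_u[t] > 0) {
      r[t] * (sd_w[t] / sd_u[t]) * u[, t] + sd_w[t] * sqrt(1 - r[t]^2) * eps[, t]
    } else sd_w[t] * eps[, t]
  }
  colnames(u) <- colnames(w) <- TRAITS
  list(u = u, w = w)
}

#' Generate a full hierarchical behavioral dataset
#'
#' Simulates the complete study design: colonies with habitat labels and
#' covariates (colony size log-uniform over the configured range, truncated
#' Poisson nest densities, queen counts), focal workers with head widths,
#' and repeated behavioral trials for the four individual-level assays.
#' Each trait follows a double hierarchical Gaussian model on the
#' standardized latent scale: the trial mean combines fixed covariate
#' effects, a colony intercept and an individual intercept, while the
#' residual SD is `exp()` of its own linear predictor plus an individual
#' log-SD intercept correlated with the mean intercept. Trait deviations at
#' the colony, individual and residual level follow the configured per-level
#' correlation matrices.
#'
#' @param config a [sim_config()] object.
#' @return list with `trials` (one row per individual x assay x repeat, raw,
#'   transformed and latent model-scale values plus standardized covariates),
#'   `colonies` (per-colony covariates), and `truth` (realized colony and
#'   individual random effects, one list element per level).
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "dataset"))
  cfg <- config
  n_col <- sum(cfg$n_colonies_per_habitat)
  K <- n_col; J <- K * cfg$n_workers_per_colony; R <- cfg$n_repeats_per_assay
  p <- length(TRAITS)

  colony_id <- sprintf("C%02d", seq_len(K))
  habitat <- rep(c("seminatural", "invaded"), cfg$n_colonies_per_habitat)
  lsz <- stats::runif(K, log(cfg$colony_size_range[1]), log(cfg$colony_size_range[2]))
  colony_size <- pmin(pmax(round(exp(lsz)), cfg$colony_size_range[1]),
                      cfg$colony_size_range[2])
  myrmica_nests <- rtrunc_pois(K, 1.5, cfg$myrmica_nest_range)
  allo_nests <- rtrunc_pois(K, 1.2, cfg$allo_nest_range)
  n_queens <- 1L + stats::rpois(K, 1 + colony_size / 800)

  worker_colony <- rep(seq_len(K), each = cfg$n_workers_per_colony)
  individual_id <- sprintf("%s_W%02d", colony_id[worker_colony],
                           rep(seq_len(cfg$n_workers_per_colony), times = K))
  worker_size <- pmax(stats::rnorm(J, cfg$worker_size_mean, cfg$worker_size_sd), 1)

  colonies <- data.frame(
    colony_id = colony_id, habitat = habitat, colony_size = colony_size,
    n_queens = n_queens, myrmica_nests = myrmica_nests, allo_nests = allo_nests,
    mean_worker_size = as.numeric(tapply(worker_size, worker_colony, mean)),
    stringsAsFactors = FALSE
  )

  # Random effects
  sd_c <- sqrt(cfg$sigma2_colony)
  Sc <- diag(sd_c, p) %*% cfg$level_correlation_matrices$colony %*% diag(sd_c, p)
  c_eff <- MASS::mvrnorm(K, mu = rep(0, p), Sigma = Sc)
  colnames(c_eff) <- TRAITS
  id_eff <- draw_individual_effects(J, cfg)

  # Trial grid: one multivariate row per (worker, repeat); assays are then
  # stacked long, sharing the row's residual correlation across traits.
  grid <- data.frame(
    worker = rep(seq_len(J), each = R),
    repeat_index = rep(seq_len(R), times = J)
  )
  grid$colony <- worker_colony[grid$worker]
  n <- nrow(grid)

  covz <- data.frame(
    intercept = 1,
    worker_size = zscore(worker_size[grid$worker]),
    colony_size = zscore(colony_size[grid$colony]),
    myrmica_nests = zscore(myrmica_nests[grid$colony]),
    allo_nests = zscore(allo_nests[grid$colony]),
    habitat = as.numeric(habitat[grid$colony] == "invaded"),
    repeat_index = zscore(grid$repeat_index)
  )
  Xmean <- as.matrix(covz[MEAN_COVARIATES])
  Xdisp <- as.matrix(covz[DISP_COVARIATES])
  covcols <- covz[-1]
  names(covcols) <- c("worker_size", "colony_size", "myrmica_nests",
                      "allo_nests", "habitat_code", "repeat_index_z")

  e_std <- MASS::mvrnorm(n, mu = rep(0, p),
                         Sigma = cfg$level_correlation_matrices$residual)
  trials_list <- vector("list", p)
  for (t in seq_len(p)) {
    trait <- TRAITS[t]
    mu <- drop(Xmean %*% cfg$beta[, t]) + id_eff$u[grid$worker, t] +
      c_eff[grid$colony, t]
    log_sd <- drop(Xdisp %*% cfg$gamma[, t]) + id_eff$w[grid$worker, t]
    z <- mu + exp(log_sd) * e_std[, t]
    raw <- to_raw(z, cfg$trait_scales[[trait]])
    if (trait == "aggression") {
      raw <- pmin(raw, 3)
      if (cfg$discretize_aggression)
        raw <- pmin(pmax(round(raw), 0), 3)
    }
    tr <- if (cfg$trait_scales[[trait]]$transform == "log1p") log1p(raw)
          else raw
    trials_list[[t]] <- data.frame(
      colony_id = colony_id[grid$colony],
      individual_id = individual_id[grid$worker],
      habitat = habitat[grid$colony],
      assay = trait,
      repeat_index = grid$repeat_index,
      raw_value = raw,
      transformed_value = tr,
      z_value = z,
      covcols,
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, trials_list)
  rownames(trials) <- NULL

  truth <- list(
    colony = data.frame(colony_id = colony_id, level = "colony",
                        c_eff, check.names = FALSE),
    individual = data.frame(
      individual_id = individual_id, colony_id = colony_id[worker_colony],
      stats::setNames(as.data.frame(id_eff$u), paste0("u_", TRAITS)),
      stats::setNames(as.data.frame(id_eff$w), paste0("w_", TRAITS))
    )
  )
  list(trials = trials, colonies = colonies, truth = truth)
}

#' Simulate colony-level nest-displacement assays
#'
#' Adds three positive displacement times (seconds until the last larva is
#' carried into the new nest chamber) per colony, generated from a
#' colony-level double hierarchical model: colony intercepts on the mean and
#' on the log residual SD, drawn jointly with the configured covariance, and
#' covariate effects of mean worker head width, colony size, nest densities,
#' habitat and trial number. Times are generated on the log scale, so they
#' are positive by construction.
#'
#' @param config a [sim_config()] object.
#' @param colonies colony table from [generate_dataset()].
#' @return `colonies` with columns `displacement_t1..t3` (raw seconds) and
#'   `displacement_z1..z3` (latent model scale); realized colony effects are
#'   attached as `attr(, "truth_displacement")`.
#' @export
generate_nest_displacement <- function(config, colonies) {
  validate_sim_config(config)
  need <- c("colony_id", "habitat", "colony_size", "myrmica_nests",
            "allo_nests", "mean_worker_size")
  miss <- setdiff(need, names(colonies))
  if (length(miss) || nrow(colonies) == 0L)
    stop_invariant(paste("colonies table missing:", paste(miss, collapse = ", ")))
  set.seed(stage_seed(config$seed, "displacement"))
  d <- config$displacement
  K <- nrow(colonies); R <- config$n_repeats_per_assay

  sd_m <- sqrt(d$sigma2_mu); sd_s <- sqrt(d$sigma2_sigma)
  r <- if (sd_m * sd_s > 0) d$cov_mu_sigma / (sd_m * sd_s) else 0
  m_k <- stats::rnorm(K, 0, sd_m)
  s_k <- if (sd_m > 0) {
    r * (sd_s / sd_m) * m_k + sd_s * sqrt(1 - r^2) * stats::rnorm(K)
  } else sd_s * stats::rnorm(K)

  grid_col <- rep(seq_len(K), each = R)
  covz <- cbind(
    intercept = 1,
    worker_size = zscore(colonies$mean_worker_size)[grid_col],
    colony_size = zscore(colonies$colony_size)[grid_col],
    myrmica_nests = zscore(colonies$myrmica_nests)[grid_col],
    allo_nests = zscore(colonies$allo_nests)[grid_col],
    habitat = as.numeric(colonies$habitat == "invaded")[grid_col],
    repeat_index = zscore(rep(seq_len(R), times = K))
  )
  mu <- drop(covz[, MEAN_COVARIATES] %*% d$beta) + m_k[grid_col]
  log_sd <- drop(covz[, DISP_COVARIATES] %*% d$gamma) + s_k[grid_col]
  z <- mu + exp(log_sd) * stats::rnorm(K * R)
  raw <- to_raw(z, config$trait_scales$displacement)

  zmat <- matrix(z, K, R, byrow = TRUE)
  rmat <- matrix(raw, K, R, byrow = TRUE)
  for (j in seq_len(R)) {
    colonies[[paste0("displacement_t", j)]] <- rmat[, j]
    colonies[[paste0("displacement_z", j)]] <- zmat[, j]
  }
  attr(colonies, "truth_displacement") <-
    data.frame(colony_id = colonies$colony_id, m = m_k, s = s_k)
  colonies
}

#' Simulate colony productivity counts linked to behavior
#'
#' Draws brood counts (larvae; worker, male and gyne pupae; winged gynes and
#' males) from negative-binomial distributions whose log expected total is a
#' linear function of habitat and the standardized colony-level means and
#' SDs of the behavioral traits (and of nest displacement when present).
#' The expected total is split across brood components by the configured
#' proportions; derived production components are recomputed exactly.
#'
#' @param config a [sim_config()] object.
#' @param trials trial table from [generate_dataset()].
#' @param colonies colony table (after [generate_nest_displacement()] if the
#'   displacement terms of the link are to be active).
#' @return `colonies` with brood-count and derived production columns.
#' @export
generate_productivity <- function(config, trials, colonies) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "productivity"))
  link <- config$productivity_link
  cf <- link$coefficients

  per_colony <- split(trials$z_value, list(trials$colony_id, trials$assay))
  n_ind <- tapply(trials$individual_id, trials$colony_id,
                  function(x) length(unique(x)))
  if (any(n_ind < 2))
    stop_invariant("each colony needs >= 2 individuals so trait SDs are defined")

  eta <- rep(cf[["intercept"]], nrow(colonies)) +
    cf[["habitat"]] * as.numeric(colonies$habitat == "invaded")
  for (trait in TRAITS) {
    sel <- trials$assay == trait
    mns <- tapply(trials$z_value[sel], trials$colony_id[sel], mean)
    sds <- tapply(trials$z_value[sel], trials$colony_id[sel], stats::sd)
    mns <- mns[colonies$colony_id]; sds <- sds[colonies$colony_id]
    mcf <- cf[[paste0("mean_", trait)]] %||% 0
    scf <- cf[[paste0("sd_", trait)]] %||% 0
    if (mcf != 0) eta <- eta + mcf * zscore(as.numeric(mns))
    if (scf != 0) eta <- eta + scf * zscore(as.numeric(sds))
  }
  if (all(paste0("displacement_t", 1:3) %in% names(colonies))) {
    dmat <- log1p(as.matrix(colonies[paste0("displacement_t", 1:3)]))
    mcf <- cf[["mean_displacement"]] %||% 0
    scf <- cf[["sd_displacement"]] %||% 0
    if (mcf != 0) eta <- eta + mcf * zscore(rowMeans(dmat))
    if (scf != 0) eta <- eta + scf * zscore(apply(dmat, 1, stats::sd))
  }

  mu_total <- exp(eta)
  for (comp in names(link$proportions)) {
    colonies[[comp]] <- stats::rnbinom(nrow(colonies),
                                       size = link$theta,
                                       mu = link$proportions[[comp]] * mu_total)
  }
  derive_production(colonies)
}

#' Simulate trial-linked production counts at the individual level
#'
#' Draws a negative-binomial count for every (individual, repeat) row whose
#' log mean is a linear function of that row's trial-level standardized
#' trait values plus an individual random intercept. Used to verify the
#' individual-level production GLMM by parameter recovery; the count is
#' written onto every assay row of the (individual, repeat) cell as column
#' `production`.
#'
#' @param config a [sim_config()] (seed source).
#' @param trials trial table from [generate_dataset()].
#' @param coefficients named vector: `intercept` (log scale) and any of the
#'   trait names.
#' @param theta NB size parameter.
#' @param sigma_id SD of the individual log-scale random intercept.
#' @return `trials` with a `production` column.
#' @export
generate_individual_counts <- function(config, trials,
                                       coefficients = c(intercept = log(600),
                                                        activity = 0.18),
                                       theta = 10, sigma_id = 0.3) {
  set.seed(stage_seed(config$seed, "productivity") + 1L)
  ids <- sort(unique(trials$individual_id))
  b_id <- stats::setNames(stats::rnorm(length(ids), 0, sigma_id), ids)
  cell <- paste(trials$individual_id, trials$repeat_index)
  cells <- unique(cell)
  eta <- rep(coefficients[["intercept"]], length(cells)) +
    b_id[sub(" .*", "", cells)]
  for (tr in intersect(names(coefficients), TRAITS)) {
    s <- trials$assay == tr
    val <- stats::setNames(trials$z_value[s],
                           paste(trials$individual_id[s], trials$repeat_index[s]))
    eta <- eta + coefficients[[tr]] * val[cells]
  }
  counts <- stats::rnbinom(length(cells), size = theta, mu = exp(eta))
  trials$production <- counts[match(cell, cells)]
  trials
}
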