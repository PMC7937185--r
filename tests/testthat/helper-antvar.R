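# Shared fixtures for the test suite: small configurations, hand-built
# trial tables, and fast MCMC settings.

quick_mcmc <- function(seed = 1L, iterations = 1500L, burn_in = 600L,
                       thinning = 2L, chains = 2L) {
  list(chains = chains, iterations = iterations, burn_in = burn_in,
       thinning = thinning, seed = seed)
}

# A minimal valid trial table built directly from vectors (one assay).
make_trials <- function(y, group, colony = NULL, assay = "activity",
                        repeat_index = NULL, habitat = NULL) {
  n <- length(y)
  colony <- colony %||% rep("C01", n)
  habitat <- habitat %||% rep("seminatural", n)
  repeat_index <- repeat_index %||% stats::ave(seq_len(n), group, FUN = seq_along)
  data.frame(colony_id = colony, individual_id = group, habitat = habitat,
             assay = assay, repeat_index = repeat_index, raw_value = pmax(y, 0),
             transformed_value = y, z_value = y, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-way grouped Gaussian data with known variance components.
make_icc_data <- function(n_groups, n_per, var_group, var_resid, seed,
                          assay = "activity") {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = n_per)
  y <- rnorm(n_groups, 0, sqrt(var_group))[g] + rnorm(n_groups * n_per, 0, sqrt(var_resid))
  make_trials(y, sprintf("I%04d", g),
              colony = sprintf("C%03d", (g - 1) %/% 10 + 1),
              repeat_index = rep(seq_len(n_per), n_groups), assay = assay)
}

# Two-trait trial table with known individual-level and residual
# correlation (no colony effects).
make_twotrait_data <- function(n_ind, n_rep, r_ind, r_res, var_ind = 1,
                               var_res = 1, seed = 1) {
  set.seed(seed)
  U <- MASS::mvrnorm(n_ind, c(0, 0), var_ind * matrix(c(1, r_ind, r_ind, 1), 2))
  idx <- rep(seq_len(n_ind), each = n_rep)
  E <- MASS::mvrnorm(n_ind * n_rep, c(0, 0), var_res * matrix(c(1, r_res, r_res, 1), 2))
  Y <- U[idx, ] + E
  colony <- sprintf("C%02d", (idx - 1) %% 20 + 1)
  id <- sprintf("I%04d", idx)
  rbind(
    make_trials(Y[, 1], id, colony, "activity", rep(seq_len(n_rep), n_ind)),
    make_trials(Y[, 2], id, colony, "exploration", rep(seq_len(n_rep), n_ind))
  )
}

# Method-of-moments estimate of the among-group correlation in a balanced
# two-trait design: S_between-of-means minus S_within/m, standardized.
mom_group_correlation <- function(y1, y2, group, m) {
  m1 <- tapply(y1, group, mean); m2 <- tapply(y2, group, mean)
  d1 <- y1 - m1[group]; d2 <- y2 - m2[group]
  Sw <- stats::cov(cbind(d1, d2)) * (length(y1) - 1) / (length(y1) - length(m1))
  Sb <- stats::cov(cbind(m1, m2)) - Sw / m
  Sb[1, 2] / sqrt(Sb[1, 1] * Sb[2, 2])
}
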