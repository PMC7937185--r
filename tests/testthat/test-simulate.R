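test_that("generated dataset matches the study design and is seed-deterministic", {
  cfg <- sim_config(seed = 7)
  dat <- generate_dataset(cfg)
  # 23 colonies x 12 workers x 3 repeats per assay
  expect_equal(nrow(dat$trials), 23 * 12 * 3 * 4)
  expect_equal(sum(dat$trials$assay == "activity"), 828)
  expect_equal(nrow(dat$colonies), 23)
  expect_equal(as.vector(table(dat$colonies$habitat)[c("seminatural", "invaded")]),
               c(12, 11))
  expect_true(all(dat$colonies$colony_size >= 219 & dat$colonies$colony_size <= 5964))
  expect_true(all(dat$colonies$myrmica_nests <= 9 & dat$colonies$allo_nests <= 3))
  validate_trial_table(dat$trials)
  validate_colony_table(dat$colonies)
  dat2 <- generate_dataset(cfg)
  expect_identical(dat, dat2)
  # a different seed must change the data
  expect_false(identical(dat$trials$z_value,
                         generate_dataset(sim_config(seed = 8))$trials$z_value))
})

test_that("configuration invariants are enforced with named errors", {
  expect_error(sim_config(n_workers_per_colony = 0), "count")
  expect_error(sim_config(sigma2_id_mu = -1), "variances")
  expect_error(sim_config(sigma2_id_mu = 0.1, sigma2_id_sigma = 0.1,
                          cov_mu_sigma = 0.5), "cov_mu_sigma")
  bad <- default_corr <- diag(4)
  bad[1, 2] <- bad[2, 1] <- 1.5
  dimnames(bad) <- list(c("activity", "meandering", "exploration", "aggression"),
                        c("activity", "meandering", "exploration", "aggression"))
  expect_error(
    sim_config(level_correlation_matrices = list(colony = bad, individual = diag(4),
                                                 residual = diag(4))),
    "positive semidefinite")
  expect_error(sim_config(colony_size_range = c(100, 10)), "colony_size_range")
})

test_that("degenerate parameters give unit-SD noise around zero", {
  cfg <- sim_config(n_colonies_per_habitat = c(20L, 20L),
                    n_workers_per_colony = 10L, n_repeats_per_assay = 5L,
                    beta = rep(0, 7), gamma = rep(0, 6),
                    sigma2_id_mu = 0, sigma2_colony = 0, sigma2_id_sigma = 0,
                    cov_mu_sigma = 0, seed = 3)
  dat <- generate_dataset(cfg)
  z <- dat$trials$z_value[dat$trials$assay == "activity"]
  n <- length(z)
  expect_lt(abs(mean(z)), 3 / sqrt(n))
  # SD of a Gaussian sample: SE ~ 1/sqrt(2 n)
  expect_lt(abs(sd(z) - 1), 3 / sqrt(2 * n))
})

test_that("realized random effects recover configured moments and correlations", {
  # 500 individuals, large repeat count: moments within 3 SE
  cfg <- sim_config(n_colonies_per_habitat = c(25L, 25L),
                    n_workers_per_colony = 10L, n_repeats_per_assay = 3L,
                    sigma2_id_mu = 1, sigma2_colony = 0.4, sigma2_id_sigma = 0.3,
                    cov_mu_sigma = 0.21 * sqrt(1 * 0.3), seed = 19)
  dat <- generate_dataset(cfg)
  tru <- dat$truth$individual
  J <- nrow(tru)
  se_var <- function(v, n) v * sqrt(2 / (n - 1))
  for (trait in c("activity", "exploration")) {
    expect_lt(abs(var(tru[[paste0("u_", trait)]]) - 1), 3 * se_var(1, J))
    expect_lt(abs(var(tru[[paste0("w_", trait)]]) - 0.3), 3 * se_var(0.3, J))
    r <- cor(tru[[paste0("u_", trait)]], tru[[paste0("w_", trait)]])
    expect_lt(abs(r - 0.21), 3 * (1 - 0.21^2) / sqrt(J - 3))
  }
  # colony-level trait correlation matches the configured matrix
  R_cfg <- cfg$level_correlation_matrices$colony
  K <- nrow(dat$truth$colony)
  r_ae <- cor(dat$truth$colony$activity, dat$truth$colony$exploration)
  expect_lt(abs(r_ae - R_cfg["activity", "exploration"]),
            3 * (1 - R_cfg["activity", "exploration"]^2) / sqrt(K - 3))
  # individual-level cross-trait correlation of the mean intercepts
  R_ind <- cfg$level_correlation_matrices$individual
  r_am <- cor(tru$u_activity, tru$u_meandering)
  expect_lt(abs(r_am - R_ind["activity", "meandering"]),
            3 * (1 - R_ind["activity", "meandering"]^2) / sqrt(J - 3))
})

test_that("nest displacement times are positive, complete, and recover the size slope", {
  cfg <- sim_config(seed = 5)
  dat <- generate_dataset(cfg)
  col <- generate_nest_displacement(cfg, dat$colonies)
  times <- unlist(col[paste0("displacement_t", 1:3)])
  expect_length(times, 69)
  expect_true(all(times > 0))
  expect_error(generate_nest_displacement(cfg, dat$colonies[0, ]), "missing|colonies")

  # at 200 colonies the colony-level regression of mean latent log time on
  # standardized colony size recovers the generating slope (-0.49);
  # averaging the three repeats keeps OLS inference valid under the colony
  # random intercept
  cfg2 <- sim_config(n_colonies_per_habitat = c(100L, 100L), seed = 13)
  dat2 <- generate_dataset(cfg2)
  col2 <- generate_nest_displacement(cfg2, dat2$colonies)
  cdat <- data.frame(
    y = rowMeans(as.matrix(col2[paste0("displacement_z", 1:3)])),
    worker_size = scale(col2$mean_worker_size)[, 1],
    colony_size = scale(col2$colony_size)[, 1],
    myrmica_nests = scale(col2$myrmica_nests)[, 1],
    allo_nests = scale(col2$allo_nests)[, 1],
    habitat_code = as.numeric(col2$habitat == "invaded"))
  fit <- lm(y ~ ., data = cdat)
  ci <- confint(fit)["colony_size", ]
  expect_gt(-0.49, ci[1])
  expect_lt(-0.49, ci[2])

  # zero colony variance: among-colony ICC of the latent times ~ 0
  cfg3 <- sim_config(displacement = list(beta = rep(0, 7), gamma = rep(0, 6),
                                         sigma2_mu = 0, sigma2_sigma = 0,
                                         cov_mu_sigma = 0),
                     n_colonies_per_habitat = c(50L, 50L), seed = 21)
  dat3 <- generate_dataset(cfg3)
  col3 <- generate_nest_displacement(cfg3, dat3$colonies)
  zmat <- as.matrix(col3[paste0("displacement_z", 1:3)])
  msb <- var(rowMeans(zmat)) * 3
  msw <- mean(apply(zmat, 1, var))
  icc <- (msb - msw) / (msb + 2 * msw)
  expect_lt(abs(icc), 0.15)
})

test_that("productivity counts follow the configured link", {
  base <- sim_config(seed = 31)
  # intercept-only link at log(100): mean total production ~ 100
  link0 <- base$productivity_link
  link0$coefficients[] <- 0
  link0$coefficients["intercept"] <- log(100)
  cfg <- sim_config(n_colonies_per_habitat = c(100L, 100L),
                    n_workers_per_colony = 4L,
                    productivity_link = link0, seed = 31)
  dat <- generate_dataset(cfg)
  col <- generate_productivity(cfg, dat$trials, dat$colonies)
  expect_true(all(col$total_production >= 0))
  expect_true(all(col$total_production == round(col$total_production)))
  # NB total: mean 100; var = sum over components of (mu_c + mu_c^2 / theta)
  pr <- link0$proportions
  var_total <- 100 + 100^2 * sum(pr^2) / base$productivity_link$theta
  expect_lt(abs(mean(col$total_production) - 100),
            3 * sqrt(var_total / nrow(col)))

  # dispersion -> infinity limit approaches Poisson (variance ~ mean)
  link0$theta <- 1e8
  cfgp <- sim_config(n_colonies_per_habitat = c(250L, 250L),
                     n_workers_per_colony = 4L,
                     productivity_link = link0, seed = 33)
  datp <- generate_dataset(cfgp)
  colp <- generate_productivity(cfgp, datp$trials, datp$colonies)
  ratio <- var(colp$n_larvae) / mean(colp$n_larvae)
  # var/mean of Poisson(50) over n colonies: SE of the ratio ~ sqrt(2/n)
  expect_lt(abs(ratio - 1), 4 * sqrt(2 / nrow(colp)))

  # undefined SD with a single worker per colony
  cfg1 <- sim_config(n_workers_per_colony = 1L, seed = 35)
  dat1 <- generate_dataset(cfg1)
  expect_error(generate_productivity(cfg1, dat1$trials, dat1$colonies),
               ">= 2 individuals")
})

test_that("individual-level count generator writes one count per trial cell", {
  cfg <- sim_config(seed = 41)
  dat <- generate_dataset(cfg)
  tr <- generate_individual_counts(cfg, dat$trials,
                                   c(intercept = log(50), activity = 0.2))
  expect_true(all(tr$production >= 0))
  cell <- paste(tr$individual_id, tr$repeat_index)
  per_cell <- tapply(tr$production, cell, function(x) length(unique(x)))
  expect_true(all(per_cell == 1))
})
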