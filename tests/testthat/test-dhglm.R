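# Build a fake fit object so summary logic can be tested on known draws.
fake_fit <- function(draws_list) {
  params <- colnames(draws_list[[1]])
  diag <- data.frame(parameter = params, rhat = 1, ess = 1e4)
  structure(list(chains = draws_list, diagnostics = diag, spec = NULL,
                 n = 0L, n_groups = 0L, n_groups2 = 0L, group_labels = NULL),
            class = "dhglm_fit")
}

test_that("model specification enforces its invariants", {
  expect_error(dhglm_spec("activity", mcmc = list(chains = 1L)), "chains")
  expect_error(dhglm_spec("activity", mcmc = list(iterations = 100L, burn_in = 100L)),
               "burn_in")
  s <- dhglm_spec("displacement", grouping = "colony_only")
  expect_equal(s$grouping, "colony_only")
})

test_that("non-standardized or singular designs are rejected", {
  cfg <- sim_config(seed = 6)
  trials <- generate_dataset(cfg)$trials
  spec <- dhglm_spec("activity", mcmc = quick_mcmc())
  bad <- trials
  bad$colony_size <- bad$colony_size * 3 + 1   # destandardize
  expect_error(fit_dhglm(bad, NULL, spec), "not standardized")
  bad2 <- trials
  bad2$worker_size <- bad2$colony_size          # collinear copy
  expect_error(fit_dhglm(bad2, NULL, spec), "singular")
})

test_that("posterior summaries follow their definitions on known draws", {
  mk <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, "beta_intercept"))
  # point mass at c: mean c, CrI [c, c], supported iff c != 0
  f <- fake_fit(list(mk(rep(2, 500)), mk(rep(2, 500))))
  s <- summarize_fit(f)
  expect_equal(s$mean, 2)
  expect_equal(c(s$lower, s$upper), c(2, 2))
  expect_true(s$supported)
  f0 <- fake_fit(list(mk(rep(0, 500)), mk(rep(0, 500))))
  expect_false(summarize_fit(f0)$supported)
  # symmetric draws around zero are not supported
  set.seed(1)
  fs <- fake_fit(list(mk(rnorm(5000)), mk(rnorm(5000))))
  expect_false(summarize_fit(fs)$supported)
  # 10,000 standard-normal draws: 95% CrI close to +/- 1.96
  set.seed(2)
  fn <- fake_fit(list(mk(rnorm(5000)), mk(rnorm(5000))))
  s <- summarize_fit(fn)
  expect_lt(abs(s$lower + 1.96), 0.08)
  expect_lt(abs(s$upper - 1.96), 0.08)
  # empty store errors
  expect_error(summarize_fit(fake_fit(list(mk(numeric(0))))), "empty")
})

test_that("sampler is deterministic given the seed and invariant to row order", {
  cfg <- sim_config(n_colonies_per_habitat = c(4L, 4L),
                    n_workers_per_colony = 6L, seed = 10)
  trials <- generate_dataset(cfg)$trials
  spec <- dhglm_spec("activity", mcmc = quick_mcmc(seed = 5, iterations = 600L,
                                                   burn_in = 300L))
  f1 <- fit_dhglm(trials, NULL, spec)
  f2 <- fit_dhglm(trials, NULL, spec)
  expect_identical(f1$chains, f2$chains)
  set.seed(42)
  shuffled <- trials[sample(nrow(trials)), ]
  f3 <- fit_dhglm(shuffled, NULL, spec)
  expect_identical(f1$chains, f3$chains)
})

test_that("every r_int_riiv draw lies in [-1, 1] and variances are non-negative", {
  cfg <- sim_config(n_colonies_per_habitat = c(5L, 5L),
                    n_workers_per_colony = 8L, seed = 14)
  trials <- generate_dataset(cfg)$trials
  fit <- fit_dhglm(trials, NULL, dhglm_spec("exploration", mcmc = quick_mcmc(seed = 3)))
  draws <- pooled_draws(fit)
  expect_true(all(abs(draws[, "r_int_riiv"]) <= 1))
  expect_true(all(draws[, c("sigma2_id_mu", "sigma2_id_sigma", "sigma2_colony")] >= 0))
  # stored covariance and correlation agree: cov = r * sqrt(v1 * v2)
  expect_equal(draws[, "cov_mu_sigma"],
               draws[, "r_int_riiv"] *
                 sqrt(draws[, "sigma2_id_mu"] * draws[, "sigma2_id_sigma"]),
               tolerance = 1e-10)
})

test_that("a dispersion variance of zero in the truth concentrates near zero", {
  cfg <- sim_config(n_colonies_per_habitat = c(10L, 10L),
                    n_workers_per_colony = 5L, n_repeats_per_assay = 10L,
                    sigma2_id_sigma = 0, cov_mu_sigma = 0, seed = 17)
  trials <- generate_dataset(cfg)$trials
  fit <- fit_dhglm(trials, NULL,
                   dhglm_spec("activity", mcmc = quick_mcmc(seed = 2,
                                                            iterations = 2000L,
                                                            burn_in = 800L)))
  med <- median(pooled_draws(fit)[, "sigma2_id_sigma"])
  expect_lt(med, 0.05)
})

test_that("random-intercept likelihood-ratio tests detect and respect structure", {
  # strong individual ICC (~0.5): p far below 0.001
  trials <- make_icc_data(100, 10, 1, 1, seed = 23)
  spec <- dhglm_spec("activity", mean_covariates = character(0))
  out <- random_intercept_lrt(trials, spec, "individual")
  expect_lt(out$p, 1e-6)
  expect_gt(out$chi2, 0)
  # a term absent from the model errors
  spec_col <- dhglm_spec("activity", mean_covariates = character(0),
                         grouping = "colony_only")
  expect_error(random_intercept_lrt(trials, spec_col, "individual"),
               "not in the")
  # null calibration: with zero group variance the boundary-corrected p
  # rejects at most ~alpha
  set.seed(31)
  rej <- 0
  for (i in 1:40) {
    null_tr <- make_icc_data(40, 3, 0, 1, seed = 1000 + i)
    p <- random_intercept_lrt(null_tr, spec, "individual")$p
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej / 40, 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("with homogeneous variance the posterior matches the ML linear mixed model", {
  cfg <- sim_config(n_colonies_per_habitat = c(12L, 11L),
                    gamma = cbind(c(-0.7, 0, 0, 0, 0, 0))[, c(1, 1, 1, 1)],
                    sigma2_id_sigma = 0, cov_mu_sigma = 0, seed = 29)
  trials <- generate_dataset(cfg)$trials
  spec <- dhglm_spec("activity", dispersion_covariates = character(0),
                     individual_dispersion = FALSE,
                     mcmc = quick_mcmc(seed = 8, iterations = 4000L,
                                       burn_in = 1500L))
  fit <- fit_dhglm(trials, NULL, spec)
  draws <- pooled_draws(fit)
  lmm <- lme4::lmer(z_value ~ worker_size + colony_size + myrmica_nests +
                      allo_nests + habitat_code + repeat_index_z +
                      (1 | individual_id) + (1 | colony_id),
                    data = trials[trials$assay == "activity", ], REML = FALSE)
  ml <- lme4::fixef(lmm)
  bcols <- grep("^beta_", colnames(draws), value = TRUE)
  dg <- fit$diagnostics
  for (i in seq_along(bcols)) {
    mcse <- sd(draws[, bcols[i]]) / sqrt(dg$ess[dg$parameter == bcols[i]])
    expect_lt(abs(mean(draws[, bcols[i]]) - ml[i]), 3 * mcse + 0.01)
  }
})
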