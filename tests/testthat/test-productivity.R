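test_that("AICc equals its closed form and drives subset selection", {
  set.seed(1)
  d <- data.frame(y = rpois(40, 5), x1 = rnorm(40), x2 = rnorm(40))
  fit <- glm(y ~ x1 + x2, family = poisson(), data = d)
  k <- attr(logLik(fit), "df")
  expect_equal(aicc(fit), AIC(fit) + 2 * k * (k + 1) / (40 - k - 1),
               tolerance = 1e-12)
  # two candidate terms: exactly 4 models visited, best has the minimum
  sel <- select_by_information_criterion(fit, data = d, strategy = "all_subsets")
  expect_equal(nrow(sel$path), 4)
  expect_equal(sel$path$aicc[1], min(sel$path$aicc))
  expect_true(all(sel$path$aicc[1] <= sel$path$aicc))
  # term order in the formula does not change the winner
  fit2 <- glm(y ~ x2 + x1, family = poisson(), data = d)
  sel2 <- select_by_information_criterion(fit2, data = d, strategy = "all_subsets")
  expect_equal(sel$path$model[1], sel2$path$model[1])
  # combinatorial guard
  big <- as.data.frame(matrix(rnorm(40 * 25), 40))
  big$y <- rpois(40, 5)
  fbig <- glm(y ~ ., family = poisson(), data = big)
  expect_error(select_by_information_criterion(fbig, data = big), "refused")
})

test_that("the overdispersion rule picks the right family", {
  cfg <- sim_config(n_colonies_per_habitat = c(50L, 50L),
                    n_workers_per_colony = 3L, seed = 21)
  dat <- generate_dataset(cfg)
  # strongly overdispersed counts (theta = 2) -> negative binomial
  link <- cfg$productivity_link; link$theta <- 2
  cfg_od <- sim_config(n_colonies_per_habitat = c(50L, 50L),
                       n_workers_per_colony = 3L, productivity_link = link,
                       seed = 21)
  col <- suppressWarnings(generate_productivity(cfg_od, dat$trials, dat$colonies))
  f <- suppressWarnings(fit_colony_production_model(col, dat$trials, "total"))
  expect_equal(f$family, "negative_binomial")
  expect_gt(f$dispersion, 0)
  # near-Poisson counts stay Poisson
  link$theta <- 1e8
  link$coefficients[] <- 0; link$coefficients["intercept"] <- log(60)
  cfg_p <- sim_config(n_colonies_per_habitat = c(50L, 50L),
                      n_workers_per_colony = 3L, productivity_link = link,
                      seed = 23)
  datp <- generate_dataset(cfg_p)
  colp <- generate_productivity(cfg_p, datp$trials, datp$colonies)
  fp <- fit_colony_production_model(colp, datp$trials, "total")
  expect_equal(fp$family, "poisson")
  # its coefficients equal the plain Poisson GLM oracle
  oracle <- glm(fp$model$formula, family = poisson(),
                data = fp$model$data %||% fp$model$model)
  expect_equal(unname(coef(fp$model)), unname(coef(oracle)), tolerance = 1e-8)
})

test_that("colony model recovers a generating exploration effect at n = 200", {
  link <- default_productivity_link()
  link$coefficients[] <- 0
  link$coefficients["intercept"] <- log(500)
  link$coefficients["mean_exploration"] <- 0.73
  link$theta <- 10
  covered <- retained <- 0
  for (rep in 1:5) {
    cfg <- sim_config(n_colonies_per_habitat = c(100L, 100L),
                      n_workers_per_colony = 3L, productivity_link = link,
                      seed = 270 + rep)
    dat <- generate_dataset(cfg)
    col <- suppressWarnings(generate_productivity(cfg, dat$trials, dat$colonies))
    f <- suppressWarnings(fit_colony_production_model(col, dat$trials, "total",
                                                      selection = "stepwise"))
    ct <- f$coefficients
    if ("mean_exploration" %in% ct$term) {
      retained <- retained + 1
      row <- ct[ct$term == "mean_exploration", ]
      covered <- covered + (row$lower < 0.73 && 0.73 < row$upper)
    }
  }
  expect_equal(retained, 5)      # a z ~ 6 effect is always selected
  expect_gte(covered, 4)         # nominal-95% CIs: allow one miss in five
})

test_that("skips and degenerate inputs are handled", {
  cfg <- sim_config(seed = 30)
  dat <- generate_dataset(cfg)
  col <- suppressWarnings(generate_productivity(cfg, dat$trials, dat$colonies))
  col$new_males <- 0L; col$new_males[1:2] <- 5L
  expect_message(
    out <- fit_colony_production_model(col, dat$trials, "males"),
    "skipped")
  expect_null(out)
  # identical response for every row is a degenerate individual-level fit
  col2 <- col; col2$total_production <- 1000L
  expect_error(fit_individual_production_model(dat$trials, col2, "total"),
               "degenerate")
})

test_that("individual model recovers a generating activity effect", {
  cfg <- sim_config(n_colonies_per_habitat = c(15L, 15L),
                    n_workers_per_colony = 5L, seed = 33)
  dat <- generate_dataset(cfg)
  tr <- generate_individual_counts(cfg, dat$trials,
                                   c(intercept = log(500), activity = 0.18),
                                   theta = 10, sigma_id = 0.3)
  f <- fit_individual_production_model(tr, response_col = "production")
  expect_equal(f$family, "negative_binomial")
  row <- f$coefficients[f$coefficients$term == "activity", ]
  expect_gt(0.18, row$lower)
  expect_lt(0.18, row$upper)
  # all-subsets selection over the four traits retains activity
  sel <- fit_individual_production_model(tr, response_col = "production",
                                         selection = "all_subsets")
  expect_true("activity" %in% sel$coefficients$term)
  expect_equal(nrow(sel$selection_path), 16)
})
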