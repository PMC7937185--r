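test_that("trial and colony tables round-trip through CSV unchanged", {
  cfg <- sim_config(seed = 2)
  dat <- generate_dataset(cfg)
  col <- generate_nest_displacement(cfg, dat$colonies)
  col <- generate_productivity(cfg, dat$trials, col)
  tdir <- withr::local_tempdir()
  write_trial_table(dat$trials, file.path(tdir, "trials.csv"))
  write_colony_table(col, file.path(tdir, "colonies.csv"))
  trials2 <- read_trial_table(file.path(tdir, "trials.csv"))
  col2 <- read_colony_table(file.path(tdir, "colonies.csv"))
  expect_equal(trials2$z_value, dat$trials$z_value, tolerance = 1e-12)
  expect_equal(trials2$individual_id, dat$trials$individual_id)
  expect_equal(col2$total_production, col$total_production)
  expect_equal(nrow(trials2), nrow(dat$trials))
})

test_that("validation errors name the violated rule and the row", {
  cfg <- sim_config(seed = 2)
  trials <- generate_dataset(cfg)$trials
  bad <- trials
  i <- which(bad$assay == "aggression")[1]
  bad$raw_value[i] <- 4
  expect_error(validate_trial_table(bad), "\\[0,3\\]")
  bad2 <- rbind(trials, trials[1, ])
  expect_error(validate_trial_table(bad2), "unique")
  bad3 <- trials
  bad3$repeat_index[1] <- 5
  expect_error(validate_trial_table(bad3), "repeat_index")
  bad4 <- trials
  bad4$colony_id[1] <- "C99"
  expect_error(validate_trial_table(bad4), "multiple colonies")
})

test_that("derived production identities hold exactly", {
  cfg <- sim_config(seed = 9)
  dat <- generate_dataset(cfg)
  col <- generate_productivity(cfg, dat$trials, dat$colonies)
  expect_identical(col$total_production,
                   col$n_larvae + col$pupae_worker + col$pupae_male +
                     col$pupae_gyne + col$winged_gynes + col$winged_males)
  expect_identical(col$new_workers, col$n_larvae + col$pupae_worker)
  expect_identical(col$new_gynes, col$pupae_gyne + col$winged_gynes)
  expect_identical(col$new_males, col$pupae_male + col$winged_males)
  # corrupting a derived column is caught
  col$total_production[3] <- col$total_production[3] + 1
  expect_error(validate_colony_table(col), "identity")
})

test_that("log1p transform and standardization behave as defined", {
  raw <- c(0, 1, 2, 3)
  trials <- make_trials(raw, sprintf("I%d", 1:4), assay = "aggression",
                        repeat_index = rep(1, 4))
  trials$raw_value <- raw
  out <- transform_and_standardize(trials)
  expect_equal(out$transformed_value, log1p(raw), tolerance = 1e-12)
  expect_equal(out$transformed_value[2], 0.6931472, tolerance = 1e-6)
  expect_lt(abs(mean(out$z_value)), 1e-12)
  expect_lt(abs(sd(out$z_value) - 1), 1e-12)
  # standardizing an already standardized column changes nothing
  again <- make_trials(out$z_value, sprintf("I%d", 1:4), assay = "activity",
                       repeat_index = rep(1, 4))
  again$raw_value <- out$z_value
  out2 <- transform_and_standardize(again,
                                    trait_policy = c(activity = "identity"))
  expect_equal(out2$z_value, out$z_value, tolerance = 1e-12)
  # zero variance is an error
  const <- make_trials(rep(2, 4), sprintf("I%d", 1:4), repeat_index = rep(1, 4))
  expect_error(transform_and_standardize(const), "zero variance")
})

test_that("complete-case filter retains exactly the fully tested individuals", {
  # 276 individuals, 49 of which lose at least one trial -> 227 retained
  cfg <- sim_config(seed = 4)
  trials <- generate_dataset(cfg)$trials
  ids <- unique(trials$individual_id)
  expect_length(ids, 276)
  set.seed(99)
  dropped_ids <- sample(ids, 49)
  drop_rows <- unlist(lapply(dropped_ids, function(id) {
    rows <- which(trials$individual_id == id)
    sample(rows, sample(1:3, 1))
  }))
  cut <- trials[-drop_rows, ]
  kept <- filter_complete_cases(cut)
  expect_length(unique(kept$individual_id), 227)
  expect_equal(nrow(kept) %% 12, 0)
  ret <- attr(kept, "retention")
  expect_equal(sum(ret$retained), 227)
  expect_equal(sum(ret$dropped), 49)
  # one individual missing exactly one aggression repeat loses all its rows
  one <- trials[!(trials$individual_id == ids[1] & trials$assay == "aggression" &
                    trials$repeat_index == 2), ]
  kept1 <- filter_complete_cases(one)
  expect_false(ids[1] %in% kept1$individual_id)
  expect_equal(nrow(kept1), nrow(trials) - 12)
  # all complete is the identity
  expect_equal(nrow(filter_complete_cases(trials)), nrow(trials))
})

test_that("Spearman screen matches the rank-then-Pearson oracle and flags pairs", {
  # brute-force oracle on all tie-free inputs of n <= 8
  set.seed(11)
  for (n in c(4, 5, 8)) {
    for (rep in 1:5) {
      x <- sample(100, n); y <- sample(100, n)
      col <- data.frame(colony_id = sprintf("C%d", 1:n), habitat = "seminatural",
                        colony_size = 100, a = x, b = y)
      res <- collinearity_screen(col, c("a", "b"), rho_threshold = 0.45)
      oracle <- cor(rank(x), rank(y))
      expect_equal(res$rho, oracle, tolerance = 1e-12)
      expect_equal(res$S, (n^3 - n) * (1 - oracle) / 6, tolerance = 1e-9)
    }
  }
  # perfect concordance through a monotone transform
  col <- data.frame(colony_id = sprintf("C%d", 1:6), habitat = "seminatural",
                    colony_size = 100, a = 1:6, b = exp(1:6))
  res <- collinearity_screen(col, c("a", "b"))
  expect_equal(res$rho, 1)
  expect_equal(res$S, 0)
  expect_true(res$flagged)
  # reversed order, n = 5: rho = -1, S = 40
  col5 <- data.frame(colony_id = sprintf("C%d", 1:5), habitat = "seminatural",
                     colony_size = 100, a = 1:5, b = 5:1)
  res5 <- collinearity_screen(col5, c("a", "b"))
  expect_equal(res5$rho, -1)
  expect_equal(res5$S, 40)
  # independent columns at n = 23 stay below the 0.45 flag threshold
  set.seed(3)
  col23 <- data.frame(colony_id = sprintf("C%d", 1:23), habitat = "seminatural",
                      colony_size = 100, a = rnorm(23), b = rnorm(23))
  expect_false(collinearity_screen(col23, c("a", "b"))$flagged)
  # constant variable reported as undefined
  colc <- data.frame(colony_id = sprintf("C%d", 1:6), habitat = "seminatural",
                     colony_size = 100, a = 1:6, b = rep(2, 6))
  expect_true(is.na(collinearity_screen(colc, c("a", "b"))$rho))
})
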