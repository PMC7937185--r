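# End-to-end workflow driver: simulate -> preprocess -> fit every model ->
# write result tables. Each stage is also callable on its own.

#' Long-format nest-displacement table for colony-level modelling
#'
#' Expands the three displacement times per colony into one row per trial,
#' log1p-transforms and standardizes the response, and standardizes the
#' colony covariates over the expanded rows (so the design matrix meets the
#' samplers' standardization contract).
#'
#' @param colonies colony table with `displacement_t1..t3`.
#' @return trial-style data frame with `assay = "displacement"`.
#' @export
displacement_long <- function(colonies) {
  tcols <- paste0("displacement_t", 1:3)
  if (!all(tcols %in% names(colonies)))
    stop_invariant("displacement columns missing from colony table")
  K <- nrow(colonies)
  raw <- as.numeric(as.matrix(colonies[tcols]))
  long <- data.frame(
    colony_id = rep(colonies$colony_id, 3),
    individual_id = rep(colonies$colony_id, 3),
    habitat = rep(colonies$habitat, 3),
    assay = "displacement",
    repeat_index = rep(1:3, each = K),
    raw_value = raw,
    transformed_value = log1p(raw)
  )
  long$z_value <- zscore(long$transformed_value)
  long$worker_size <- zscore(rep(colonies$mean_worker_size, 3))
  long$colony_size <- zscore(rep(colonies$colony_size, 3))
  long$myrmica_nests <- zscore(rep(colonies$myrmica_nests, 3))
  long$allo_nests <- zscore(rep(colonies$allo_nests, 3))
  long$habitat_code <- as.numeric(long$habitat == "invaded")
  long$repeat_index_z <- zscore(long$repeat_index)
  long
}

#' Run the full analysis workflow on a synthetic dataset
#'
#' Generates a dataset at the configured scale, then runs every stage of
#' the analysis: double hierarchical fits for the four individual traits
#' and colony-level nest displacement, random-intercept likelihood-ratio
#' tests, the four-trait and five-trait multivariate syndrome models with
#' correlation decomposition, repeatability estimates at both levels, and
#' colony- plus individual-level productivity regressions. All result
#' tables are written as CSV under `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param mcmc MCMC settings shared by the Bayesian stages.
#' @param n_bootstrap,n_permutations repeatability resampling sizes.
#' @return named list of all fitted objects and tables, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = "results",
                         mcmc = list(chains = 2L, iterations = 3000L,
                                     burn_in = 1000L, thinning = 2L,
                                     seed = config$seed),
                         n_bootstrap = 200L, n_permutations = 199L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- generate_dataset(config)
  colonies <- generate_nest_displacement(config, dat$colonies)
  colonies <- generate_productivity(config, dat$trials, colonies)
  trials <- dat$trials
  write_trial_table(trials, file.path(out_dir, "trials.csv"))
  write_colony_table(colonies, file.path(out_dir, "colonies.csv"))
  utils::write.csv(dat$truth$individual, file.path(out_dir, "truth_individual.csv"),
                   row.names = FALSE)
  utils::write.csv(dat$truth$colony, file.path(out_dir, "truth_colony.csv"),
                   row.names = FALSE)

  # double hierarchical fits, one per trait
  dh_summaries <- list(); lrt_rows <- list()
  for (trait in TRAITS) {
    spec <- dhglm_spec(trait, mcmc = mcmc)
    fit <- fit_dhglm(trials, colonies, spec)
    sm <- suppressWarnings(summarize_fit(fit))
    sm$trait <- trait
    dh_summaries[[trait]] <- sm
    for (term in c("individual", "colony")) {
      lrt <- random_intercept_lrt(trials, spec, term)
      lrt_rows[[paste(trait, term)]] <- data.frame(
        trait = trait, term = term, chi2 = lrt$chi2, p = lrt$p)
    }
  }
  disp_long <- displacement_long(colonies)
  disp_spec <- dhglm_spec("displacement", grouping = "colony_only", mcmc = mcmc)
  disp_fit <- fit_dhglm(disp_long, colonies, disp_spec)
  sm <- suppressWarnings(summarize_fit(disp_fit))
  sm$trait <- "displacement"
  dh_summaries$displacement <- sm
  dh_tab <- do.call(rbind, dh_summaries)
  utils::write.csv(dh_tab, file.path(out_dir, "dhglm_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, lrt_rows),
                   file.path(out_dir, "random_intercept_lrt.csv"),
                   row.names = FALSE)

  # behavioral syndrome
  syn4 <- fit_multitrait_model(trials, colonies, TRAITS,
                               random_levels = c("colony", "individual"),
                               mcmc = mcmc)
  syn5 <- fit_multitrait_model(trials, colonies, c(TRAITS, "displacement"),
                               random_levels = "colony", mcmc = mcmc)
  corr4 <- syndrome_correlations(syn4)
  corr5 <- syndrome_correlations(syn5)
  syn_rows <- list()
  for (lev in names(corr4)) {
    for (pair in names(corr4[[lev]]$cri)) {
      v <- corr4[[lev]]$cri[[pair]]
      syn_rows[[paste("4trait", lev, pair)]] <- data.frame(
        model = "four_trait", level = lev, pair = pair, r = v[["mean"]],
        lower = v[["lower"]], upper = v[["upper"]])
    }
  }
  for (pair in names(corr5$colony$cri)) {
    v <- corr5$colony$cri[[pair]]
    syn_rows[[paste("5trait colony", pair)]] <- data.frame(
      model = "five_trait", level = "colony", pair = pair, r = v[["mean"]],
      lower = v[["lower"]], upper = v[["upper"]])
  }
  syn_tab <- do.call(rbind, syn_rows)
  rownames(syn_tab) <- NULL
  utils::write.csv(syn_tab, file.path(out_dir, "syndrome_correlations.csv"),
                   row.names = FALSE)
  habitat_test <- fixed_effect_pmcmc(rowMeans(syn4$fixed))

  # repeatability
  rpt <- repeatability_table(trials, n_bootstrap = n_bootstrap,
                             n_permutations = n_permutations,
                             seed = config$seed)
  disp_rpt <- estimate_repeatability(disp_long, "displacement", "colony",
                                     n_bootstrap = n_bootstrap,
                                     n_permutations = n_permutations,
                                     seed = config$seed)
  rpt <- rbind(rpt, data.frame(stratum = "all", trait = "displacement",
                               level = "colony", R = disp_rpt$R,
                               ci_lower = disp_rpt$ci[["lower"]],
                               ci_upper = disp_rpt$ci[["upper"]],
                               p = disp_rpt$p))
  utils::write.csv(rpt, file.path(out_dir, "repeatability.csv"),
                   row.names = FALSE)

  # productivity
  prod_rows <- list(); prod_fits <- list()
  for (resp in c("total", "workers", "gynes", "males")) {
    fit <- fit_colony_production_model(colonies, trials, resp,
                                       selection = "stepwise")
    if (is.null(fit)) next
    ct <- fit$coefficients
    ct$response <- resp; ct$scope <- "colony"; ct$habitat_subset <- "all"
    prod_rows[[paste("colony", resp)]] <- ct
    prod_fits[[paste("colony", resp)]] <- fit
  }
  cc <- filter_complete_cases(trials)
  for (hab in c("seminatural", "invaded")) {
    for (resp in c("total", "workers")) {
      fit <- fit_individual_production_model(cc, colonies, resp, hab)
      ct <- fit$coefficients
      ct$response <- resp; ct$scope <- "individual"; ct$habitat_subset <- hab
      prod_rows[[paste("individual", hab, resp)]] <- ct
      prod_fits[[paste("individual", hab, resp)]] <- fit
    }
  }
  prod_tab <- do.call(rbind, prod_rows)
  rownames(prod_tab) <- NULL
  utils::write.csv(prod_tab, file.path(out_dir, "productivity_models.csv"),
                   row.names = FALSE)

  # collinearity screen on the colony covariates
  screen <- collinearity_screen(colonies,
                                c("colony_size", "n_queens", "n_larvae"))
  utils::write.csv(screen, file.path(out_dir, "collinearity_screen.csv"),
                   row.names = FALSE)

  invisible(list(trials = trials, colonies = colonies, truth = dat$truth,
                 dhglm = dh_tab, lrt = do.call(rbind, lrt_rows),
                 syndrome = syn_tab, habitat_pmcmc = habitat_test,
                 repeatability = rpt, productivity = prod_tab,
                 productivity_fits = prod_fits, screen = screen))
}
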