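#!/usr/bin/env Rscript
# Stage 5: fitness consequences — production counts regressed on behavior.
#
# Colony level: habitat + standardized colony means and SDs of the five
# traits, negative-binomial GLM (Poisson first, NB when overdispersed) with
# stepwise AIC selection, for total production, new workers, new gynes and
# (when enough colonies produced them) new males. Individual level:
# production joined to each worker's trial rows, NB GLMM with individual
# random intercept, fitted separately per habitat.

library(antvar)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
data_dir <- file.path("results", "data")
out_dir <- file.path("results", "productivity")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

trials <- read_trial_table(file.path(data_dir, "trials.csv"))
colonies <- read_colony_table(file.path(data_dir, "colonies.csv"))
cc <- filter_complete_cases(trials)

rows <- list()
for (resp in c("total", "workers", "gynes", "males")) {
  fit <- suppressWarnings(
    fit_colony_production_model(colonies, trials, resp, selection = "stepwise"))
  if (is.null(fit)) next
  cat(sprintf("\nColony-level %s (%s, dispersion %.1f):\n", resp, fit$family,
              fit$dispersion))
  print(fit$coefficients[c("term", "estimate", "lower", "upper", "supported")],
        digits = 3, row.names = FALSE)
  ct <- fit$coefficients
  ct$response <- resp; ct$scope <- "colony"; ct$habitat_subset <- "all"
  rows[[paste("colony", resp)]] <- ct
}

for (hab in c("seminatural", "invaded")) {
  for (resp in c("total", "workers", "gynes")) {
    fit <- suppressMessages(
      fit_individual_production_model(cc, colonies, resp, hab))
    cat(sprintf("\nIndividual-level %s in %s (%s):\n", resp, hab, fit$family))
    print(fit$coefficients[c("term", "estimate", "lower", "upper", "supported")],
          digits = 3, row.names = FALSE)
    ct <- fit$coefficients
    ct$response <- resp; ct$scope <- "individual"; ct$habitat_subset <- hab
    rows[[paste("individual", hab, resp)]] <- ct
  }
}

tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.csv(tab, file.path(out_dir, "productivity_models.csv"), row.names = FALSE)
cat(sprintf("\nWrote %d coefficient rows to %s\n", nrow(tab),
            file.path(out_dir, "productivity_models.csv")))
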