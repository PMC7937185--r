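#!/usr/bin/env Rscript
# Stage 4: behavioral consistency — intraclass-correlation repeatability of
# each trait at the colony level (grouping every colony's workers and
# trials) and the individual level (grouping each worker's repeats), with
# parametric-bootstrap CIs and randomization-test p-values; also stratified
# by habitat.

library(antvar)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
data_dir <- file.path("results", "data")
out_dir <- file.path("results", "repeatability")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

trials <- read_trial_table(file.path(data_dir, "trials.csv"))
colonies <- read_colony_table(file.path(data_dir, "colonies.csv"))
cc <- filter_complete_cases(trials)

tab <- repeatability_table(cc, n_bootstrap = 1000L, n_permutations = 999L,
                           seed = seed)
disp <- displacement_long(colonies)
d <- estimate_repeatability(disp, "displacement", "colony",
                            n_bootstrap = 1000L, n_permutations = 999L,
                            seed = seed)
tab <- rbind(tab, data.frame(stratum = "all", trait = "displacement",
                             level = "colony", R = d$R,
                             ci_lower = d$ci[["lower"]],
                             ci_upper = d$ci[["upper"]], p = d$p))
by_hab <- repeatability_table(cc, by = "habitat", n_bootstrap = 1000L,
                              n_permutations = 999L, seed = seed)
out <- rbind(tab, by_hab)
write.csv(out, file.path(out_dir, "repeatability.csv"), row.names = FALSE)

cat("Repeatability (all habitats):\n")
print(tab, digits = 3, row.names = FALSE)
cat("\nBy habitat:\n")
print(by_hab, digits = 3, row.names = FALSE)
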