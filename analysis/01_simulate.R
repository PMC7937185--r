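#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study at the field design scale.
#
# 23 colonies (12 seminatural, 11 invaded), 12 focal workers each, three
# repeats of four individual assays, three nest-displacement trials per
# colony, and brood counts linked to colony behavior. Writes the
# interchange CSVs consumed by every later stage, plus the truth
# side-tables used for parameter-recovery checks.

library(antvar)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out_dir <- file.path("results", "data")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
dat <- generate_dataset(cfg)
colonies <- generate_nest_displacement(cfg, dat$colonies)
colonies <- generate_productivity(cfg, dat$trials, colonies)

write_trial_table(dat$trials, file.path(out_dir, "trials.csv"))
write_colony_table(colonies, file.path(out_dir, "colonies.csv"))
write.csv(dat$truth$individual, file.path(out_dir, "truth_individual.csv"),
          row.names = FALSE)
write.csv(dat$truth$colony, file.path(out_dir, "truth_colony.csv"),
          row.names = FALSE)

cat(sprintf("Simulated %d trials for %d workers in %d colonies (seed %d)\n",
            nrow(dat$trials), length(unique(dat$trials$individual_id)),
            nrow(colonies), seed))
cat(sprintf("Colony sizes %d-%d workers; total production %d-%d\n",
            min(colonies$colony_size), max(colonies$colony_size),
            min(colonies$total_production), max(colonies$total_production)))

# the collinearity screen that motivates using colony size alone
screen <- collinearity_screen(colonies, c("colony_size", "n_queens", "n_larvae"))
print(screen)
cat(attr(screen, "recommendation"), "\n")
write.csv(screen, file.path(out_dir, "collinearity_screen.csv"), row.names = FALSE)
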