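#!/usr/bin/env Rscript
# Stage 1: generate the synthetic pooled multi-survey dataset.
#
# Emulates six survey waves (2003-2016, alternating DHS/MICS) of girl-level
# records on a 6x6 lattice standing in for a 36/37-state contiguity map,
# with clustered outcomes driven by structured + unstructured spatial
# effects, smooth age and period effects, an iid space-time interaction and
# social-norm fixed effects. Writes dataset/truth/graph + manifest under
# results/simulate/.

suppressPackageStartupMessages(library(starlogit))
seed <- as.integer(Sys.getenv("STARLOGIT_SEED", "1"))
out <- "results/simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

paths <- run_simulate(out, seed = seed, n_mothers = 5800, rows = 6, cols = 6,
                      missing_rate = 0.01)
d <- read_observation_table(paths$dataset)
cat(sprintf("wrote %s: %d girls of %d mothers (%.2f girls/mother), crude prevalence %.1f%%\n",
            paths$dataset, nrow(d), length(unique(d$mother_id)),
            nrow(d) / length(unique(d$mother_id)), 100 * mean(d$fgm,
                                                              na.rm = TRUE)))
cat("per-wave sample sizes:\n")
print(table(d$year, d$survey))
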