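#!/usr/bin/env Rscript
# Stage 2: weighted bivariate crosstabs and Moran's I clustering tests.
#
# Survey-weighted prevalence by covariate level (the descriptive table the
# weights exist for), then global Moran's I on crude region prevalence --
# analytic normality test and a 999-permutation Monte-Carlo test. Reads
# stage-1 output; writes results/descriptives/.

suppressPackageStartupMessages(library(starlogit))
seed <- as.integer(Sys.getenv("STARLOGIT_SEED", "1"))
out <- "results/descriptives"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d <- read_observation_table("results/simulate/dataset.tsv")
g <- read_graph("results/simulate/graph.gra", "gra")
cc <- listwise_delete(d)
cat("listwise deletion dropped", attr(cc, "n_dropped"), "rows\n")

for (cv in c("education", "residence", "mother_cut", "support", "year")) {
  tab <- weighted_prevalence_table(cc, cc$weight, by = cv)
  utils::write.csv(tab, file.path(out, paste0("crosstab_", cv, ".csv")),
                   row.names = FALSE)
  cat("\nweighted prevalence by", cv, ":\n")
  print(tab, digits = 3)
}

crude <- vapply(seq_len(g$n_regions),
                function(s) mean(cc$fgm[cc$state == s]), numeric(1))
mt <- morans_i_test(crude, g, "analytic")
mc <- morans_i_test(crude, g, "monte_carlo", n_sims = 999,
                    seed = derive_seed(seed, "moran"))
cat(sprintf("\nMoran's I on crude region prevalence: I = %.3f\n",
            mt$statistic))
cat(sprintf("  analytic p = %.4f | monte-carlo p (999 perms) = %.4f\n",
            mt$p_value, mc$p_value))
jsonlite::write_json(list(statistic = mt$statistic,
                          p_analytic = mt$p_value, p_mc = mc$p_value),
                     file.path(out, "moran.json"), auto_unbox = TRUE,
                     digits = NA)
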