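#' Deterministic per-stage seed derivation
#'
#' All randomness in a pipeline run flows from a single top-level seed;
#' each stage (or model id) gets its own child seed derived by hashing the
#' stage label, kept below 2^31.
#'
#' @param seed top-level integer seed.
#' @param stage stage label.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647L)
}

#' Write / read an observation table as tab-delimited text
#'
#' @param table observation table (data frame).
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_observation_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_observation_table
#' @export
read_observation_table <- function(path) {
  if (!file.exists(path)) stop("observation table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a ground-truth parameter set as JSON
#'
#' @param truth a `truth_params` object.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$xi <- list(values = as.vector(truth$xi), n_regions = nrow(truth$xi),
               n_years = ncol(truth$xi))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  xi <- matrix(x$xi$values, x$xi$n_regions, x$xi$n_years)
  x$xi <- xi
  for (nm in c("f_age", "f_year", "f_str", "f_unstr")) {
    x[[nm]] <- unlist(x[[nm]])
  }
  x$fixed_effects <- lapply(x$fixed_effects, unlist)
  class(x) <- "truth_params"
  x
}

write_manifest <- function(path, ...) {
  jsonlite::write_json(list(...), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline stage: simulate a pooled dataset to disk
#'
#' Draws a truth, forward-simulates the observation table, and writes
#' `dataset.tsv`, `truth.json`, `graph.gra` and `manifest.json` under
#' `out_dir`. Deterministic under the seed: the same seed yields
#' byte-identical files.
#'
#' @param out_dir output directory (must exist).
#' @param seed top-level seed.
#' @param n_mothers number of mothers.
#' @param rows,cols lattice dimensions of the synthetic region graph.
#' @param truth_config overrides for [draw_truth()].
#' @param missing_rate optional MCAR covariate missingness rate.
#' @return invisible list of written paths.
#' @export
run_simulate <- function(out_dir, seed = 1, n_mothers = 5000,
                         rows = 6, cols = 6, truth_config = list(),
                         missing_rate = 0) {
  if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
  graph <- make_lattice_graph(rows, cols)
  truth <- draw_truth(graph, truth_config, seed = derive_seed(seed, "truth"))
  tab <- simulate_dataset(truth, graph, n_mothers = n_mothers,
                          seed = derive_seed(seed, "dataset"))
  if (missing_rate > 0) {
    tab <- inject_missingness(tab, missing_rate,
                              seed = derive_seed(seed, "missing"))
  }
  paths <- list(dataset = file.path(out_dir, "dataset.tsv"),
                truth = file.path(out_dir, "truth.json"),
                graph = file.path(out_dir, "graph.gra"),
                manifest = file.path(out_dir, "manifest.json"))
  write_observation_table(tab, paths$dataset)
  write_truth(truth, paths$truth)
  write_graph(graph, paths$graph, dialect = "gra")
  write_manifest(paths$manifest, stage = "simulate", seed = seed,
                 n_mothers = n_mothers, rows = rows, cols = cols,
                 missing_rate = missing_rate, n_girls = nrow(tab))
  invisible(paths)
}

#' Pipeline stage: fit one model and write every posterior summary
#'
#' Applies listwise deletion (logging the dropped-row count in the
#' manifest), fits the requested model, and writes `por_table.csv`,
#' `prevalence_by_state.csv`, `spatial_class.csv`, `deviance_map.csv`,
#' `dic.json`, per-term coefficient chains under `chains/`, and
#' `manifest.json` (seed, schedule, retained draw count) under `out_dir`.
#'
#' @param data observation table (may contain missing covariates).
#' @param graph the companion [adjacency_graph].
#' @param out_dir output directory (must exist).
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()].
#' @return invisible list with the fit and written paths.
#' @export
run_fit <- function(data, graph, out_dir, spec = model_spec(
                      survey = TRUE,
                      covariates = c("education", "residence", "mother_cut",
                                     "support"),
                      interaction = "iid"),
                    config = mcmc_config()) {
  if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
  cc <- listwise_delete(data, spec_columns(spec))
  n_dropped <- attr(cc, "n_dropped")
  message("listwise deletion dropped ", n_dropped, " of ", nrow(data), " rows")
  terms <- build_model_terms(cc, graph, spec)
  fit <- run_mcmc(cc, terms, config)
  d <- dic(fit, cc)
  por <- posterior_odds_ratios(fit)
  prev <- predicted_prevalence(fit, cc, graph)
  cls <- classify_spatial_effects(fit)
  dmap <- deviance_map(fit, cc, graph)
  utils::write.csv(por, file.path(out_dir, "por_table.csv"), row.names = FALSE)
  utils::write.csv(prev, file.path(out_dir, "prevalence_by_state.csv"),
                   row.names = FALSE)
  utils::write.csv(cls, file.path(out_dir, "spatial_class.csv"),
                   row.names = FALSE)
  utils::write.csv(dmap, file.path(out_dir, "deviance_map.csv"),
                   row.names = FALSE)
  jsonlite::write_json(d, file.path(out_dir, "dic.json"), auto_unbox = TRUE,
                       digits = NA)
  chain_dir <- file.path(out_dir, "chains")
  dir.create(chain_dir, showWarnings = FALSE)
  for (nm in names(fit$coef)) {
    utils::write.csv(fit$coef[[nm]],
                     file.path(chain_dir, paste0(gsub("[^A-Za-z0-9_]", "_", nm),
                                                 ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(fit$tau2, file.path(chain_dir, "tau2.csv"),
                   row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"),
                 stage = "fit", seed = config$seed,
                 n_iter = config$n_iter, burn_in = config$burn_in,
                 thin = config$thin, a = config$a, b = config$b,
                 retained = fit$n_draws, n_dropped = n_dropped,
                 n_obs = nrow(cc),
                 terms = names(terms))
  invisible(list(fit = fit, dic = d, out_dir = out_dir))
}

#' Pipeline stage: fit the model suite and write the DIC table
#'
#' Wraps [fit_model_suite()]: listwise deletion first, one shared seed
#' policy across models, `dic_table.csv` plus a manifest written under
#' `out_dir`.
#'
#' @param data observation table.
#' @param graph the companion [adjacency_graph].
#' @param out_dir output directory (must exist).
#' @param models model ids.
#' @param config an [mcmc_config()].
#' @param ... passed to [fit_model_suite()].
#' @return invisible DIC table.
#' @export
run_suite <- function(data, graph, out_dir,
                      models = c("m1", "m2", "m3", "m4", "m5", "m6"),
                      config = mcmc_config(), ...) {
  if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
  cols <- unique(c("fgm", "state", "year", "survey", "mother_age",
                   "education", "residence", "mother_cut", "support"))
  cc <- listwise_delete(data, intersect(cols, names(data)))
  tab <- fit_model_suite(cc, graph, models = models, config = config, ...)
  utils::write.csv(tab, file.path(out_dir, "dic_table.csv"),
                   row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"),
                 stage = "suite", seed = config$seed, models = models,
                 n_iter = config$n_iter, burn_in = config$burn_in,
                 thin = config$thin,
                 n_dropped = attr(cc, "n_dropped"), n_obs = nrow(cc))
  invisible(tab)
}
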