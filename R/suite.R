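#' Model specifications of the nested six-model suite
#'
#' The nested sequence fitted to the pooled data:
#' \describe{
#'   \item{m1}{spatial (structured + unstructured) + f(year)}
#'   \item{m2}{m1 + survey fixed effect}
#'   \item{m3}{spatial + categorical covariates + f(age) + f(year)}
#'   \item{m4}{m3 + survey}
#'   \item{m5}{m4 + space-time interaction as an RW2 smooth}
#'   \item{m6}{m4 + space-time interaction as an iid random effect}
#' }
#' Starred variants `m1*`/`m3*` drop the year smooth (and survey and
#' interaction) for single-survey-year data.
#'
#' @param covariates categorical fixed-effect columns of m3--m6.
#' @param references reference-level overrides (see [model_spec()]).
#' @param n_knots interior knots of the age P-spline.
#' @param a,b inverse-gamma hyperparameters.
#' @return named list of [model_spec()] objects keyed by model id.
#' @export
suite_model_specs <- function(covariates = c("education", "residence",
                                             "mother_cut", "support"),
                              references = list(), n_knots = 20,
                              a = 1, b = 0.0005) {
  base <- function(...) model_spec(..., references = references,
                                   n_knots = n_knots, a = a, b = b)
  list(
    "m1" = base(year_smooth = TRUE, age_smooth = FALSE, survey = FALSE),
    "m2" = base(year_smooth = TRUE, age_smooth = FALSE, survey = TRUE),
    "m3" = base(year_smooth = TRUE, age_smooth = TRUE, survey = FALSE,
                covariates = covariates),
    "m4" = base(year_smooth = TRUE, age_smooth = TRUE, survey = TRUE,
                covariates = covariates),
    "m5" = base(year_smooth = TRUE, age_smooth = TRUE, survey = TRUE,
                covariates = covariates, interaction = "smooth"),
    "m6" = base(year_smooth = TRUE, age_smooth = TRUE, survey = TRUE,
                covariates = covariates, interaction = "iid"),
    "m1*" = base(year_smooth = FALSE, age_smooth = FALSE, survey = FALSE),
    "m3*" = base(year_smooth = FALSE, age_smooth = TRUE, survey = FALSE,
                 covariates = covariates)
  )
}

# tie-break order: smaller = simpler
suite_complexity <- c("m1*" = 1, "m1" = 2, "m2" = 3, "m3*" = 4, "m3" = 5,
                      "m4" = 6, "m6" = 7, "m5" = 8)

#' Fit the nested model suite and rank by DIC
#'
#' Fits each requested model with its own seed derived deterministically
#' from the shared configuration seed, computes the DIC of each, and
#' returns the table sorted by DIC with the best (lowest-DIC) model
#' flagged; DIC ties break toward the simpler model.
#'
#' @param data complete-case observation table.
#' @param graph the companion [adjacency_graph].
#' @param models character vector of model ids (subset of
#'   `names(suite_model_specs())`, no duplicates).
#' @param config an [mcmc_config()] applied to every model.
#' @param covariates,references,n_knots passed to [suite_model_specs()].
#' @param keep_fits return the fitted `posterior_samples` objects too.
#' @return data frame `model`, `dic`, `p_d`, `d_bar`, `best`, sorted by
#'   DIC (with attribute `fits` when `keep_fits = TRUE`).
#' @export
fit_model_suite <- function(data, graph,
                            models = c("m1", "m2", "m3", "m4", "m5", "m6"),
                            config = mcmc_config(),
                            covariates = c("education", "residence",
                                           "mother_cut", "support"),
                            references = list(), n_knots = 20,
                            keep_fits = FALSE) {
  if (anyDuplicated(models)) {
    stop("duplicate model ids: ",
         paste(unique(models[duplicated(models)]), collapse = ", "))
  }
  specs <- suite_model_specs(covariates = covariates,
                             references = references, n_knots = n_knots,
                             a = config$a, b = config$b)
  unknown <- setdiff(models, names(specs))
  if (length(unknown)) stop("unknown model id(s): ",
                            paste(unknown, collapse = ", "))
  if (length(models) == 0) {
    return(data.frame(model = character(0), dic = numeric(0),
                      p_d = numeric(0), d_bar = numeric(0),
                      best = logical(0)))
  }
  fits <- list()
  rows <- list()
  for (i in seq_along(models)) {
    id <- models[i]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, id)
    terms <- build_model_terms(data, graph, specs[[id]])
    fit <- run_mcmc(data, terms, cfg)
    d <- dic(fit, data)
    rows[[i]] <- data.frame(model = id, dic = d$dic, p_d = d$p_d,
                            d_bar = d$d_bar, stringsAsFactors = FALSE)
    if (keep_fits) fits[[id]] <- fit
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$dic, suite_complexity[out$model]), ]
  rownames(out) <- NULL
  best_dic <- min(out$dic)
  cand <- out$model[out$dic <= best_dic + 1e-9]
  best_id <- cand[which.min(suite_complexity[cand])]
  out$best <- out$model == best_id
  if (keep_fits) attr(out, "fits") <- fits
  out
}
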