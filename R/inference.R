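#' Grouped Bernoulli (binomial) deviance
#'
#' Saturated deviance of grouped binary data,
#' `D = 2 sum{ y log(y / mu) + (n - y) log((n - y)/(n - mu)) }` with
#' `mu = n * mu_hat` the fitted count and the convention `0 log 0 = 0`.
#' Per-unit contributions quantify local misfit (the deviance map).
#'
#' @param y successes per unit.
#' @param n trials per unit (`0 <= y <= n`).
#' @param mu_hat fitted probabilities, strictly inside (0, 1).
#' @return list with `total` and `contributions` (summing to `total`).
#' @export
bernoulli_deviance <- function(y, n, mu_hat) {
  if (any(y < 0 | y > n)) stop("need 0 <= y <= n")
  if (any(mu_hat <= 0 | mu_hat >= 1)) {
    if (any((mu_hat == 0 & y > 0) | (mu_hat == 1 & y < n))) {
      stop("infinite deviance: fitted probability 0/1 contradicts the data")
    }
    stop("mu_hat must lie strictly in (0, 1)")
  }
  fit <- n * mu_hat
  t1 <- ifelse(y == 0, 0, y * log(y / fit))
  t2 <- ifelse(n - y == 0, 0, (n - y) * log((n - y) / (n - fit)))
  contrib <- 2 * (t1 + t2)
  list(total = sum(contrib), contributions = contrib)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = D_bar + p_D` with `D_bar` the posterior mean of the girl-level
#' deviance `-2 log L(eta)` over stored draws, `p_D = D_bar - D_hat` the
#' effective parameter count, and `D_hat` the deviance at the posterior
#' mean of the linear predictor (which, `eta` being linear in the
#' coefficients, is the predictor at the posterior-mean coefficients).
#' A negative `p_D` is reported with a warning, not hidden.
#'
#' @param samples a [run_mcmc()] result.
#' @param data the observation table the model was fitted to.
#' @param y_col outcome column.
#' @return list with `dic`, `p_d`, `d_bar`, `d_at_mean`.
#' @export
dic <- function(samples, data, y_col = "fgm") {
  if (samples$n_draws < 2) stop("DIC needs at least 2 retained draws")
  y <- data[[y_col]]
  d_bar <- mean(samples$deviance)
  coef_means <- lapply(samples$coef, colMeans)
  eta_hat <- eta_from_coefs(samples, coefs = coef_means)
  d_hat <- -2 * bernoulli_loglik(y, eta_hat)
  p_d <- d_bar - d_hat
  if (p_d < 0) warning("negative effective parameter count p_D = ",
                       round(p_d, 2), call. = FALSE)
  list(dic = d_bar + p_d, p_d = p_d, d_bar = d_bar, d_at_mean = d_hat)
}

#' Posterior odds ratios of a fixed-effect block
#'
#' For every non-reference level of each categorical covariate in the
#' joint fixed block: the posterior mean of `exp(beta)` (the posterior
#' odds ratio proper) with 2.5%/97.5% quantiles, plus `exp` of the
#' posterior-mean coefficient for comparison. Reference levels are emitted
#' with POR 1.00 and an empty interval.
#'
#' @param samples a [run_mcmc()] result whose term list contains a fixed
#'   block built by [build_model_terms()].
#' @param term_name name of the fixed block (default `"fixed"`).
#' @return data frame with columns `covariate`, `level`, `por`, `lower`,
#'   `upper`, `por_at_mean`, `reference`.
#' @export
posterior_odds_ratios <- function(samples, term_name = "fixed") {
  tm <- samples$terms[[term_name]]
  if (is.null(tm) || tm$kind != "fixed") {
    stop("'", term_name, "' is not a fixed-effect term; smooth terms are ",
         "reported as curves, not odds ratios")
  }
  draws <- samples$coef[[term_name]]
  meta <- tm$meta
  rows <- list()
  for (cv in unique(meta$covariate)) {
    if (cv == "(Intercept)") next
    ref <- tm$references[[cv]]
    rows[[length(rows) + 1]] <- data.frame(
      covariate = cv, level = paste0(ref, " (ref)"), por = 1, lower = NA,
      upper = NA, por_at_mean = 1, reference = TRUE,
      stringsAsFactors = FALSE)
    for (k in which(meta$covariate == cv)) {
      b <- draws[, meta$column[k]]
      e <- exp(b)
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, level = meta$level[k], por = mean(e),
        lower = unname(stats::quantile(e, 0.025)),
        upper = unname(stats::quantile(e, 0.975)),
        por_at_mean = exp(mean(b)), reference = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior predicted prevalence by region
#'
#' For each stored draw, each girl's linear predictor is back-transformed,
#' `p = exp(eta)/(1 + exp(eta))`, and averaged over the girls observed in
#' each region; the per-region draw averages are then summarised by
#' posterior mean and a 95% credible band. Regions with no observations
#' are reported at the covariate-reference profile (intercept + spatial
#' effects only) and flagged `borrowed` — their estimate rests entirely on
#' the spatial prior borrowing strength from neighbours.
#'
#' @param samples a [run_mcmc()] result.
#' @param data the observation table.
#' @param graph the companion [adjacency_graph].
#' @return data frame `region`, `label`, `n`, `prevalence`, `lower`,
#'   `upper`, `borrowed`.
#' @export
predicted_prevalence <- function(samples, data, graph) {
  S <- graph$n_regions
  st <- data$state
  counts <- tabulate(st, nbins = S)
  prev <- matrix(NA_real_, samples$n_draws, S)
  spatial_terms <- intersect(c("f_str", "f_unstr"), names(samples$terms))
  fixed_nm <- names(samples$terms)[vapply(samples$terms,
                                          function(t) t$kind == "fixed", TRUE)]
  for (d in seq_len(samples$n_draws)) {
    eta <- eta_from_coefs(samples, draw = d)
    p <- stats::plogis(eta)
    obs_mean <- vapply(seq_len(S), function(s) {
      if (counts[s] > 0) mean(p[st == s]) else NA_real_
    }, numeric(1))
    if (any(counts == 0)) {
      # reference-profile eta: intercept + spatial effects
      eta_ref <- samples$coef[[fixed_nm]][d, 1]
      for (nm in spatial_terms) eta_ref <- eta_ref + samples$coef[[nm]][d, ]
      obs_mean[counts == 0] <- stats::plogis(eta_ref)[counts == 0]
    }
    prev[d, ] <- obs_mean
  }
  data.frame(region = seq_len(S), label = graph$labels, n = counts,
             prevalence = colMeans(prev),
             lower = apply(prev, 2, stats::quantile, 0.025),
             upper = apply(prev, 2, stats::quantile, 0.975),
             borrowed = counts == 0, stringsAsFactors = FALSE)
}

#' Per-region deviance map
#'
#' Aggregates outcomes to regions (`y_k` cut girls of `n_k`) and evaluates
#' the grouped deviance of [bernoulli_deviance()] at the posterior-mean
#' predicted prevalence: smaller values indicate a better local fit.
#'
#' @param samples a [run_mcmc()] result.
#' @param data the observation table.
#' @param graph the companion [adjacency_graph].
#' @return data frame `region`, `label`, `y`, `n`, `mu_hat`, `deviance`.
#' @export
deviance_map <- function(samples, data, graph) {
  pv <- predicted_prevalence(samples, data, graph)
  S <- graph$n_regions
  yk <- vapply(seq_len(S), function(s) sum(data$fgm[data$state == s]),
               numeric(1))
  nk <- pv$n
  keep <- nk > 0
  dv <- rep(NA_real_, S)
  dd <- bernoulli_deviance(yk[keep], nk[keep], pv$prevalence[keep])
  dv[keep] <- dd$contributions
  data.frame(region = seq_len(S), label = graph$labels, y = yk, n = nk,
             mu_hat = pv$prevalence, deviance = dv, stringsAsFactors = FALSE)
}

#' Classify regions by the significance of their spatial effect
#'
#' A region is `high` when the 2.5% posterior quantile of its spatial
#' effect is above zero, `low` when the 97.5% quantile is below zero, else
#' `nonsignificant` — the black/white/grey map convention. By default the
#' total spatial effect `f_str + f_unstr` is classified; set
#' `which = "structured"` for the MRF component alone.
#'
#' @param samples a [run_mcmc()] result with spatial terms.
#' @param level credible level (default 0.95).
#' @param which `"total"` or `"structured"`.
#' @return data frame `region`, `label`, `mean`, `lower`, `upper`, `class`.
#' @export
classify_spatial_effects <- function(samples, level = 0.95,
                                     which = c("total", "structured")) {
  which <- match.arg(which)
  if (!"f_str" %in% names(samples$terms)) stop("model has no spatial terms")
  eff <- samples$coef[["f_str"]]
  if (which == "total" && "f_unstr" %in% names(samples$terms)) {
    eff <- eff + samples$coef[["f_unstr"]]
  }
  alpha <- (1 - level) / 2
  lo <- apply(eff, 2, stats::quantile, alpha)
  hi <- apply(eff, 2, stats::quantile, 1 - alpha)
  cls <- ifelse(lo > 0, "high", ifelse(hi < 0, "low", "nonsignificant"))
  data.frame(region = seq_len(ncol(eff)), label = colnames(eff),
             mean = colMeans(eff), lower = lo, upper = hi, class = cls,
             stringsAsFactors = FALSE)
}

#' Weighted bivariate prevalence crosstab
#'
#' Survey-weighted prevalence of the outcome by the levels of one
#' categorical covariate, the "Number (%)" descriptive table: per level
#' the weighted count and the weighted percent cut. With all weights equal
#' it reduces exactly to the unweighted proportions.
#'
#' @param table observation table with an `fgm` column.
#' @param weights positive weights (defaults to the `weight` column, or 1s).
#' @param by covariate column name.
#' @return data frame `level`, `n_weighted`, `pct_cut`.
#' @export
weighted_prevalence_table <- function(table, weights = NULL, by) {
  if (!by %in% names(table)) {
    stop("unknown covariate '", by, "'; columns are: ",
         paste(names(table), collapse = ", "))
  }
  if (is.null(weights)) {
    weights <- if ("weight" %in% names(table)) table$weight
               else rep(1, nrow(table))
  }
  if (any(weights <= 0)) stop("weights must be positive")
  keep <- !is.na(table[[by]]) & !is.na(table$fgm)
  tb <- table[keep, , drop = FALSE]
  w <- weights[keep]
  levs <- sort(unique(as.character(tb[[by]])))
  out <- do.call(rbind, lapply(levs, function(l) {
    sel <- tb[[by]] == l
    data.frame(level = l, n_weighted = sum(w[sel]),
               pct_cut = 100 * sum(w[sel] * tb$fgm[sel]) / sum(w[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Percentage-point decline between two printed prevalence figures
#'
#' Convenience arithmetic for national headline comparisons, e.g. a fall
#' from 30.0% to 25.3% is a decline of 4.7 percentage points.
#'
#' @param from_pct earlier prevalence, in percent.
#' @param to_pct later prevalence, in percent.
#' @return the decline `from_pct - to_pct` in percentage points.
#' @export
prevalence_decline <- function(from_pct, to_pct) {
  from_pct - to_pct
}
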