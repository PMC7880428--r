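#' Global Moran's I spatial autocorrelation statistic
#'
#' With binary contiguity weights `w_rs = 1` iff regions r and s are
#' neighbours, centred values `z = x - mean(x)` and `W0 = sum(w)`:
#' \deqn{I = (S / W0) \sum_{r,s} w_{rs} z_r z_s / \sum_r z_r^2.}
#' Positive values indicate spatial clustering of like values, negative
#' values dispersion. The statistic is invariant to affine maps
#' `a*x + b`, `a > 0`.
#'
#' @param values per-region numeric vector (length `S`).
#' @param graph an [adjacency_graph] with at least one edge.
#' @return the Moran's I statistic (scalar).
#' @export
morans_i <- function(values, graph) {
  S <- graph$n_regions
  if (length(values) != S) stop("values must have length n_regions = ", S)
  if (!all(is.finite(values))) stop("values must be finite")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop("degenerate input: values are constant (zero variance)")
  W0 <- 2 * nrow(graph$edges)
  if (W0 == 0) stop("graph has no edges")
  cross <- 2 * sum(z[graph$edges[, 1]] * z[graph$edges[, 2]])
  (S / W0) * cross / ss
}

#' Moran's I clustering test
#'
#' Tests the null of no spatial autocorrelation. The analytic method uses
#' the normality approximation: `E[I] = -1/(S-1)` and the closed-form
#' normality variance for binary symmetric weights, with a one-sided
#' (greater, i.e. clustering) p-value by default. The Monte-Carlo method
#' permutes the region values and reports
#' `p = (1 + #{I_sim >= I_obs}) / (n_sims + 1)`, which can never be zero.
#'
#' @param values per-region numeric vector.
#' @param graph an [adjacency_graph].
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param n_sims permutation count for the Monte-Carlo method (>= 99).
#' @param seed optional integer seed for the permutations.
#' @param alternative `"greater"` (clustering, default), `"less"` or
#'   `"two.sided"` (analytic method only).
#' @return list with `statistic`, `expectation`, `p_value`, `method`, and
#'   for the analytic method `variance` and `z_score`.
#' @export
morans_i_test <- function(values, graph, method = c("analytic", "monte_carlo"),
                          n_sims = 999, seed = NULL,
                          alternative = c("greater", "less", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  S <- graph$n_regions
  I_obs <- morans_i(values, graph)
  EI <- -1 / (S - 1)
  if (method == "analytic") {
    # normality moments for symmetric binary weights
    W0 <- 2 * nrow(graph$edges)
    S1 <- 2 * W0                       # (1/2) sum (w_rs + w_sr)^2 = 4E
    S2 <- 4 * sum(graph$neighbor_counts^2)
    VI <- (S^2 * S1 - S * S2 + 3 * W0^2) / (W0^2 * (S^2 - 1)) - EI^2
    zsc <- (I_obs - EI) / sqrt(VI)
    p <- switch(alternative,
                greater = stats::pnorm(zsc, lower.tail = FALSE),
                less = stats::pnorm(zsc),
                two.sided = 2 * stats::pnorm(abs(zsc), lower.tail = FALSE))
    list(statistic = I_obs, expectation = EI, variance = VI,
         z_score = zsc, p_value = p, method = "analytic",
         alternative = alternative)
  } else {
    if (n_sims < 99) stop("n_sims must be >= 99 for the Monte-Carlo test")
    if (!is.null(seed)) set.seed(as.integer(seed))
    sims <- vapply(seq_len(n_sims), function(i) {
      morans_i(sample(values), graph)
    }, numeric(1))
    k <- switch(alternative,
                greater = sum(sims >= I_obs),
                less = sum(sims <= I_obs),
                two.sided = sum(abs(sims - EI) >= abs(I_obs - EI)))
    list(statistic = I_obs, expectation = EI,
         p_value = (1 + k) / (n_sims + 1), n_sims = n_sims,
         method = "monte_carlo", alternative = alternative)
  }
}
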