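#' MCMC sampler configuration
#'
#' The default schedule is 20,000 iterations, the first
#' 4,000 discarded as burn-in, every 20th of the remaining 16,000 retained
#' (800 stored draws), with diffuse inverse-gamma IG(a = 1, b = 0.0005)
#' hyperpriors on all variance parameters.
#'
#' @param n_iter total iterations.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw (>= 1).
#' @param a,b inverse-gamma hyperparameters (> 0).
#' @param seed integer RNG seed.
#' @param block_order optional character vector of term names fixing the
#'   update order (default: order of the term list, fixed block first).
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 20000, burn_in = 4000, thin = 20,
                        a = 1, b = 0.0005, seed = 1, block_order = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if (a <= 0 || b <= 0) stop("hyperparameters a, b must be > 0")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), a = a, b = b,
                 seed = as.integer(seed), block_order = block_order),
            class = "mcmc_config")
}

#' Number of post-burn-in draws a configuration retains
#'
#' With the default schedule this is 16,000 pre-thinning samples
#' and 800 stored draws (every 20th).
#'
#' @param config an [mcmc_config()].
#' @return list with `post_burn_in` (`n_iter - burn_in`) and `stored`
#'   (`floor(post_burn_in / thin)`).
#' @export
retained_draws <- function(config) {
  pb <- config$n_iter - config$burn_in
  list(post_burn_in = pb, stored = pb %/% config$thin)
}

#' IWLS working response and weights for the Bernoulli logit likelihood
#'
#' At linear predictor `eta`: `p = logit^-1(eta)`, weights
#' `w = p(1 - p)` floored at `eps`, working response
#' `ytilde = eta + (y - p) / w`. These are the quantities the Gaussian
#' Metropolis-Hastings proposal is built from.
#'
#' @param y binary outcome vector.
#' @param eta current linear predictor (finite).
#' @param eps floor on the weights (default 1e-6) preventing division
#'   blow-up at extreme `eta`.
#' @return list with `p`, `weights`, `working_response`.
#' @export
iwls_quantities <- function(y, eta, eps = 1e-6) {
  if (!all(is.finite(eta))) stop("eta must be finite")
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), eps)
  list(p = p, weights = w, working_response = eta + (y - p) / w)
}

# numerically stable Bernoulli log-likelihood sum(y*eta - log(1+e^eta))
bernoulli_loglik <- function(y, eta) {
  sum(y * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
}

# Cholesky with escalating jitter for near-singular proposal precisions
chol_jitter <- function(P, label = "block") {
  jit <- 0
  for (k in 0:6) {
    R <- tryCatch(chol(P + diag(jit, nrow(P))), error = function(e) NULL)
    if (!is.null(R)) {
      if (k > 0) warning("proposal precision for ", label,
                         " jittered by ", jit, call. = FALSE)
      return(R)
    }
    jit <- if (jit == 0) 1e-8 * mean(diag(P)) else jit * 100
  }
  stop("proposal precision for ", label, " is singular beyond repair")
}

# Gaussian proposal N(m, P^{-1}) built from the IWLS approximation at the
# current state (success probabilities `p` precomputed from eta), using the
# partial residual for this block. For one-hot designs (`index` set) X'WX
# is diagonal and the grouped sums go through one sparse crossprod each.
iwls_proposal <- function(X, Kot, y, p, beta, index = NULL, grp = NULL,
                          diag_penalty = FALSE) {
  w <- pmax(p * (1 - p), 1e-6)
  if (!is.null(index)) {
    wr <- w * beta[index] + (y - p)
    d <- as.numeric(Matrix::crossprod(X, w))
    b <- as.numeric(Matrix::crossprod(X, wr))
    if (diag_penalty) {
      # P is diagonal: identity penalty + one-hot design
      dP <- d + Kot
      R <- sqrt(dP)
      return(list(R = R, m = b / dP, diagonal = TRUE))
    }
    P <- diag(d, length(beta))
  } else if (!is.null(grp)) {
    # design factorises as G Xu with G one-hot over distinct rows:
    # X'WX = Xu' diag(G'w) Xu, X'v = Xu' G'v
    Xb <- (grp$unique_design %*% beta)[grp$index]
    wr <- w * Xb + (y - p)
    wg <- as.numeric(Matrix::crossprod(grp$G, w))
    P <- crossprod(grp$unique_design, wg * grp$unique_design)
    b <- as.numeric(crossprod(grp$unique_design,
                              as.numeric(Matrix::crossprod(grp$G, wr))))
  } else {
    Xb <- as.numeric(X %*% beta)
    wr <- w * Xb + (y - p)
    P <- as.matrix(Matrix::crossprod(X, w * X))
    b <- as.numeric(Matrix::crossprod(X, wr))
  }
  if (!is.null(Kot)) P <- P + Kot
  R <- chol_jitter(P)
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  list(R = R, m = m, diagonal = FALSE)
}

# log N(x; m, P^{-1}) with P = R'R (constants kept; they cancel in the MH
# ratio only because forward and reverse densities share the dimension)
dmvn_prec_log <- function(x, prop) {
  if (isTRUE(prop$diagonal)) {
    v <- prop$R * (x - prop$m)
    sum(log(prop$R)) - 0.5 * sum(v^2) - 0.5 * length(x) * log(2 * pi)
  } else {
    v <- prop$R %*% (x - prop$m)
    sum(log(diag(prop$R))) - 0.5 * sum(v^2) -
      0.5 * length(x) * log(2 * pi)
  }
}

#' One Metropolis-Hastings update of a coefficient block
#'
#' Proposes from the Gaussian IWLS approximation `N(m, P^{-1})` with
#' `P = X'WX + K/tau2` built at the current state, and accepts with the
#' exact MH ratio under the Bernoulli likelihood and the (improper)
#' Gaussian penalty prior; fixed-effect blocks use a flat prior (`K = 0`).
#' The reverse proposal density is evaluated from the IWLS approximation
#' rebuilt at the proposed state (Gamerman's scheme).
#'
#' @param term a `model_term`.
#' @param beta current coefficients of the block.
#' @param y binary outcomes.
#' @param eta current full linear predictor (consistent with `beta`).
#' @param tau2 block variance (ignored for fixed terms).
#' @param loglik current `bernoulli_loglik(y, eta)`, if already known.
#' @param p current success probabilities `plogis(eta)`, if already known.
#' @return list with `beta`, `eta`, `accepted`, and `loglik` / `p` of the
#'   returned state.
#' @export
update_coefficient_block <- function(term, beta, y, eta, tau2 = NULL,
                                     loglik = NULL, p = NULL) {
  X <- term$design
  K <- if (term$kind == "fixed") NULL else term$penalty$matrix
  diag_pen <- !is.null(term$index) && !is.null(term$penalty) &&
    term$penalty$kind == "identity"
  Kot <- if (is.null(K)) NULL else if (diag_pen) 1 / tau2 else K / tau2
  logprior <- function(b) {
    if (is.null(K)) 0
    else if (diag_pen) -0.5 / tau2 * sum(b^2)
    else -0.5 / tau2 * sum(b * (K %*% b))
  }
  if (is.null(p)) p <- stats::plogis(eta)
  if (is.null(loglik)) loglik <- bernoulli_loglik(y, eta)
  fwd <- iwls_proposal(X, Kot, y, p, beta, index = term$index,
                       grp = term$grp, diag_penalty = diag_pen)
  z <- stats::rnorm(length(beta))
  beta1 <- if (fwd$diagonal) fwd$m + z / fwd$R
           else drop(fwd$m + backsolve(fwd$R, z))
  eta1 <- if (!is.null(term$index)) {
    eta + (beta1 - beta)[term$index]
  } else if (!is.null(term$grp)) {
    eta + (term$grp$unique_design %*% (beta1 - beta))[term$grp$index]
  } else {
    eta + as.numeric(X %*% (beta1 - beta))
  }
  p1 <- stats::plogis(eta1)
  rev <- iwls_proposal(X, Kot, y, p1, beta1, index = term$index,
                       grp = term$grp, diag_penalty = diag_pen)
  ll1 <- bernoulli_loglik(y, eta1)
  log_alpha <- (ll1 + logprior(beta1) + dmvn_prec_log(beta, rev)) -
    (loglik + logprior(beta) + dmvn_prec_log(beta1, fwd))
  if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
    list(beta = beta1, eta = eta1, accepted = TRUE, loglik = ll1, p = p1)
  } else {
    list(beta = beta, eta = eta, accepted = FALSE, loglik = loglik, p = p)
  }
}

#' Gibbs update of a block variance parameter
#'
#' The inverse-gamma prior IG(a, b) is conjugate to the Gaussian penalty
#' prior, giving the full conditional
#' `tau2 | beta ~ IG(a + rank(K)/2, b + beta'K beta / 2)`.
#'
#' @param beta current block coefficients.
#' @param penalty the block's [penalty_matrix].
#' @param a,b inverse-gamma hyperparameters.
#' @return one draw of `tau2`.
#' @export
update_variance <- function(beta, penalty, a = 1, b = 0.0005) {
  qf <- sum(beta * (penalty$matrix %*% beta))
  if (qf < -1e-8) stop("negative quadratic form: penalty matrix is not PSD")
  shape <- a + penalty$rank / 2
  rate <- b + max(qf, 0) / 2
  1 / stats::rgamma(1, shape = shape, rate = rate)
}

#' Run the MH-IWLS sampler on a structured additive logit model
#'
#' One iteration sweeps the coefficient blocks in fixed order
#' (fixed effects, then each smooth/spatial/interaction term), re-centres
#' every non-fixed block after its update (absorbing the mean into the
#' intercept, which leaves the likelihood untouched), then draws every
#' block variance from its conjugate inverse-gamma full conditional.
#'
#' @param data complete-case observation table (after [listwise_delete()]).
#' @param terms term list from [build_model_terms()].
#' @param config an [mcmc_config()].
#' @param y_col outcome column (default `"fgm"`).
#' @param verbose print progress milestones.
#' @return an object of class `posterior_samples`: per-term coefficient
#'   draw matrices (`draws x M`), variance draws, per-draw deviance
#'   (`-2 log L`), per-block acceptance rates, the term list and config.
#' @export
run_mcmc <- function(data, terms, config = mcmc_config(), y_col = "fgm",
                     verbose = FALSE) {
  y <- data[[y_col]]
  if (is.null(y) || !all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  n <- length(y)
  for (tm in terms) {
    if (nrow(tm$design) != n) stop("design rows != data rows for term ", tm$name)
  }
  set.seed(config$seed)
  tnames <- vapply(terms, `[[`, "", "name")
  order_ <- if (is.null(config$block_order)) tnames else config$block_order
  if (!setequal(order_, tnames)) stop("block_order must permute the term names")
  penalized <- tnames[vapply(terms, function(t) t$kind != "fixed", TRUE)]
  fixed_name <- tnames[vapply(terms, function(t) t$kind == "fixed", TRUE)]
  has_fixed <- length(fixed_name) == 1

  beta <- lapply(terms, function(t) numeric(ncol(t$design)))
  names(beta) <- tnames
  tau2 <- stats::setNames(rep(0.1, length(penalized)), penalized)
  eta <- numeric(n)

  rd <- retained_draws(config)
  n_store <- rd$stored
  coef_draws <- lapply(terms, function(t)
    matrix(NA_real_, n_store, ncol(t$design),
           dimnames = list(NULL, t$colnames)))
  names(coef_draws) <- tnames
  tau2_draws <- matrix(NA_real_, n_store, length(penalized),
                       dimnames = list(NULL, penalized))
  deviance <- numeric(n_store)
  acc <- stats::setNames(numeric(length(tnames)), tnames)

  stored <- 0L
  ll <- bernoulli_loglik(y, eta)
  pcur <- stats::plogis(eta)
  for (it in seq_len(config$n_iter)) {
    for (nm in order_) {
      tm <- terms[[nm]]
      up <- update_coefficient_block(tm, beta[[nm]], y, eta,
                                     tau2 = if (tm$kind == "fixed") NULL
                                            else tau2[[nm]],
                                     loglik = ll, p = pcur)
      beta[[nm]] <- up$beta
      eta <- up$eta
      ll <- up$loglik
      pcur <- up$p
      acc[nm] <- acc[nm] + up$accepted
      if (!all(is.finite(eta))) {
        stop("non-finite linear predictor after updating block '", nm, "'")
      }
      if (tm$kind != "fixed" && has_fixed) {
        ct <- apply_centering(tm, beta[[nm]])
        beta[[nm]] <- ct$coefficients
        beta[[fixed_name]][1] <- beta[[fixed_name]][1] + ct$intercept_shift
      }
    }
    for (nm in penalized) {
      tau2[[nm]] <- update_variance(beta[[nm]], terms[[nm]]$penalty,
                                    a = config$a, b = config$b)
    }
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0 &&
        stored < n_store) {
      stored <- stored + 1L
      for (nm in tnames) coef_draws[[nm]][stored, ] <- beta[[nm]]
      tau2_draws[stored, ] <- tau2
      deviance[stored] <- -2 * ll
    }
    if (verbose && it %% 1000 == 0) {
      message("iteration ", it, "/", config$n_iter)
    }
  }
  structure(list(coef = coef_draws, tau2 = tau2_draws, deviance = deviance,
                 accept_rate = acc / config$n_iter, n_draws = stored,
                 terms = terms, config = config, n_obs = n),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %d stored draws, %d observations\n",
              x$n_draws, x$n_obs))
  cat("acceptance rates:\n")
  print(round(x$accept_rate, 3))
  invisible(x)
}

# reconstruct the linear predictor for one stored draw (or from a
# coefficient list) by summing X_j beta_j over terms
eta_from_coefs <- function(samples, draw = NULL, coefs = NULL) {
  terms <- samples$terms
  eta <- numeric(samples$n_obs)
  for (nm in names(terms)) {
    b <- if (is.null(coefs)) samples$coef[[nm]][draw, ] else coefs[[nm]]
    eta <- eta + as.numeric(terms[[nm]]$design %*% b)
  }
  eta
}
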