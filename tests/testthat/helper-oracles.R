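# Independent oracles used across the test files. These deliberately take
# the slow, direct route (recursions, loops, enumeration) so they share no
# code path with the implementation they check.

# Cox-de Boor recursion for a single B-spline basis function B_{i,k}(x)
# over knot vector `kn` (degree k, 0-based i)
cox_de_boor <- function(x, i, k, kn) {
  if (k == 0) {
    # half-open intervals: callers evaluate at interior points only
    return(as.numeric(x >= kn[i + 1] & x < kn[i + 2]))
  }
  d1 <- kn[i + k + 1] - kn[i + 1]
  d2 <- kn[i + k + 2] - kn[i + 2]
  t1 <- if (d1 > 0) (x - kn[i + 1]) / d1 * cox_de_boor(x, i, k - 1, kn) else 0
  t2 <- if (d2 > 0) (kn[i + k + 2] - x) / d2 * cox_de_boor(x, i + 1, k - 1, kn) else 0
  t1 + t2
}

# all permutations of 1..n (for exhaustive Moran permutation tests, n <= 6)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# dense pseudo-inverse restricted to the non-null eigenspace
pseudo_inverse <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  e$vectors[, keep] %*% diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep])
}

# tiny two-column logit dataset used by the sampler oracle tests
make_small_logit_data <- function(n = 200, b0 = -0.4, b1 = 0.9, seed = 42) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  eta <- b0 + b1 * x
  data.frame(
    fgm = rbinom(n, 1, plogis(eta)),
    state = 1L,
    x1 = ifelse(x == 1, "B", "A"),
    stringsAsFactors = FALSE)
}

# fixed-effects-only term list (intercept + one dummy) over a 1-region graph
small_logit_terms <- function(data) {
  g1 <- adjacency_graph(1, matrix(integer(0), ncol = 2))
  spec <- model_spec(spatial = FALSE, year_smooth = FALSE,
                     age_smooth = FALSE, covariates = "x1",
                     references = list(x1 = "A"))
  list(graph = g1, terms = build_model_terms(data, g1, spec))
}

# dense-grid numerical posterior (flat priors) for the 2-coefficient logit
# model: returns mean and sd of (b0, b1) by 2-D Riemann sum
grid_posterior_2par <- function(y, x, half_width = 6, n_grid = 161) {
  fit <- glm(y ~ x, family = binomial())
  ctr <- coef(fit); se <- sqrt(diag(vcov(fit)))
  b0s <- seq(ctr[1] - half_width * se[1], ctr[1] + half_width * se[1],
             length.out = n_grid)
  b1s <- seq(ctr[2] - half_width * se[2], ctr[2] + half_width * se[2],
             length.out = n_grid)
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta) - sum(log1p(exp(eta)))
  }
  ll <- outer(b0s, b1s, Vectorize(loglik))
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  m0 <- sum(rowSums(post) * b0s)
  m1 <- sum(colSums(post) * b1s)
  s0 <- sqrt(sum(rowSums(post) * (b0s - m0)^2))
  s1 <- sqrt(sum(colSums(post) * (b1s - m1)^2))
  list(mean = c(m0, m1), sd = c(s0, s1))
}
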