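# small helper: hand-built posterior_samples object over given terms/draws
fake_samples <- function(terms, coef, n_obs) {
  structure(list(coef = coef, tau2 = NULL,
                 deviance = rep(NA_real_, nrow(coef[[1]])),
                 n_draws = nrow(coef[[1]]), terms = terms,
                 config = mcmc_config(n_iter = 10, burn_in = 1, thin = 1),
                 n_obs = n_obs),
            class = "posterior_samples")
}

test_that("grouped deviance matches direct substitution and the likelihood
           identity", {
  # saturated fit
  expect_equal(bernoulli_deviance(c(2, 5), c(4, 10), c(0.5, 0.5))$total, 0)
  # single Bernoulli at mu = 0.5: 2 log 2
  expect_equal(bernoulli_deviance(1, 1, 0.5)$total, 2 * log(2),
               tolerance = 1e-12)
  # random grouped table vs -2 (loglik - saturated loglik)
  set.seed(3)
  n <- c(7, 12, 30, 5)
  mu <- runif(4, 0.1, 0.9)
  y <- rbinom(4, n, 0.6)
  dd <- bernoulli_deviance(y, n, mu)
  ll <- function(p) sum(dbinom(y, n, p, log = TRUE))
  p_sat <- pmin(pmax(y / n, 1e-12), 1 - 1e-12)
  expect_equal(dd$total, -2 * (ll(mu) - ll(p_sat)), tolerance = 1e-6)
  expect_equal(sum(dd$contributions), dd$total)
  expect_error(bernoulli_deviance(1, 1, 1), "deviance|mu_hat")
  expect_error(bernoulli_deviance(3, 2, 0.5), "y <= n")
})

test_that("DIC decomposes as d_bar + p_d and matches a conjugate oracle", {
  # degenerate posterior: all draws identical => p_d = 0, dic = d_bar
  d <- make_small_logit_data(n = 80, seed = 9)
  st <- small_logit_terms(d)
  fit <- run_mcmc(d, st$terms["fixed"], mcmc_config(n_iter = 60,
                                                    burn_in = 20, thin = 1,
                                                    seed = 1))
  fit$coef$fixed <- matrix(rep(c(0.3, -0.2), each = 40), 40, 2,
                           dimnames = dimnames(fit$coef$fixed))
  eta_fix <- starlogit:::eta_from_coefs(fit, coefs = list(fixed = c(0.3, -0.2)))
  fit$deviance <- rep(-2 * starlogit:::bernoulli_loglik(d$fgm, eta_fix), 40)
  dd <- dic(fit, d)
  expect_equal(dd$p_d, 0, tolerance = 1e-9)
  expect_equal(dd$dic, dd$d_bar, tolerance = 1e-9)
  expect_equal(dd$dic, dd$d_bar + dd$p_d)

  # intercept-only model: flat prior on the logit => analytic posterior
  # Beta(s, n - s) on p; DIC computable by numerical integration
  set.seed(11)
  y <- rbinom(150, 1, 0.35)
  dd2 <- data.frame(fgm = y, state = 1L,
                    x1 = rep("A", 150), stringsAsFactors = FALSE)
  g1 <- adjacency_graph(1, matrix(integer(0), ncol = 2))
  spec <- model_spec(spatial = FALSE, year_smooth = FALSE,
                     age_smooth = FALSE)
  terms <- build_model_terms(dd2, g1, spec)
  fit2 <- run_mcmc(dd2, terms, mcmc_config(n_iter = 6000, burn_in = 1000,
                                           thin = 1, seed = 2))
  got <- dic(fit2, dd2)
  s <- sum(y); n <- length(y)
  dev_p <- function(p) -2 * (s * log(p) + (n - s) * log(1 - p))
  d_bar_oracle <- integrate(function(p) dev_p(p) * dbeta(p, s, n - s),
                            1e-6, 1 - 1e-6)$value
  # d_at_mean uses the posterior mean of eta = logit(p)
  eta_bar <- integrate(function(p) qlogis(p) * dbeta(p, s, n - s),
                       1e-6, 1 - 1e-6)$value
  d_hat_oracle <- dev_p(plogis(eta_bar))
  dic_oracle <- 2 * d_bar_oracle - d_hat_oracle
  expect_lt(abs(got$dic - dic_oracle), 0.6)
  expect_lt(abs(got$p_d - (d_bar_oracle - d_hat_oracle)), 0.35)
})

test_that("posterior odds ratios summarise exp(beta) with reference rows at
           1.00", {
  d <- make_small_logit_data(n = 60, seed = 5)
  st <- small_logit_terms(d)
  fit <- run_mcmc(d, st$terms["fixed"], mcmc_config(n_iter = 40,
                                                    burn_in = 10, thin = 1,
                                                    seed = 1))
  # all-zero draws: POR exactly 1 with unit interval
  fit$coef$fixed[] <- 0
  por0 <- posterior_odds_ratios(fit)
  expect_equal(por0$por[!por0$reference], 1)
  expect_equal(por0$lower[!por0$reference], 1)
  expect_equal(por0$por[por0$reference], 1)
  expect_true(is.na(por0$upper[por0$reference]))

  # lognormal oracle: draws ~ N(log 2, 0.01^2)
  set.seed(6)
  nfit <- fit
  nfit$coef$fixed <- cbind(`(Intercept)` = rep(0, 5000),
                           `x1:B` = rnorm(5000, log(2), 0.01))
  por <- posterior_odds_ratios(nfit)
  row <- por[por$level == "B", ]
  expect_equal(row$por, 2 * exp(0.01^2 / 2), tolerance = 0.001)
  expect_equal(row$lower, 2 * exp(qnorm(0.025) * 0.01), tolerance = 0.001)
  expect_equal(row$upper, 2 * exp(qnorm(0.975) * 0.01), tolerance = 0.001)

  expect_error(posterior_odds_ratios(fit, "f_str"), "not a fixed")
})

test_that("predicted prevalence back-transforms and responds monotonically", {
  g <- make_lattice_graph(2, 2)
  set.seed(8)
  d <- data.frame(fgm = rbinom(40, 1, 0.5),
                  state = rep(1:4, each = 10), stringsAsFactors = FALSE)
  X <- starlogit:::indicator_design(d$state, 4, labels = g$labels)
  terms <- list(
    fixed = local({
      tm <- model_term("fixed", "fixed",
                       methods::as(matrix(1, 40, 1,
                                          dimnames = list(NULL, "(Intercept)")),
                                   "CsparseMatrix"))
      tm$meta <- data.frame(column = "(Intercept)",
                            covariate = "(Intercept)",
                            level = "(Intercept)")
      tm$references <- list()
      tm
    }),
    f_str = model_term("f_str", "mrf", X, penalty = mrf_precision(g)))
  coef <- list(fixed = matrix(0, 20, 1,
                              dimnames = list(NULL, "(Intercept)")),
               f_str = matrix(0, 20, 4, dimnames = list(NULL, g$labels)))
  smp <- fake_samples(terms, coef, 40)
  pv <- predicted_prevalence(smp, d, g)
  expect_equal(pv$prevalence, rep(0.5, 4))
  expect_false(any(pv$borrowed))

  smp2 <- smp
  smp2$coef$fixed[] <- 1.2
  pv2 <- predicted_prevalence(smp2, d, g)
  expect_true(all(pv2$prevalence > pv$prevalence))

  # unobserved region: flagged borrowed, estimated at the reference profile
  d3 <- d[d$state != 4, ]
  X3 <- starlogit:::indicator_design(d3$state, 4, labels = g$labels)
  terms3 <- terms
  terms3$fixed$design <- terms$fixed$design[1:30, , drop = FALSE]
  terms3$f_str <- model_term("f_str", "mrf", X3, penalty = mrf_precision(g))
  smp3 <- fake_samples(terms3, coef, 30)
  pv3 <- predicted_prevalence(smp3, d3, g)
  expect_true(pv3$borrowed[4])
  expect_equal(pv3$prevalence[4], 0.5)

  # deviance map contributions sum to the grouped total
  dm <- deviance_map(smp, d, g)
  dd <- bernoulli_deviance(dm$y, dm$n, dm$mu_hat)
  expect_equal(sum(dm$deviance), dd$total)
})

test_that("spatial significance classes follow the credible-interval rule", {
  g <- make_lattice_graph(1, 3)
  X <- starlogit:::indicator_design(rep(1:3, each = 5), 3, labels = g$labels)
  terms <- list(f_str = model_term("f_str", "mrf", X,
                                   penalty = mrf_precision(g)))
  set.seed(12)
  draws <- cbind(abs(rnorm(400)) + 0.01,      # strictly positive
                 -abs(rnorm(400)) - 0.01,     # strictly negative
                 rnorm(400))                  # symmetric around 0
  colnames(draws) <- g$labels
  smp <- fake_samples(terms, list(f_str = draws), 15)
  cls <- classify_spatial_effects(smp, which = "structured")
  expect_equal(cls$class, c("high", "low", "nonsignificant"))
})

test_that("weighted crosstabs match unweighted proportions and a
           row-replication oracle", {
  set.seed(14)
  d <- data.frame(fgm = rbinom(300, 1, 0.3),
                  residence = sample(c("Rural", "Urban"), 300, TRUE),
                  stringsAsFactors = FALSE)
  t1 <- weighted_prevalence_table(d, rep(1, 300), by = "residence")
  for (l in t1$level) {
    sel <- d$residence == l
    expect_equal(t1$pct_cut[t1$level == l], 100 * mean(d$fgm[sel]))
    expect_equal(t1$n_weighted[t1$level == l], sum(sel))
  }

  # doubling the weight of urban rows == physically duplicating those rows
  w <- ifelse(d$residence == "Urban", 2, 1)
  t2 <- weighted_prevalence_table(d, w, by = "residence")
  d_exp <- rbind(d, d[d$residence == "Urban", ])
  t3 <- weighted_prevalence_table(d_exp, rep(1, nrow(d_exp)),
                                  by = "residence")
  expect_equal(t2$pct_cut, t3$pct_cut)
  expect_equal(t2$n_weighted, t3$n_weighted)

  expect_error(weighted_prevalence_table(d, w, by = "nope"), "unknown")
  expect_equal(prevalence_decline(30.0, 25.3), 4.7)
})

test_that("model suite handles empty, duplicate and single-year inputs", {
  g <- make_lattice_graph(2, 2)
  tr <- draw_truth(g, seed = 1)
  d <- simulate_dataset(tr, g, n_mothers = 200, seed = 2)

  empty <- fit_model_suite(d, g, models = character(0))
  expect_equal(nrow(empty), 0)
  expect_error(fit_model_suite(d, g, models = c("m1", "m1")), "duplicate")
  expect_error(fit_model_suite(d, g, models = "m9"), "unknown")

  d1y <- d[d$year == d$year[1], ]
  expect_error(build_model_terms(d1y, g, model_spec()), "starred")
})
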