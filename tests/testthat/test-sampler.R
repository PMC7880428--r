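test_that("IWLS quantities follow the closed forms and the defining
           identity", {
  q1 <- iwls_quantities(1, 0)
  expect_equal(q1$weights, 0.25)
  expect_equal(q1$working_response, 2)
  q0 <- iwls_quantities(0, 0)
  expect_equal(q0$working_response, -2)

  set.seed(17)
  y <- rbinom(50, 1, 0.5)
  eta <- rnorm(50, 0, 2)
  q <- iwls_quantities(y, eta)
  # w*ytilde + p - y - eta*w = 0 elementwise
  expect_equal(q$weights * q$working_response + q$p - y - eta * q$weights,
               rep(0, 50), tolerance = 1e-12)
  # extreme eta: weights floored, nothing blows up
  qq <- iwls_quantities(c(0, 1), c(-40, 40))
  expect_true(all(is.finite(qq$working_response)))
  expect_error(iwls_quantities(1, Inf), "finite")
})

test_that("variance full conditional has the conjugate IG moments and uses
           the penalty rank", {
  # beta = 0: tau2 ~ IG(a + rank/2, b), mean b / (a + rank/2 - 1)
  K <- identity_penalty(4)
  set.seed(23)
  draws <- replicate(20000, update_variance(rep(0, 4), K, a = 3, b = 2))
  expect_equal(mean(draws), 2 / (3 + 2 - 1), tolerance = 0.03)

  # rank of the ICAR penalty on a connected 36-region graph is 35
  K36 <- mrf_precision(make_lattice_graph(6, 6))
  ev <- eigen(K36$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-8), 35)
  expect_equal(K36$rank, 35L)

  # beta'Kbeta enters the rate: large coefficients shrink tau2 upward
  set.seed(24)
  b_big <- rnorm(4, sd = 10)
  d2 <- replicate(5000, update_variance(b_big, K, a = 3, b = 2))
  expect_gt(mean(d2), mean(draws))
})

test_that("sampler is deterministic under a seed and recovers an
           intercept-only posterior", {
  d <- make_small_logit_data(n = 120, b0 = 0, b1 = 0, seed = 31)
  d$fgm <- rep(c(0, 1), 60)  # exactly balanced
  g1 <- adjacency_graph(1, matrix(integer(0), ncol = 2))
  ispec <- model_spec(spatial = FALSE, year_smooth = FALSE,
                      age_smooth = FALSE)  # intercept only
  iterms <- build_model_terms(d, g1, ispec)
  cfg <- mcmc_config(n_iter = 1500, burn_in = 500, thin = 1, seed = 7)
  fit <- run_mcmc(d, iterms, cfg)
  # balanced outcome: posterior of the intercept centred at 0
  b0_draws <- fit$coef$fixed[, 1]
  expect_lt(abs(mean(b0_draws)), 3 * sd(b0_draws) / sqrt(50))

  fit2 <- run_mcmc(d, iterms, cfg)
  expect_identical(fit$coef, fit2$coef)
  expect_identical(fit$deviance, fit2$deviance)

  cfg2 <- mcmc_config(n_iter = 1500, burn_in = 500, thin = 1, seed = 8)
  fit3 <- run_mcmc(d, iterms, cfg2)
  expect_false(identical(fit$coef$fixed, fit3$coef$fixed))
  # different seeds agree within Monte-Carlo error
  expect_lt(abs(mean(fit3$coef$fixed[, 1]) - mean(b0_draws)), 0.15)
})

test_that("a tiny prior variance shrinks a smooth block toward zero", {
  set.seed(43)
  n <- 400
  age <- sample(15:49, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(0.8 * sin(age / 5)))
  bb <- bspline_basis(age, n_interior_knots = 8)
  tm <- model_term("f(age)", "pspline",
                   methods::as(bb$design, "CsparseMatrix"),
                   penalty = rw2_penalty(bb$basis$n_basis))
  run_chain <- function(tau2) {
    b <- numeric(ncol(bb$design))
    eta <- numeric(n)
    set.seed(3)
    for (i in 1:60) {
      up <- update_coefficient_block(tm, b, y, eta, tau2 = tau2)
      b <- up$beta; eta <- up$eta
    }
    max(abs(as.numeric(bb$design %*% b) - mean(bb$design %*% b)))
  }
  # RW2 null space (linear trends) is unpenalised, so shrinkage acts on
  # the curvature: the tightly-shrunk fit is flatter than the loose one
  expect_gt(run_chain(10), run_chain(1e-9))
})

test_that("schedule bookkeeping matches the reference design", {
  cfg <- mcmc_config()
  rd <- retained_draws(cfg)
  expect_equal(rd$post_burn_in, 16000)
  expect_equal(rd$stored, 800)
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(mcmc_config(a = 0), "hyperparameters")
})

test_that("full model runs end to end with centred spatial blocks and sane
           acceptance", {
  g <- make_lattice_graph(3, 3)
  tr <- draw_truth(g, seed = 2)
  d <- simulate_dataset(tr, g, n_mothers = 500, seed = 3)
  spec <- model_spec(survey = TRUE, covariates = c("education", "mother_cut"),
                     interaction = "iid", n_knots = 6)
  terms <- build_model_terms(d, g, spec)
  fit <- run_mcmc(d, terms, mcmc_config(n_iter = 300, burn_in = 100,
                                        thin = 2, seed = 5))
  expect_equal(fit$n_draws, 100)
  expect_true(all(fit$accept_rate > 0.2 & fit$accept_rate <= 1))
  # every stored non-fixed draw is centred over the observed design rows
  for (nm in c("f_str", "f_unstr", "xi")) {
    tm <- terms[[nm]]
    fitted_means <- apply(fit$coef[[nm]], 1, function(b)
      mean(as.numeric(tm$design %*% b)))
    expect_equal(fitted_means, rep(0, 100), tolerance = 1e-10)
  }
})
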