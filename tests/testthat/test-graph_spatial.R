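test_that("edge-list and .gra readers agree and validate their input", {
  el <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# path graph", "R1 R2", "R2 R3"), el)
  g <- read_graph(el, "edge_list", labels = c("R1", "R2", "R3"))
  expect_equal(g$n_regions, 3)
  expect_equal(g$neighbor_counts, c(1, 2, 1))

  gra <- withr::local_tempfile(fileext = ".gra")
  writeLines(c("3", "R1", "1", "2", "R2", "2", "1 3", "R3", "1", "2"), gra)
  g2 <- read_graph(gra, "gra")
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$labels, g$labels)
  expect_equal(g2$neighbor_counts, g$neighbor_counts)

  # round-trips are lossless in both dialects
  for (dial in c("edge_list", "gra")) {
    f <- withr::local_tempfile()
    write_graph(g, f, dial)
    gr <- read_graph(f, dial, labels = if (dial == "edge_list") g$labels)
    expect_equal(gr$edges, g$edges)
  }

  loop <- withr::local_tempfile()
  writeLines("2 2", loop)
  expect_error(read_graph(loop, "edge_list"), "self-loop")
  asym <- withr::local_tempfile()
  writeLines(c("2", "A", "1", "2", "B", "0", ""), asym)
  expect_error(read_graph(asym, "gra"), "asymmetric")
  expect_error(adjacency_graph(3, rbind(c(1, 4))), "out of range")
  expect_error(adjacency_graph(3, rbind(c(2, 2))), "self-loop")
})

test_that("MRF precision is the graph Laplacian with ICAR structure", {
  g2 <- adjacency_graph(2, rbind(c(1, 2)))
  K2 <- mrf_precision(g2)
  expect_equal(unname(K2$matrix), rbind(c(1, -1), c(-1, 1)))
  expect_equal(K2$rank, 1L)

  g3 <- adjacency_graph(3, rbind(c(1, 2), c(2, 3)))
  K3 <- mrf_precision(g3)
  expect_equal(unname(K3$matrix),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  expect_equal(K3$rank, 2L)

  # general ICAR properties + pairwise-difference identity on a lattice
  g <- make_lattice_graph(4, 5)
  K <- mrf_precision(g)
  expect_equal(unname(rowSums(K$matrix)), rep(0, 20))
  ev <- eigen(K$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_equal(sum(ev > 1e-10), K$rank)
  set.seed(7)
  for (i in 1:5) {
    b <- rnorm(20)
    qf_edges <- sum((b[g$edges[, 1]] - b[g$edges[, 2]])^2)
    expect_equal(drop(t(b) %*% K$matrix %*% b), qf_edges, tolerance = 1e-10)
  }
})

test_that("ICAR conditionals are neighbour averages with variance tau2/N_s", {
  g <- make_lattice_graph(3, 3)
  K <- mrf_precision(g)$matrix
  tau2 <- 0.7
  nbr <- starlogit:::neighbor_list(g)
  set.seed(11)
  f <- rnorm(9)
  for (s in 1:9) {
    cond_mean <- -sum(K[s, -s] * f[-s]) / K[s, s]
    expect_equal(cond_mean, mean(f[nbr[[s]]]), tolerance = 1e-12)
    expect_equal(tau2 / K[s, s], tau2 / g$neighbor_counts[s])
  }
})

test_that("intrinsic GMRF draws honour the sum-to-zero constraint and
           covariance tau2 * pinv(K)", {
  g2 <- adjacency_graph(2, rbind(c(1, 2)))
  d2 <- sample_igmrf(g2, tau2 = 1, n_draws = 50, seed = 1)
  expect_equal(unname(d2[, 1]), unname(-d2[, 2]), tolerance = 1e-12)

  g <- make_lattice_graph(6, 6)
  draws <- sample_igmrf(g, tau2 = 0.8, n_draws = 20000, seed = 2)
  expect_equal(unname(rowSums(draws)), rep(0, 20000), tolerance = 1e-8)
  emp <- cov(draws)
  theo <- 0.8 * pseudo_inverse(mrf_precision(g)$matrix)
  # entrywise Monte-Carlo tolerance ~ 6 * sd of a covariance estimate
  tol <- 6 * sqrt((outer(diag(theo), diag(theo)) + theo^2) / 20000)
  expect_true(all(abs(emp - theo) < tol + 1e-8))

  disc <- adjacency_graph(4, rbind(c(1, 2), c(3, 4)))
  expect_error(sample_igmrf(disc, 1, 1, 1), "disconnected")
})

test_that("Moran's I matches hand-evaluated cases and is affine-invariant", {
  g2 <- adjacency_graph(2, rbind(c(1, 2)))
  expect_equal(morans_i(c(1, -1), g2), -1)

  # 2x2 rook lattice, checkerboard +1/-1: all 8 directed edge products -1
  g4 <- make_lattice_graph(2, 2)
  expect_equal(morans_i(c(1, -1, -1, 1), g4), -1)

  expect_error(morans_i(rep(3, 4), g4), "constant")

  g <- make_lattice_graph(3, 3)
  set.seed(5)
  x <- rnorm(9)
  expect_equal(morans_i(2.5 * x + 7, g), morans_i(x, g), tolerance = 1e-12)
})

test_that("Moran tests: analytic null mean and Monte-Carlo vs exhaustive
           permutations", {
  g <- adjacency_graph(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  set.seed(3)
  x <- rnorm(5)
  at <- morans_i_test(x, g, "analytic")
  expect_equal(at$expectation, -1 / 4)

  # exhaustive permutation distribution (5! = 120) as the oracle
  I_obs <- morans_i(x, g)
  perms <- all_perms(5)
  I_all <- apply(perms, 1, function(pm) morans_i(x[pm], g))
  p_exact <- mean(I_all >= I_obs - 1e-12)
  mc <- morans_i_test(x, g, "monte_carlo", n_sims = 4999, seed = 9)
  expect_lt(abs(mc$p_value - p_exact), 0.03)
  expect_gt(mc$p_value, 0)
})
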