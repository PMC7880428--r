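#' Rook-contiguity lattice graph
#'
#' A rows x cols lattice with rook (edge-sharing) adjacency, the stand-in
#' for a national state-contiguity map: a 6x6 lattice has 36 regions, the
#' scale of Nigeria's 36 states + FCT. Interior cells have 4 neighbours,
#' corners 2.
#'
#' @param rows,cols lattice dimensions, `rows * cols >= 2`.
#' @return an [adjacency_graph] with labels `"r.c"`.
#' @export
make_lattice_graph <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 2) stop("lattice must have at least 2 cells")
  idx <- function(r, c) (r - 1L) * cols + c
  edges <- NULL
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) edges <- rbind(edges, c(idx(r, c), idx(r, c + 1L)))
      if (r < rows) edges <- rbind(edges, c(idx(r, c), idx(r + 1L, c)))
    }
  }
  labels <- as.vector(t(outer(seq_len(rows), seq_len(cols), paste, sep = ".")))
  adjacency_graph(rows * cols, edges, labels = labels)
}

#' Default pooled survey design
#'
#' Six survey waves 2003--2016, alternating DHS and MICS, with wave shares
#' proportional to the pooled girl counts of the six source surveys
#' (3281, 7768, 17691, 16874, 25176, 17529).
#'
#' @return data frame with columns `year`, `survey`, `share` (shares sum to 1).
#' @export
default_survey_design <- function() {
  n <- c(3281, 7768, 17691, 16874, 25176, 17529)
  data.frame(year = c(2003L, 2007L, 2008L, 2011L, 2013L, 2016L),
             survey = c("DHS", "MICS", "DHS", "MICS", "DHS", "MICS"),
             share = n / sum(n),
             stringsAsFactors = FALSE)
}

# default generator configuration; see the methods vignette for the
# provenance of each value (fixed effects are logs of pooled-data
# odds ratios; variances sized to give realistic effect ranges).
default_truth_config <- function() {
  list(
    intercept = -3.7,
    fixed_effects = list(
      education = c(None = log(2.6), Primary = log(2.35),
                    Secondary = log(1.928)),
      residence = c(Urban = log(0.955)),
      mother_cut = c(Cut = log(18.153)),
      support = c(Continued = log(13.944), `Depends` = log(3.111)),
      survey = c(MICS = log(0.877))
    ),
    tau2_str = 0.5, tau2_unstr = 0.05, tau2_xi = 0.25,
    tau2_age = 5e-5, tau2_year = 0.004,
    interaction = "iid",
    age_grid = 15:49,
    years = c(2003L, 2007L, 2008L, 2011L, 2013L, 2016L)
  )
}

# a centred RW2 path of length n with increment variance tau2
rw2_path <- function(n, tau2) {
  if (n < 3 || tau2 == 0) return(numeric(n))
  b <- numeric(n)
  u <- stats::rnorm(n - 2, sd = sqrt(tau2))
  for (m in 3:n) b[m] <- 2 * b[m - 1] - b[m - 2] + u[m - 2]
  b - mean(b)
}

#' Draw a ground-truth parameter set
#'
#' Samples every component of the structured additive predictor from its
#' own prior, giving a "true" parameter set for forward simulation and
#' recovery scoring: the structured region effect from the intrinsic GMRF
#' on the graph, the unstructured effect iid Gaussian, the age and year
#' smooths as centred RW2 paths on their grids, the space-time interaction
#' iid or RW2-in-time per the chosen variant, and fixed effects from the
#' configuration (defaults are logs of pooled-survey odds
#' ratios, e.g. a mother's own cut status at log 18.153).
#'
#' @param graph a connected [adjacency_graph] (`S` regions).
#' @param config named list overriding entries of the default configuration
#'   (`intercept`, `fixed_effects`, `tau2_str`, `tau2_unstr`, `tau2_xi`,
#'   `tau2_age`, `tau2_year`, `interaction` in `c("iid","smooth","none")`,
#'   `age_grid`, `years`).
#' @param seed integer seed.
#' @return an object of class `truth_params`; all random components are
#'   mean-centred over their support.
#' @export
draw_truth <- function(graph, config = list(), seed = 1) {
  cfg <- utils::modifyList(default_truth_config(), config)
  for (v in c("tau2_str", "tau2_unstr", "tau2_xi", "tau2_age", "tau2_year")) {
    if (!is.numeric(cfg[[v]]) || cfg[[v]] < 0) stop(v, " must be >= 0")
  }
  set.seed(as.integer(seed))
  S <- graph$n_regions
  T_ <- length(cfg$years)
  f_str <- if (cfg$tau2_str > 0) {
    drop(sample_igmrf(graph, cfg$tau2_str, n_draws = 1))
  } else numeric(S)
  f_unstr <- if (cfg$tau2_unstr > 0) {
    v <- stats::rnorm(S, sd = sqrt(cfg$tau2_unstr)); v - mean(v)
  } else numeric(S)
  f_age <- rw2_path(length(cfg$age_grid), cfg$tau2_age)
  f_year <- rw2_path(T_, cfg$tau2_year)
  xi <- matrix(0, S, T_, dimnames = list(graph$labels, cfg$years))
  if (cfg$interaction == "iid" && cfg$tau2_xi > 0) {
    xi[] <- stats::rnorm(S * T_, sd = sqrt(cfg$tau2_xi))
    xi <- xi - mean(xi)
  } else if (cfg$interaction == "smooth" && cfg$tau2_xi > 0) {
    for (s in seq_len(S)) xi[s, ] <- rw2_path(T_, cfg$tau2_xi)
    xi <- xi - mean(xi)
  }
  structure(list(intercept = cfg$intercept,
                 fixed_effects = cfg$fixed_effects,
                 f_age = stats::setNames(f_age, cfg$age_grid),
                 f_year = stats::setNames(f_year, cfg$years),
                 f_str = stats::setNames(f_str, graph$labels),
                 f_unstr = stats::setNames(f_unstr, graph$labels),
                 xi = xi,
                 tau2_str = cfg$tau2_str, tau2_unstr = cfg$tau2_unstr,
                 tau2_xi = cfg$tau2_xi, tau2_age = cfg$tau2_age,
                 tau2_year = cfg$tau2_year,
                 interaction = cfg$interaction,
                 age_grid = cfg$age_grid, years = cfg$years),
            class = "truth_params")
}

# mother-level covariate marginals for the generator (vignette documents
# the choices; roughly national-survey-like mixes)
mother_covariate_pools <- function() {
  list(
    education = list(levels = c("None", "Primary", "Secondary", "Higher"),
                     prob = c(0.35, 0.22, 0.30, 0.13)),
    residence = list(levels = c("Rural", "Urban"), prob = c(0.60, 0.40)),
    mother_cut = list(levels = c("Not cut", "Cut"), prob = c(0.70, 0.30)),
    support = list(levels = c("Stopped", "Continued", "Depends"),
                   prob = c(0.55, 0.33, 0.12))
  )
}

#' Forward-simulate a pooled multi-survey girl-level dataset
#'
#' Mothers are assigned to survey waves (by the design shares), to regions
#' (uniformly) and to mother-level covariates; each mother bears a
#' truncated-Poisson number of daughters who inherit all mother-level
#' covariates — this within-mother sharing induces the clustered,
#' non-independent binary outcomes the hierarchical model is built for.
#' Every girl's linear predictor is assembled additively from the truth
#' (intercept + fixed effects + f(age) + f(year) + f_str + f_unstr + xi)
#' and her outcome drawn `y ~ Bernoulli(logit^-1(eta))`. Survey weights are
#' Gamma(4, 4) draws normalised to mean 1 (used by descriptive crosstabs
#' only, never by the Bayesian fit).
#'
#' @param truth a [draw_truth()] result.
#' @param graph the companion [adjacency_graph].
#' @param n_mothers number of mothers.
#' @param girls_lambda Poisson rate of the zero-truncated daughters-per-
#'   mother distribution (default 1.21, giving mean ~1.727 girls/mother,
#'   the pooled-survey nesting ratio 88319/51141).
#' @param survey_design data frame `year`/`survey`/`share` (shares sum to
#'   1); default [default_survey_design()].
#' @param seed integer seed.
#' @return a data frame (the observation table) with columns `fgm`,
#'   `state`, `year`, `survey`, `mother_age`, `mother_id`, `education`,
#'   `residence`, `mother_cut`, `support`, `weight`, and attribute `truth_eta`
#'   (the per-girl true linear predictor, for recovery scoring).
#' @export
simulate_dataset <- function(truth, graph, n_mothers = 5000,
                             girls_lambda = 1.21,
                             survey_design = default_survey_design(),
                             seed = 1) {
  if (n_mothers < 1) stop("empty design: n_mothers must be >= 1")
  if (abs(sum(survey_design$share) - 1) > 1e-8) {
    stop("survey design shares must sum to 1")
  }
  if (!all(survey_design$year %in% truth$years)) {
    stop("survey design contains years absent from the truth's year grid")
  }
  set.seed(as.integer(seed))
  S <- graph$n_regions
  pools <- mother_covariate_pools()

  wave <- sample.int(nrow(survey_design), n_mothers, replace = TRUE,
                     prob = survey_design$share)
  m <- data.frame(
    mother_id = seq_len(n_mothers),
    state = sample.int(S, n_mothers, replace = TRUE),
    year = survey_design$year[wave],
    survey = survey_design$survey[wave],
    mother_age = sample(truth$age_grid, n_mothers, replace = TRUE,
                        prob = stats::dnorm(truth$age_grid, 30, 8)),
    stringsAsFactors = FALSE)
  for (cv in names(pools)) {
    m[[cv]] <- sample(pools[[cv]]$levels, n_mothers, replace = TRUE,
                      prob = pools[[cv]]$prob)
  }
  # zero-truncated Poisson daughters per mother (rejection; P(0) ~ 0.30)
  ng <- stats::rpois(n_mothers, girls_lambda)
  while (any(ng == 0)) {
    z <- ng == 0
    ng[z] <- stats::rpois(sum(z), girls_lambda)
  }
  g <- m[rep(seq_len(n_mothers), ng), , drop = FALSE]
  rownames(g) <- NULL
  n <- nrow(g)

  eta <- rep(truth$intercept, n)
  for (cv in names(truth$fixed_effects)) {
    fe <- truth$fixed_effects[[cv]]
    if (cv %in% names(g)) {
      hit <- match(g[[cv]], names(fe))
      eta <- eta + ifelse(is.na(hit), 0, fe[pmax(hit, 1)])
    }
  }
  eta <- eta + truth$f_age[match(g$mother_age, truth$age_grid)]
  eta <- eta + truth$f_year[match(g$year, truth$years)]
  eta <- eta + truth$f_str[g$state] + truth$f_unstr[g$state]
  eta <- eta + truth$xi[cbind(g$state, match(g$year, truth$years))]
  eta <- unname(eta)

  g$fgm <- stats::rbinom(n, 1, stats::plogis(eta))
  w <- stats::rgamma(n, shape = 4, rate = 4)
  g$weight <- w / mean(w)
  out <- g[, c("fgm", "state", "year", "survey", "mother_age", "mother_id",
               "education", "residence", "mother_cut", "support", "weight")]
  attr(out, "truth_eta") <- eta
  out
}

#' Inject missing covariate values completely at random
#'
#' Sets covariate cells (never the outcome, region, year or survey columns)
#' to `NA` independently with the given rate, emulating item nonresponse
#' that downstream listwise deletion removes.
#'
#' @param table observation table.
#' @param rate per-cell missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @param columns covariate columns eligible for missingness.
#' @return the table with `NA`s injected.
#' @export
inject_missingness <- function(table, rate, seed = 1,
                               columns = c("education", "residence",
                                           "mother_cut", "support",
                                           "mother_age")) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(table)
  set.seed(as.integer(seed))
  columns <- intersect(columns, names(table))
  for (cl in columns) {
    hit <- stats::runif(nrow(table)) < rate
    table[[cl]][hit] <- NA
  }
  table
}
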