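#' Cubic B-spline basis with equidistant knots
#'
#' Builds the design matrix of a P-spline smooth `f(x) = sum_m beta_m B_m(x)`
#' over an equidistant knot grid spanning the observed range of `x`, with
#' `degree` extra boundary knots appended on each side at the same spacing.
#' The basis dimension is `M = n_interior_knots + degree + 1` and the basis
#' is a partition of unity on the domain (every design row sums to 1).
#'
#' @param x covariate vector (finite; `NA` must be removed upstream by
#'   listwise deletion).
#' @param n_interior_knots number of interior knots (>= 2 recommended; the
#'   RW2 penalty regularises even when `M` exceeds the number of distinct
#'   `x` values).
#' @param degree spline degree (default 3, cubic).
#' @param domain optional `c(min, max)` overriding the observed range (used
#'   to evaluate a fitted smooth on a new grid).
#' @return list with `basis` (a `spline_basis`: knots, degree, n_basis,
#'   domain) and `design` (`length(x) x M` matrix).
#' @export
bspline_basis <- function(x, n_interior_knots = 20, degree = 3, domain = NULL) {
  if (anyNA(x) || !all(is.finite(x))) {
    stop("x contains NA or non-finite values; apply listwise deletion first")
  }
  if (n_interior_knots < 1) stop("n_interior_knots must be >= 1")
  if (degree < 0) stop("degree must be >= 0")
  if (is.null(domain)) domain <- range(x)
  a <- domain[1]; b <- domain[2]
  if (any(x < a | x > b)) stop("x outside basis domain [", a, ", ", b, "]")
  if (a == b) stop("degenerate domain: min(x) == max(x)")
  h <- (b - a) / (n_interior_knots + 1)
  knots <- seq(a - degree * h, b + degree * h, by = h)
  # guard against fp drift on the right boundary
  knots[length(knots)] <- b + degree * h + 1e-8 * h
  M <- n_interior_knots + degree + 1
  design <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = FALSE)
  stopifnot(ncol(design) == M)
  basis <- structure(list(knots = knots, degree = degree, n_basis = M,
                          domain = c(a, b)),
                     class = "spline_basis")
  if (length(unique(x)) < M) {
    message("note: fewer distinct x values (", length(unique(x)),
            ") than basis dimension (", M, "); the RW2 penalty regularises")
  }
  list(basis = basis, design = design)
}

# evaluate an existing basis at new points (prediction grid)
eval_spline_basis <- function(basis, x) {
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1, outer.ok = FALSE)
}

#' Second-order random-walk penalty matrix
#'
#' `K = D2' D2` with `D2` the `(M-2) x M` second-difference operator, so the
#' quadratic form is the sum of squared second differences
#' `sum_m (beta_m - 2 beta_{m-1} + beta_{m-2})^2` — the RW2 prior
#' `beta_m = 2 beta_{m-1} - beta_{m-2} + u_m`, `u_m ~ N(0, tau2)`, in
#' penalty form. Null space: constant and linear sequences; rank `M - 2`.
#'
#' @param M basis dimension (>= 3).
#' @return a [penalty_matrix] of kind `"rw2"`.
#' @export
rw2_penalty <- function(M) {
  M <- as.integer(M)
  if (is.na(M) || M < 3) stop("RW2 penalty requires M >= 3")
  D2 <- diff(diag(M), differences = 2)
  penalty_matrix(crossprod(D2), "rw2", rank = M - 2L)
}

#' Identity penalty (iid Gaussian random effect)
#'
#' `K = I_M`, full rank: the penalty form of independent
#' `N(0, tau2)` coefficients (unstructured region effects, iid space-time
#' interaction).
#'
#' @param M block dimension.
#' @return a [penalty_matrix] of kind `"identity"`.
#' @export
identity_penalty <- function(M) {
  penalty_matrix(diag(M), "identity", rank = as.integer(M))
}

# Block-diagonal RW2 over `n_times` ordered time points within each of
# `n_groups` groups (the "smooth" space-time interaction variant: temporal
# autocorrelation within region). Coefficients ordered group-major:
# (g1 t1..tT, g2 t1..tT, ...). Rank = n_groups * (n_times - 2).
interaction_rw2_penalty <- function(n_groups, n_times) {
  if (n_times < 3) stop("interaction RW2 requires >= 3 time points")
  K1 <- rw2_penalty(n_times)$matrix
  K <- kronecker(diag(n_groups), K1)
  penalty_matrix(K, "rw2", rank = as.integer(n_groups * (n_times - 2)))
}

#' One additive model term
#'
#' A `model_term` bundles the design matrix `X_j`, the penalty `K_j` and
#' bookkeeping for one additive component `f_j = X_j beta_j` of the
#' structured additive predictor. `kind = "fixed"` terms carry a flat prior
#' (no penalty); all other kinds carry a `penalty_matrix` and a variance
#' parameter `tau_j^2` with an IG(a, b) hyperprior.
#'
#' @param name term identifier.
#' @param kind one of `"fixed"`, `"pspline"`, `"mrf"`, `"iid_region"`,
#'   `"interaction_smooth"`, `"interaction_iid"`.
#' @param design `n x M` design matrix (base or `Matrix` sparse).
#' @param penalty a [penalty_matrix], or `NULL` for fixed terms.
#' @param colnames_ labels of the `M` coefficients.
#' @param reference reference level (fixed categorical terms only).
#' @param covariate source column name(s) in the observation table.
#' @param basis optional `spline_basis` for pspline terms.
#' @return an object of class `model_term`.
#' @export
model_term <- function(name, kind, design, penalty = NULL, colnames_ = NULL,
                       reference = NULL, covariate = NULL, basis = NULL) {
  kind <- match.arg(kind, c("fixed", "pspline", "mrf", "iid_region",
                            "interaction_smooth", "interaction_iid"))
  if (kind == "fixed") {
    if (!is.null(penalty)) stop("fixed terms have a flat prior (no penalty)")
  } else {
    if (is.null(penalty)) stop("non-fixed terms require a penalty matrix")
    if (ncol(design) != nrow(penalty$matrix)) {
      stop("design column count (", ncol(design),
           ") must equal penalty dimension (", nrow(penalty$matrix), ")")
    }
  }
  if (is.null(colnames_)) {
    colnames_ <- colnames(design)
    if (is.null(colnames_)) colnames_ <- paste0(name, seq_len(ncol(design)))
  }
  # fast path for 0/1 one-hot designs: row i has a single 1 in column
  # index[i], so X'WX is diagonal and X beta = beta[index]
  index <- NULL
  if (methods::is(design, "sparseMatrix")) {
    sm <- Matrix::summary(design)
    if (nrow(sm) == nrow(design) && all(sm$x == 1) &&
        !anyDuplicated(sm$i)) {
      index <- integer(nrow(design))
      index[sm$i] <- sm$j
    }
  }
  structure(list(name = name, kind = kind, design = design, penalty = penalty,
                 colnames = colnames_, reference = reference,
                 covariate = covariate, basis = basis, index = index),
            class = "model_term")
}

#' @export
print.model_term <- function(x, ...) {
  cat(sprintf("model_term '%s': kind=%s, %d x %d design%s\n",
              x$name, x$kind, nrow(x$design), ncol(x$design),
              if (is.null(x$penalty)) " (flat prior)"
              else paste0(", penalty ", x$penalty$kind)))
  invisible(x)
}

#' Dummy-code a categorical covariate as a fixed-effect term
#'
#' Treatment contrasts with an explicit reference level: one indicator
#' column per non-reference level, so posterior odds ratios read directly
#' against the reference row (POR of the reference is 1 by construction).
#'
#' @param column character/factor vector of level labels.
#' @param reference the reference level (must occur in the level set).
#' @param name term name (defaults to `"fixed"`).
#' @return a `model_term` of kind `"fixed"` (possibly with zero columns if
#'   every row is at the reference).
#' @export
encode_categorical <- function(column, reference, name = "fixed") {
  column <- as.character(column)
  if (anyNA(column)) stop("NA in categorical column; apply listwise deletion first")
  levs <- unique(column)
  if (!reference %in% levs) {
    stop("reference level '", reference, "' not observed; levels are: ",
         paste(sort(levs), collapse = ", "))
  }
  others <- setdiff(sort(levs), reference)
  design <- matrix(0, length(column), length(others),
                   dimnames = list(NULL, others))
  for (l in others) design[column == l, l] <- 1
  model_term(name, "fixed", design, colnames_ = others,
             reference = reference)
}

#' Centre a fitted additive component to mean zero
#'
#' Enforces the identifiability convention that every non-fixed function is
#' centred on zero over the observed data: the empirical mean of
#' `X_j beta_j` is subtracted from the coefficients and returned as an
#' intercept correction, leaving the linear predictor unchanged. Requires
#' the design rows to sum to one (true of all terms built here: indicator
#' designs and B-spline partitions of unity).
#'
#' @param term a non-fixed `model_term`.
#' @param coefficients current coefficient vector for the term.
#' @return list with `coefficients` (centred) and `intercept_shift` (the
#'   amount to add to the global intercept).
#' @export
apply_centering <- function(term, coefficients) {
  if (term$kind == "fixed") stop("fixed terms are not centred")
  f <- as.numeric(term$design %*% coefficients)
  shift <- mean(f)
  rs <- as.numeric(term$design %*% rep(1, length(coefficients)))
  if (max(abs(rs - 1)) > 1e-8) {
    stop("apply_centering requires design rows summing to 1")
  }
  list(coefficients = coefficients - shift, intercept_shift = shift)
}
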