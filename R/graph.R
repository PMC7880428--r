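#' Construct a region adjacency graph
#'
#' An adjacency graph records the contiguity structure of the study regions:
#' which regions share a border. It is the carrier of the Markov random field
#' (ICAR) prior on structured spatial effects, where each region's conditional
#' mean is the average of its neighbours.
#'
#' @param n_regions number of regions `S`.
#' @param edges two-column integer matrix of unordered neighbour pairs, one
#'   row per edge, indices in `1..S`.
#' @param labels optional character vector of region names (defaults to
#'   `"R1".."RS"`).
#' @return an object of class `adjacency_graph` with fields `n_regions`,
#'   `labels`, `edges` (canonicalised, `r < s`, deduplicated),
#'   `neighbor_counts` and `n_components`.
#' @examples
#' g <- adjacency_graph(3, rbind(c(1, 2), c(2, 3)))
#' g$neighbor_counts  # 1 2 1
#' @export
adjacency_graph <- function(n_regions, edges, labels = NULL) {
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 1) {
    stop("n_regions must be a positive integer")
  }
  if (is.null(labels)) labels <- paste0("R", seq_len(n_regions))
  if (length(labels) != n_regions) {
    stop("labels must have length n_regions")
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(is.na(edges))) stop("edge indices must be integers")
    bad <- edges[, 1] < 1 | edges[, 1] > n_regions |
      edges[, 2] < 1 | edges[, 2] > n_regions
    if (any(bad)) {
      stop(sprintf("edge index out of range 1..%d: (%d, %d)",
                   n_regions,
                   edges[which(bad)[1], 1], edges[which(bad)[1], 2]))
    }
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) {
      stop(sprintf("self-loop not allowed: region %d", edges[which(loops)[1], 1]))
    }
    # canonical order r < s, drop duplicates
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  counts <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_regions)
  g <- structure(
    list(n_regions = n_regions,
         labels = as.character(labels),
         edges = edges,
         neighbor_counts = counts,
         n_components = NA_integer_),
    class = "adjacency_graph")
  g$n_components <- graph_components(g)$n
  g
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d regions, %d edges, %d connected component(s)\n",
              x$n_regions, nrow(x$edges), x$n_components))
  invisible(x)
}

# Connected components by iterative label propagation (no igraph dependency
# needed for graphs of a few hundred regions).
graph_components <- function(graph) {
  S <- graph$n_regions
  comp <- seq_len(S)
  e <- graph$edges
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(e))) {
      m <- min(comp[e[k, 1]], comp[e[k, 2]])
      if (comp[e[k, 1]] > m) { comp[e[k, 1]] <- m; changed <- TRUE }
      if (comp[e[k, 2]] > m) { comp[e[k, 2]] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  ids <- match(comp, sort(unique(comp)))
  list(n = length(unique(ids)), membership = ids)
}

#' Read a region adjacency graph from file
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`edge_list`}{one edge per line, two whitespace-separated region
#'     labels (or 1-based indices); `#` starts a comment. The region set is
#'     the sorted union of labels unless `labels` is supplied.}
#'   \item{`gra`}{BayesX-style map file: first line the region count `S`,
#'     then for each region three lines -- its label, its neighbour count
#'     `N_s`, and `N_s` neighbour indices (1-based positions in file order).}
#' }
#'
#' @param path file path.
#' @param dialect `"edge_list"` or `"gra"`.
#' @param labels optional full region label set for the edge-list dialect
#'   (so isolated regions can be represented).
#' @return an [adjacency_graph].
#' @export
read_graph <- function(path, dialect = c("edge_list", "gra"), labels = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("graph file not found: ", path)
  lines <- readLines(path)
  if (dialect == "edge_list") {
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[[:space:]]+")
    bad <- lengths(parts) != 2
    if (any(bad)) stop("edge-list line must have exactly two fields: '",
                       lines[which(bad)[1]], "'")
    a <- vapply(parts, `[`, "", 1)
    b <- vapply(parts, `[`, "", 2)
    if (is.null(labels)) labels <- sort(unique(c(a, b)))
    ia <- match(a, labels)
    ib <- match(b, labels)
    if (anyNA(ia) || anyNA(ib)) {
      stop("edge-list label not in region label set: ",
           paste(setdiff(c(a, b), labels), collapse = ", "))
    }
    loops <- ia == ib
    if (any(loops)) stop("self-loop not allowed: region '", a[which(loops)[1]], "'")
    adjacency_graph(length(labels), cbind(ia, ib), labels = labels)
  } else {
    # blank lines are significant: a 0-neighbour region lists no indices
    lines <- trimws(lines)
    S <- suppressWarnings(as.integer(lines[1]))
    if (is.na(S) || S < 1) stop(".gra format error: first line must be the region count")
    if (length(lines) != 1 + 3 * S) {
      stop(sprintf(".gra format error: expected %d lines (1 + 3*S), got %d",
                   1 + 3 * S, length(lines)))
    }
    labs <- character(S)
    nbr <- vector("list", S)
    for (s in seq_len(S)) {
      base <- 1 + 3 * (s - 1)
      labs[s] <- lines[base + 1]
      ns <- suppressWarnings(as.integer(lines[base + 2]))
      if (is.na(ns) || ns < 0) {
        stop(".gra format error: bad neighbour count for region ", labs[s])
      }
      ids <- if (ns == 0) integer(0) else {
        v <- suppressWarnings(as.integer(strsplit(lines[base + 3], "[[:space:]]+")[[1]]))
        v[!is.na(v)]
      }
      if (length(ids) != ns) {
        stop(".gra format error: region ", labs[s],
             " declares ", ns, " neighbours but lists ", length(ids))
      }
      if (any(ids < 1 | ids > S)) {
        stop(".gra format error: neighbour index out of range for region ", labs[s])
      }
      if (any(ids == s)) stop(".gra format error: self-loop at region ", labs[s])
      nbr[[s]] <- ids
    }
    # symmetry check before canonicalisation
    for (s in seq_len(S)) {
      for (r in nbr[[s]]) {
        if (!(s %in% nbr[[r]])) {
          stop(sprintf(".gra format error: asymmetric neighbour pair (%s, %s)",
                       labs[s], labs[r]))
        }
      }
    }
    edges <- do.call(rbind, lapply(seq_len(S), function(s) {
      r <- nbr[[s]][nbr[[s]] > s]
      if (length(r)) cbind(s, r) else NULL
    }))
    if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
    adjacency_graph(S, edges, labels = labs)
  }
}

#' Write a region adjacency graph to file
#'
#' Inverse of [read_graph()]; round-trips losslessly in either dialect.
#'
#' @param graph an [adjacency_graph].
#' @param path output file path.
#' @param dialect `"edge_list"` or `"gra"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, dialect = c("edge_list", "gra")) {
  dialect <- match.arg(dialect)
  if (dialect == "edge_list") {
    lines <- apply(graph$edges, 1, function(e) {
      paste(graph$labels[e[1]], graph$labels[e[2]])
    })
    writeLines(as.character(lines), path)
  } else {
    nbr <- neighbor_list(graph)
    out <- as.character(graph$n_regions)
    for (s in seq_len(graph$n_regions)) {
      out <- c(out, graph$labels[s], as.character(length(nbr[[s]])),
               paste(nbr[[s]], collapse = " "))
    }
    writeLines(out, path)
  }
  invisible(path)
}

neighbor_list <- function(graph) {
  nbr <- vector("list", graph$n_regions)
  for (k in seq_len(nrow(graph$edges))) {
    r <- graph$edges[k, 1]; s <- graph$edges[k, 2]
    nbr[[r]] <- c(nbr[[r]], s)
    nbr[[s]] <- c(nbr[[s]], r)
  }
  lapply(nbr, function(v) sort(unique(v)))
}

#' Penalty matrix object
#'
#' A symmetric positive semidefinite matrix `K` acting as the (improper)
#' Gaussian prior precision of a coefficient block, up to the variance
#' parameter: `pi(beta | tau2) ~ exp(-beta' K beta / (2 tau2))`.
#'
#' @param matrix symmetric PSD matrix.
#' @param kind one of `"mrf"`, `"rw2"`, `"identity"`.
#' @param rank integer rank of `matrix`.
#' @return an object of class `penalty_matrix`.
#' @export
penalty_matrix <- function(matrix, kind, rank) {
  matrix <- as.matrix(matrix)
  if (!isSymmetric(unname(matrix), tol = 1e-10)) stop("penalty matrix must be symmetric")
  structure(list(matrix = matrix, kind = kind, rank = as.integer(rank)),
            class = "penalty_matrix")
}

#' @export
print.penalty_matrix <- function(x, ...) {
  cat(sprintf("penalty_matrix: kind=%s, dim=%d, rank=%d\n",
              x$kind, nrow(x$matrix), x$rank))
  invisible(x)
}

#' Intrinsic MRF (ICAR) precision matrix of an adjacency graph
#'
#' Builds the graph Laplacian `K` with `K[s,s] = N_s` (neighbour count) and
#' `K[r,s] = -1` for neighbouring regions. This is the precision structure
#' implied by the conditional ICAR prior where region `s` given the rest is
#' Gaussian with mean the neighbour average and variance `tau2 / N_s`. Rows
#' sum to zero; the rank is `S - c` for `c` connected components.
#'
#' @param graph an [adjacency_graph].
#' @return a [penalty_matrix] of kind `"mrf"`.
#' @export
mrf_precision <- function(graph) {
  S <- graph$n_regions
  K <- matrix(0, S, S)
  if (nrow(graph$edges) > 0) {
    for (k in seq_len(nrow(graph$edges))) {
      r <- graph$edges[k, 1]; s <- graph$edges[k, 2]
      K[r, s] <- K[r, s] - 1
      K[s, r] <- K[s, r] - 1
    }
  }
  diag(K) <- graph$neighbor_counts
  dimnames(K) <- list(graph$labels, graph$labels)
  penalty_matrix(K, "mrf", rank = S - graph$n_components)
}

#' Sample from an intrinsic Gaussian Markov random field
#'
#' Draws zero-mean spatial effect vectors whose precision is `K_mrf / tau2`
#' restricted to the sum-to-zero subspace (the ICAR null space for a
#' connected graph). Sampling is by spectral decomposition of `K`: the
#' null-space direction (the constant vector) is dropped and each remaining
#' eigen-direction `v_i` receives an independent `N(0, tau2 / lambda_i)`
#' coordinate. Draws are re-centred to enforce the zero-sum identifiability
#' constraint exactly.
#'
#' @param graph a connected [adjacency_graph].
#' @param tau2 positive variance (smoothing) parameter.
#' @param n_draws number of draws.
#' @param seed optional integer seed (RNG state is used as-is when `NULL`).
#' @return `n_draws x S` matrix; each row sums to zero.
#' @export
sample_igmrf <- function(graph, tau2, n_draws = 1, seed = NULL) {
  if (graph$n_components != 1) {
    stop("graph is disconnected (", graph$n_components, " components); ",
         "intrinsic GMRF sampling requires a per-component sum-to-zero ",
         "constraint -- split the graph and sample per component")
  }
  if (!is.numeric(tau2) || tau2 <= 0) stop("tau2 must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  S <- graph$n_regions
  K <- mrf_precision(graph)$matrix
  eig <- eigen(K, symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-10
  lam <- eig$values[keep]
  V <- eig$vectors[, keep, drop = FALSE]
  z <- matrix(stats::rnorm(n_draws * length(lam)), n_draws, length(lam))
  draws <- z %*% (t(V) * (1 / sqrt(lam))) * sqrt(tau2)
  draws <- draws - rowMeans(draws)  # exact zero-sum
  colnames(draws) <- graph$labels
  draws
}
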