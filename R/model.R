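#' Specify a structured additive logit model
#'
#' Declares which additive components enter the linear predictor
#' \deqn{logit(p_i) = f_str(state_i) + f_unstr(state_i) + f(year) + f(age)
#'   + z_i' omega + survey + xi,}
#' mirroring the nested model suite m1--m6: m1 = spatial + f(year); m2 adds
#' the survey fixed effect; m3 adds categorical covariates and f(age); m4 =
#' m3 + survey; m5/m6 add the space-time interaction as an RW2 smooth or an
#' iid random effect. Starred single-year variants drop the year smooth,
#' survey effect and interaction.
#'
#' @param spatial include structured (MRF) + unstructured (iid) region effects.
#' @param year_smooth include the RW2 smooth over survey years.
#' @param age_smooth include the P-spline smooth of mother's age.
#' @param survey include the survey-type fixed effect (DHS reference).
#' @param covariates character vector of categorical fixed-effect columns.
#' @param interaction `"none"`, `"smooth"` (RW2 over years within region) or
#'   `"iid"` (exchangeable region-year random effect).
#' @param references named list of reference levels for the categorical
#'   covariates (defaults chosen so odds ratios read against the
#'   conventional baseline: education "Higher", residence "Rural",
#'   mother_cut "Not cut", support "Stopped", survey "DHS").
#' @param n_knots interior knot count for the age P-spline (default 20).
#' @param a,b inverse-gamma hyperparameters shared by all variance
#'   parameters (defaults a = 1, b = 0.0005: diffuse).
#' @return an object of class `star_model_spec`.
#' @export
model_spec <- function(spatial = TRUE, year_smooth = TRUE, age_smooth = TRUE,
                       survey = FALSE,
                       covariates = character(0),
                       interaction = c("none", "smooth", "iid"),
                       references = list(),
                       n_knots = 20, a = 1, b = 0.0005) {
  interaction <- match.arg(interaction)
  defaults <- list(education = "Higher", residence = "Rural",
                   mother_cut = "Not cut", support = "Stopped",
                   survey = "DHS")
  refs <- utils::modifyList(defaults, references)
  if (a <= 0 || b <= 0) stop("hyperparameters a, b must be > 0")
  structure(list(spatial = spatial, year_smooth = year_smooth,
                 age_smooth = age_smooth, survey = survey,
                 covariates = covariates, interaction = interaction,
                 references = refs, n_knots = n_knots, a = a, b = b),
            class = "star_model_spec")
}

# columns a spec needs from the observation table
spec_columns <- function(spec) {
  cols <- c("fgm", "state")
  if (spec$year_smooth || spec$interaction != "none") cols <- c(cols, "year")
  if (spec$survey) cols <- c(cols, "survey")
  if (spec$age_smooth) cols <- c(cols, "mother_age")
  c(cols, spec$covariates)
}

#' Listwise deletion of incomplete records
#'
#' Drops every row with at least one missing value among the columns the
#' model uses (the handling applied to the survey microdata before both the
#' descriptive and the Bayesian analyses).
#'
#' @param data observation table (data frame).
#' @param columns columns to scan; defaults to all columns.
#' @return the complete-case data frame, with attribute `n_dropped`.
#' @export
listwise_delete <- function(data, columns = names(data)) {
  columns <- intersect(columns, names(data))
  keep <- stats::complete.cases(data[, columns, drop = FALSE])
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# grouped-row factorisation of a design whose rows take few distinct
# values: design == G %*% unique_design with G one-hot (sampler fast path)
make_grp <- function(index, unique_design) {
  list(index = index,
       unique_design = as.matrix(unique_design),
       G = indicator_design(index, nrow(unique_design)))
}

# sparse 0/1 indicator design, n x n_levels
indicator_design <- function(index, n_levels, labels = NULL) {
  X <- Matrix::sparseMatrix(i = seq_along(index), j = index, x = 1,
                            dims = c(length(index), n_levels))
  if (!is.null(labels)) colnames(X) <- labels
  X
}

#' Build the additive term list for a model specification
#'
#' Turns an observation table plus a region graph into the concrete
#' `model_term` list the sampler consumes: a joint fixed block (intercept +
#' treatment-coded dummies + survey), the age P-spline with RW2 penalty, the
#' year RW2 smooth, MRF-structured and iid unstructured region effects, and
#' the chosen space-time interaction. The data must already be
#' complete-case for the columns the spec uses.
#'
#' @param data observation table (see [simulate_dataset()] for the schema).
#' @param graph the companion [adjacency_graph].
#' @param spec a [model_spec()].
#' @return list of `model_term` objects; the fixed block is first.
#' @export
build_model_terms <- function(data, graph, spec) {
  need <- spec_columns(spec)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("observation table lacks columns required by the model: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!stats::complete.cases(data[, need, drop = FALSE]))) {
    stop("missing values in model columns; apply listwise_delete() first")
  }
  n <- nrow(data)
  if (n == 0) stop("empty observation table")
  if (any(data$state < 1 | data$state > graph$n_regions)) {
    stop("state index outside 1..", graph$n_regions)
  }
  terms <- list()

  # joint fixed block: intercept + categorical dummies (+ survey)
  fixed_design <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fixed_meta <- data.frame(column = "(Intercept)", covariate = "(Intercept)",
                           level = "(Intercept)", stringsAsFactors = FALSE)
  fixed_refs <- list()
  fixed_covs <- spec$covariates
  if (spec$survey) fixed_covs <- c(fixed_covs, "survey")
  for (cv in fixed_covs) {
    ref <- spec$references[[cv]]
    if (is.null(ref)) {
      stop("no reference level declared for covariate '", cv, "'")
    }
    tm <- encode_categorical(data[[cv]], ref, name = cv)
    if (ncol(tm$design) > 0) {
      cn <- paste0(cv, ":", tm$colnames)
      colnames(tm$design) <- cn
      fixed_design <- cbind(fixed_design, tm$design)
      fixed_meta <- rbind(fixed_meta,
                          data.frame(column = cn, covariate = cv,
                                     level = tm$colnames,
                                     stringsAsFactors = FALSE))
    }
    fixed_refs[[cv]] <- ref
  }
  # sparse storage: dummies are 0/1 and spline rows have degree+1 nonzeros
  fixed <- model_term("fixed", "fixed",
                      methods::as(fixed_design, "CsparseMatrix"))
  key <- do.call(paste, as.data.frame(fixed_design))
  ukey <- unique(key)
  fixed$grp <- make_grp(match(key, ukey),
                        fixed_design[!duplicated(key), , drop = FALSE])
  fixed$meta <- fixed_meta
  fixed$references <- fixed_refs
  terms <- c(terms, list(fixed))

  if (spec$age_smooth) {
    bb <- bspline_basis(data$mother_age, n_interior_knots = spec$n_knots)
    tm_age <- model_term("f(age)", "pspline",
                         methods::as(bb$design, "CsparseMatrix"),
                         penalty = rw2_penalty(bb$basis$n_basis),
                         covariate = "mother_age", basis = bb$basis)
    ua <- sort(unique(data$mother_age))
    tm_age$grp <- make_grp(match(data$mother_age, ua),
                           eval_spline_basis(bb$basis, ua))
    terms <- c(terms, list(tm_age))
  }

  years <- if ("year" %in% names(data)) sort(unique(data$year)) else integer(0)
  if (spec$year_smooth) {
    if (length(years) < 3) {
      stop("f(year) needs >= 3 distinct survey years (single-year data: ",
           "use the starred model variants without the year component)")
    }
    yd <- indicator_design(match(data$year, years), length(years),
                           labels = as.character(years))
    tm <- model_term("f(year)", "pspline", yd,
                     penalty = rw2_penalty(length(years)),
                     covariate = "year")
    tm$year_levels <- years
    terms <- c(terms, list(tm))
  }

  if (spec$spatial) {
    sd_ <- indicator_design(data$state, graph$n_regions, labels = graph$labels)
    terms <- c(terms, list(
      model_term("f_str", "mrf", sd_, penalty = mrf_precision(graph),
                 covariate = "state"),
      model_term("f_unstr", "iid_region", sd_,
                 penalty = identity_penalty(graph$n_regions),
                 covariate = "state")))
  }

  if (spec$interaction != "none") {
    if (length(years) < 3) {
      stop("space-time interaction needs >= 3 distinct survey years")
    }
    S <- graph$n_regions; T_ <- length(years)
    cell <- (data$state - 1L) * T_ + match(data$year, years)  # state-major
    labs <- as.vector(t(outer(graph$labels, years, paste, sep = ":")))
    xd <- indicator_design(cell, S * T_, labels = labs)
    if (spec$interaction == "smooth") {
      tm <- model_term("xi", "interaction_smooth", xd,
                       penalty = interaction_rw2_penalty(S, T_),
                       covariate = c("state", "year"))
    } else {
      tm <- model_term("xi", "interaction_iid", xd,
                       penalty = identity_penalty(S * T_),
                       covariate = c("state", "year"))
    }
    tm$year_levels <- years
    terms <- c(terms, list(tm))
  }
  names(terms) <- vapply(terms, `[[`, "", "name")
  terms
}
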