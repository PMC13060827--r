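#' Model specification for a hierarchical distributional fit
#'
#' Describes one per-feature model: the family, which shape parameters get
#' cohort random intercepts, the age-smooth configuration and the data
#' columns. The location (`mu`) and scale (`log sigma`) submodels always
#' contain an intercept, a cohort random intercept, a penalised B-spline
#' smooth of age and a sex fixed effect; the shape submodels (`nu`, `log
#' tau`) contain an intercept plus, optionally, a cohort random intercept.
#'
#' @param family A `gamharm_family` or family name.
#' @param feature Name of the response column.
#' @param shape_re Named logical vector, e.g. `c(nu = TRUE, tau = TRUE)`:
#'   which shape parameters receive cohort random intercepts (ignored for
#'   parameters the family lacks).
#' @param n_knots Number of interior knots of the age P-spline (default 20).
#' @param degree B-spline degree (default 3, cubic).
#' @param penalty_order Order of the difference penalty (default 2).
#' @param max_iterations Maximum outer backfitting cycles (default 200).
#' @param min_cohort_n Minimum rows per cohort (default 10); smaller cohorts
#'   are refused with an error naming the cohort.
#' @param subject_re Include a subject-level random intercept in `mu`
#'   (longitudinal extension; default `FALSE`).
#' @param age_col,sex_col,cohort_col,subject_col Column names.
#' @return An object of class `gamharm_spec`.
#' @export
model_spec <- function(family = shash_family(), feature = "y",
                       shape_re = c(nu = TRUE, tau = TRUE),
                       n_knots = 20, degree = 3, penalty_order = 2,
                       max_iterations = 200, min_cohort_n = 10,
                       subject_re = FALSE,
                       age_col = "age", sex_col = "sex",
                       cohort_col = "cohort", subject_col = "subject") {
  structure(list(family = get_family(family), feature = feature,
                 shape_re = shape_re, n_knots = n_knots, degree = degree,
                 penalty_order = penalty_order,
                 max_iterations = max_iterations,
                 min_cohort_n = min_cohort_n, subject_re = subject_re,
                 age_col = age_col, sex_col = sex_col,
                 cohort_col = cohort_col, subject_col = subject_col),
            class = "gamharm_spec")
}

# B-spline basis with linear extrapolation beyond the boundary knots:
# outside [a, b] the basis is continued as B(x0) + (x - x0) B'(x0), keeping
# predictions defined (and flagged) for ages unseen at fit time.
bspline_basis <- function(x, boundary, n_knots, degree) {
  a <- boundary[1]; b <- boundary[2]
  # Eilers-Marx construction: equally spaced knots extended beyond both
  # boundaries (no repetition), so the difference-penalty null space is
  # exactly the polynomials of degree < penalty order in age
  h <- (b - a) / (n_knots + 1L)
  aug <- seq(a - degree * h, b + degree * h,
             length.out = n_knots + 2L + 2L * degree)
  K <- length(aug) - degree - 1L
  inside <- x >= a & x <= b
  B <- matrix(0, length(x), K)
  if (any(inside)) {
    # outer.ok tolerates one-ulp excursions past the boundary knots
    B[inside, ] <- splines::splineDesign(aug, x[inside], ord = degree + 1L,
                                         outer.ok = TRUE)
  }
  lo <- x < a; hi <- x > b
  for (side in list(list(sel = lo, x0 = a), list(sel = hi, x0 = b))) {
    if (any(side$sel)) {
      B0 <- splines::splineDesign(aug, side$x0, ord = degree + 1L,
                                  outer.ok = TRUE)
      B1 <- splines::splineDesign(aug, side$x0, ord = degree + 1L,
                                  derivs = 1L, outer.ok = TRUE)
      B[side$sel, ] <- rep(1, sum(side$sel)) %o% drop(B0) +
        (x[side$sel] - side$x0) %o% drop(B1)
    }
  }
  structure(B, extrapolated = lo | hi, knots = aug, boundary = boundary)
}

# Drop the constant direction from the basis so the smooth is identifiable
# next to the global intercept: coefficients live in the (K-1)-dim subspace
# orthogonal to the all-ones direction (B-spline partition of unity).
spline_reparam <- function(K) {
  qr.Q(qr(matrix(1, K, 1)), complete = TRUE)[, -1, drop = FALSE]
}

spline_penalty <- function(K, order) {
  D <- diff(diag(K), differences = order)
  crossprod(D)
}

#' Build per-parameter design structures
#'
#' Materialises the linear predictors as design matrices: intercept and sex
#' contrast (fixed), a reduced-rank P-spline basis of age (difference
#' penalty), and cohort indicator columns (ridge-penalised random
#' intercepts). Sex is coded 0/1 with the lexicographically smaller label as
#' reference.
#'
#' @param table A data frame with the spec's age, sex, cohort (and feature)
#'   columns, no missing values in covariates.
#' @param spec A `gamharm_spec`.
#' @return A list with design matrices `X` per distributional parameter,
#'   block index lists, the spline penalty, and metadata needed to rebuild
#'   the design at prediction time.
#' @export
build_design <- function(table, spec) {
  table <- as.data.frame(table)
  for (col in c(spec$age_col, spec$sex_col, spec$cohort_col)) {
    if (!col %in% names(table)) {
      stop_gamharm("required column '", col, "' is missing",
                   class = "gamharm_data_error")
    }
    if (any(is.na(table[[col]]))) {
      stop_gamharm("missing values in column '", col,
                   "'; exclude incomplete rows before fitting",
                   class = "gamharm_data_error")
    }
  }
  age <- as.numeric(table[[spec$age_col]])
  if (length(unique(age)) <= spec$degree) {
    stop_gamharm("age has ", length(unique(age)),
                 " distinct values; the spline basis is rank-deficient",
                 class = "gamharm_data_error")
  }
  cohort <- as.character(table[[spec$cohort_col]])
  levels <- sort(unique(cohort))
  counts <- table(cohort)
  small <- names(counts)[counts < spec$min_cohort_n]
  if (length(small)) {
    stop_gamharm("cohort(s) ", paste(small, collapse = ", "), " have fewer than ",
                 spec$min_cohort_n, " observations", class = "gamharm_data_error")
  }
  Z <- outer(cohort, levels, "==") * 1
  colnames(Z) <- levels

  sex_raw <- as.character(table[[spec$sex_col]])
  sex_levels <- sort(unique(sex_raw))
  if (length(sex_levels) > 2) {
    stop_gamharm("sex column has more than two levels", class = "gamharm_data_error")
  }
  sex_ref <- sex_levels[1]
  sexind <- as.numeric(sex_raw != sex_ref)

  boundary <- range(age)
  B_raw <- bspline_basis(age, boundary, spec$n_knots, spec$degree)
  K <- ncol(B_raw)
  Q <- spline_reparam(K)
  B <- B_raw %*% Q
  S <- t(Q) %*% spline_penalty(K, spec$penalty_order) %*% Q
  S_rank <- qr(S)$rank

  family <- spec$family
  Xmu <- cbind(`(Intercept)` = 1, sex = sexind, B, Z)
  p_sp <- ncol(B)
  blocks_ls <- list(fixed = 1:2, spline = 2 + seq_len(p_sp),
                    re = 2 + p_sp + seq_along(levels))
  X <- list(mu = Xmu, sigma = Xmu)
  blocks <- list(mu = blocks_ls, sigma = blocks_ls)

  subj <- NULL
  if (isTRUE(spec$subject_re)) {
    subj <- as.character(table[[spec$subject_col]])
    su <- sort(unique(subj))
    Zs <- outer(subj, su, "==") * 1
    colnames(Zs) <- su
    X$mu <- cbind(Xmu, Zs)
    blocks$mu$subject <- ncol(Xmu) + seq_along(su)
  }

  for (p in setdiff(family$params, c("mu", "sigma"))) {
    if (isTRUE(spec$shape_re[[p]])) {
      X[[p]] <- cbind(`(Intercept)` = 1, Z)
      blocks[[p]] <- list(fixed = 1L, re = 1 + seq_along(levels))
    } else {
      X[[p]] <- cbind(`(Intercept)` = matrix(1, nrow(table), 1))
      blocks[[p]] <- list(fixed = 1L)
    }
  }

  list(X = X, blocks = blocks, S_spline = S, S_rank = S_rank,
       meta = list(cohort_levels = levels, sex_ref = sex_ref,
                   boundary = boundary, n_knots = spec$n_knots,
                   degree = spec$degree, penalty_order = spec$penalty_order,
                   K = K, subject_levels = if (!is.null(subj)) sort(unique(subj)),
                   extrapolated = attr(B_raw, "extrapolated")))
}

# Rebuild the covariate design at prediction time from stored metadata.
predict_design <- function(meta, age, sex, cohort) {
  unseen <- setdiff(unique(as.character(cohort)), meta$cohort_levels)
  if (length(unseen)) {
    stop_gamharm("cohort level(s) ", paste(unseen, collapse = ", "),
                 " were not present at fit time", class = "gamharm_data_error")
  }
  B_raw <- bspline_basis(as.numeric(age), meta$boundary, meta$n_knots, meta$degree)
  B <- B_raw %*% spline_reparam(meta$K)
  Z <- outer(as.character(cohort), meta$cohort_levels, "==") * 1
  sexind <- as.numeric(as.character(sex) != meta$sex_ref)
  list(B = B, Z = Z, sexind = sexind,
       extrapolated = attr(B_raw, "extrapolated"))
}
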