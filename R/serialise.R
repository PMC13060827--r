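#' Serialise a fitted model to a self-describing JSON document
#'
#' Stores the family, links, spline configuration (knot range, counts,
#' degree, penalty order), all coefficient vectors, random-effect tables,
#' smoothing parameters and the convergence record, so harmonisation can run
#' later without refitting.
#'
#' @param fit A `gamharm_fit`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return Invisibly the path, or the JSON string when `path` is `NULL`.
#' @export
model_to_json <- function(fit, path = NULL) {
  doc <- list(
    format = "gamharm_fit",
    version = 1L,
    feature = fit$feature,
    family = fit$family$name,
    links = as.list(fit$family$links),
    spec = list(n_knots = fit$spec$n_knots, degree = fit$spec$degree,
                penalty_order = fit$spec$penalty_order,
                shape_re = as.list(fit$spec$shape_re),
                subject_re = fit$spec$subject_re,
                max_iterations = fit$spec$max_iterations,
                min_cohort_n = fit$spec$min_cohort_n,
                age_col = fit$spec$age_col, sex_col = fit$spec$sex_col,
                cohort_col = fit$spec$cohort_col,
                subject_col = fit$spec$subject_col,
                feature = fit$spec$feature),
    meta = list(cohort_levels = fit$meta$cohort_levels,
                sex_ref = fit$meta$sex_ref, boundary = fit$meta$boundary,
                n_knots = fit$meta$n_knots, degree = fit$meta$degree,
                penalty_order = fit$meta$penalty_order, K = fit$meta$K,
                subject_levels = fit$meta$subject_levels),
    coef = fit$coef,
    blocks = fit$blocks,
    lambda = lapply(fit$lambda, as.list),
    re = fit$re,
    converged = fit$converged,
    n_iterations = fit$n_iter,
    global_deviance = fit$deviance,
    fallback_path = fit$fallback_path)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Restore a fitted model from its JSON document
#'
#' @param path Path to a document written by [model_to_json()], or the JSON
#'   string itself.
#' @return A `gamharm_fit` usable by [predict_parameters()] and the
#'   harmonisation stages.
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "gamharm_fit")) {
    stop_gamharm("not a gamharm model document", class = "gamharm_io_error")
  }
  fam <- get_family(doc$family)
  spec <- do.call(model_spec, c(list(family = fam),
                                doc$spec[setdiff(names(doc$spec), "shape_re")],
                                list(shape_re = unlist(doc$spec$shape_re))))
  blocks <- lapply(doc$blocks, function(b) lapply(b, as.integer))
  re <- lapply(doc$re, function(r) {
    r$offsets <- stats::setNames(as.numeric(r$offsets), r$levels)
    r
  })
  structure(list(spec = spec, family = fam, feature = doc$feature,
                 coef = lapply(doc$coef, as.numeric), blocks = blocks,
                 meta = doc$meta, lambda = doc$lambda, re = re,
                 converged = doc$converged, n_iter = doc$n_iterations,
                 deviance = doc$global_deviance,
                 fallback_path = doc$fallback_path),
            class = "gamharm_fit")
}
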