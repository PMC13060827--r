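#' The prespecified distribution-selection hierarchy
#'
#' Six specifications attempted in order until one converges:
#' \enumerate{
#'   \item SHASH with cohort random intercepts on both shape parameters
#'     (skewness `nu` and tail weight `tau`);
#'   \item SHASH with a random intercept on `nu` only;
#'   \item SHASH with a random intercept on `tau` only;
#'   \item SHASH with both shape parameters as global intercepts;
#'   \item generalised gamma (requires a strictly positive response);
#'   \item normal (final fallback).
#' }
#' The location and scale submodels are identical in every member.
#'
#' @return A list of specification templates (family name + shape_re).
#' @export
fallback_hierarchy <- function() {
  list(
    list(family = "SHASH", shape_re = c(nu = TRUE,  tau = TRUE)),
    list(family = "SHASH", shape_re = c(nu = TRUE,  tau = FALSE)),
    list(family = "SHASH", shape_re = c(nu = FALSE, tau = TRUE)),
    list(family = "SHASH", shape_re = c(nu = FALSE, tau = FALSE)),
    list(family = "GG",    shape_re = c(nu = FALSE, tau = FALSE)),
    list(family = "NORMAL", shape_re = c(nu = FALSE, tau = FALSE))
  )
}

#' Fit a feature with the sequential distribution-selection fallback
#'
#' Attempts each member of [fallback_hierarchy()] in order and returns the
#' first converged fit. Every attempt is recorded in the returned model's
#' `fallback_path` (family, shape random effects, converged flag, iteration
#' count, deviance or the error message), so the attempted sequence is
#' always a prefix of the documented hierarchy. A GG attempt on a response
#' with non-positive values is recorded as failed (support violation) and
#' the hierarchy continues.
#'
#' @param table Data frame with feature and covariates.
#' @param feature Response column name.
#' @param spec_args Named list of extra arguments forwarded to
#'   [model_spec()] (e.g. `n_knots`, `min_cohort_n`, `subject_re`).
#' @param seed Optional integer seed.
#' @param control A [fit_control()].
#' @return A `gamharm_fit` with a populated `fallback_path`.
#' @export
fit_with_fallback <- function(table, feature, spec_args = list(),
                              seed = NULL, control = fit_control()) {
  spec_args$shape_re <- NULL   # the hierarchy owns the shape random effects
  path <- list()
  for (step in fallback_hierarchy()) {
    spec <- do.call(model_spec, c(list(family = step$family, feature = feature,
                                       shape_re = step$shape_re), spec_args))
    fit <- tryCatch(fit_gamlss(table, spec, seed = seed, control = control),
                    gamharm_error = function(e) e)
    attempt <- list(family = step$family, shape_re = step$shape_re)
    if (inherits(fit, "condition")) {
      attempt$converged <- FALSE
      attempt$error <- conditionMessage(fit)
      path[[length(path) + 1]] <- attempt
      next
    }
    attempt$converged <- fit$converged
    attempt$n_iter <- fit$n_iter
    attempt$deviance <- fit$deviance
    path[[length(path) + 1]] <- attempt
    if (fit$converged) {
      fit$fallback_path <- path
      return(fit)
    }
  }
  diag_txt <- vapply(path, function(a) {
    paste0(a$family, "[nu_re=", a$shape_re[["nu"]], ",tau_re=",
           a$shape_re[["tau"]], "]: ",
           if (!is.null(a$error)) a$error else
             paste0("not converged after ", a$n_iter, " cycles"))
  }, "")
  stop_gamharm("no member of the distribution hierarchy converged for '",
               feature, "':\n  ", paste(diag_txt, collapse = "\n  "),
               class = "gamharm_fit_error")
}
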