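#' Control settings for the backfitting fitter
#'
#' @param max_outer Maximum outer backfitting cycles; `NULL` takes the spec's
#'   `max_iterations` (default 200).
#' @param dev_tol Convergence tolerance on the change in global deviance; the
#'   fit is declared converged when the absolute change is below `dev_tol`
#'   for two consecutive outer cycles.
#' @param lambda_update_until Smoothing and random-effect variance parameters
#'   are updated by local-ML (EM) steps up to this cycle, then frozen so the
#'   penalised objective decreases monotonically thereafter.
#' @param max_halvings Maximum step-halvings per inner update.
#' @param trace Print per-cycle deviance.
#' @return A list of class `gamharm_control`.
#' @export
fit_control <- function(max_outer = NULL, dev_tol = 1e-3,
                        lambda_update_until = 25, max_halvings = 12,
                        trace = FALSE) {
  structure(list(max_outer = max_outer, dev_tol = dev_tol,
                 lambda_update_until = lambda_update_until,
                 max_halvings = max_halvings, trace = trace),
            class = "gamharm_control")
}

# Likelihood evaluation that never throws for parameter values visited during
# optimisation: invalid rows score -Inf and are rejected by step-halving.
ll_internal <- function(y, family, th) {
  switch(family$name,
         SHASH = shash_logpdf(y, th$mu, th$sigma, th$nu, th$tau),
         GG = {
           out <- rep(-Inf, length(y))
           ok <- th$mu > 0 & abs(th$nu) > 1e-12
           if (all(ok)) out <- gg_logpdf(y, th$mu, th$sigma, th$nu)
           else if (any(ok)) {
             idx <- which(ok)
             out[idx] <- gg_logpdf(y[idx], rep_len(th$mu, length(y))[idx],
                                   rep_len(th$sigma, length(y))[idx],
                                   rep_len(th$nu, length(y))[idx])
           }
           out
         },
         NORMAL = stats::dnorm(y, th$mu, th$sigma, log = TRUE))
}

eta_to_theta <- function(family, etas) {
  th <- list()
  for (p in family$params) th[[p]] <- invert_link(etas[[p]], family$links[[p]])
  th
}

#' Fit a hierarchical GAMLSS by penalised backfitting
#'
#' RS-type backfitting: the outer loop cycles over the distributional
#' parameters; for each, an iteratively reweighted penalised least-squares
#' update of the fixed effects, P-spline coefficients and ridge-penalised
#' cohort random intercepts, using numerically differentiated first and
#' second derivatives of the log-likelihood with respect to the linear
#' predictor. Smoothing parameters and random-intercept variances are
#' estimated by local maximum likelihood (EM steps) during early cycles.
#' Convergence requires the change in global deviance to fall below
#' `control$dev_tol` on two consecutive cycles with all coefficients finite
#' and every inner Hessian positive definite; otherwise the returned fit has
#' `converged = FALSE` (consumed by [fit_with_fallback()], never an error).
#'
#' @param table Data frame with the spec's feature and covariate columns.
#' @param spec A [model_spec()].
#' @param seed Optional integer seed (the algorithm is deterministic; the
#'   seed is applied for reproducibility of any downstream stochastic use).
#' @param control A [fit_control()].
#' @return An object of class `gamharm_fit`.
#' @export
fit_gamlss <- function(table, spec, seed = NULL, control = fit_control()) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  family <- spec$family
  y <- as.numeric(table[[spec$feature]])
  if (any(!is.finite(y))) {
    stop_gamharm("response '", spec$feature, "' contains non-finite values",
                 class = "gamharm_data_error")
  }
  if (stats::sd(y) == 0) {
    stop_gamharm("response '", spec$feature, "' is constant",
                 class = "gamharm_data_error")
  }
  if (family$name == "GG" && any(y <= 0)) {
    stop_gamharm("GG family requires a strictly positive response",
                 class = "gamharm_data_error")
  }
  d <- build_design(table, spec)
  n <- length(y)
  params <- family$params
  max_outer <- control$max_outer %||% spec$max_iterations

  ## ----- starting values: the Normal limit of the family ------------------
  beta <- lambda <- list()
  for (k in params) {
    beta[[k]] <- numeric(ncol(d$X[[k]]))
    lam <- c()
    if (!is.null(d$blocks[[k]]$spline)) lam["spline"] <- 1
    if (!is.null(d$blocks[[k]]$re)) lam["re"] <- 1
    if (!is.null(d$blocks[[k]]$subject)) lam["subject"] <- 1
    lambda[[k]] <- lam
  }
  Xmu <- d$X$mu
  P0 <- diag(1e-6, ncol(Xmu))
  P0[d$blocks$mu$fixed, d$blocks$mu$fixed] <- 0
  diag(P0)[1] <- 0
  b_init <- tryCatch(
    solve(crossprod(Xmu) + P0 + diag(1e-8, ncol(Xmu)), crossprod(Xmu, y)),
    error = function(e) NULL)
  if (!is.null(b_init)) beta$mu <- drop(b_init)
  mu0 <- drop(Xmu %*% beta$mu)
  if (family$name == "GG" && any(mu0 <= 0)) {
    beta$mu <- numeric(ncol(Xmu)); beta$mu[1] <- mean(y)
    mu0 <- rep(mean(y), n)
  }
  res_sd <- max(stats::sd(y - mu0), 1e-6)
  beta$sigma[1] <- if (family$name == "GG") {
    log(max(res_sd / max(mean(y), 1e-6), 1e-3))
  } else log(res_sd)
  if (family$name == "GG") beta$nu[1] <- 1
  # SHASH nu, tau start at 0 on link scale: the Normal limit

  etas <- lapply(params, function(k) drop(d$X[[k]] %*% beta[[k]]))
  names(etas) <- params
  ll0 <- ll_internal(y, family, eta_to_theta(family, etas))

  penalty_matrix <- function(k) {
    p <- ncol(d$X[[k]])
    P <- matrix(0, p, p)
    bl <- d$blocks[[k]]
    if (!is.null(bl$spline)) {
      P[bl$spline, bl$spline] <- lambda[[k]]["spline"] * d$S_spline
    }
    if (!is.null(bl$re)) diag(P)[bl$re] <- lambda[[k]]["re"]
    if (!is.null(bl$subject)) diag(P)[bl$subject] <- lambda[[k]]["subject"]
    P
  }
  pen_value <- function(k, b) {
    bl <- d$blocks[[k]]; v <- 0
    if (!is.null(bl$spline)) {
      bs <- b[bl$spline]
      v <- v + lambda[[k]]["spline"] * drop(t(bs) %*% d$S_spline %*% bs)
    }
    if (!is.null(bl$re)) v <- v + lambda[[k]]["re"] * sum(b[bl$re]^2)
    if (!is.null(bl$subject)) v <- v + lambda[[k]]["subject"] * sum(b[bl$subject]^2)
    unname(v)
  }

  dev_trace <- pdev_trace <- lambda_changed <- numeric(0)
  hess_pd <- TRUE
  Cinv_store <- list()
  conv_count <- 0L
  dev_prev <- Inf
  converged <- FALSE
  n_iter <- 0L

  for (cycle in seq_len(max_outer)) {
    n_iter <- cycle
    hess_pd <- TRUE   # the convergence rule checks the final cycle's updates
    lam_before <- unlist(lambda)
    for (k in params) {
      X <- d$X[[k]]
      eta_k <- etas[[k]]
      h <- 1e-4 * (1 + abs(eta_k))
      ep <- etas; ep[[k]] <- eta_k + h
      em <- etas; em[[k]] <- eta_k - h
      llp <- ll_internal(y, family, eta_to_theta(family, ep))
      llm <- ll_internal(y, family, eta_to_theta(family, em))
      u <- (llp - llm) / (2 * h)
      w <- -(llp - 2 * ll0 + llm) / h^2
      u[!is.finite(u)] <- 0
      wpos <- w[is.finite(w) & w > 0]
      wref <- if (length(wpos)) stats::median(wpos) else 1
      w[!is.finite(w) | w <= 1e-10 * wref] <- 1e-3 * wref
      w <- pmin(w, 1e6 * wref)

      P <- penalty_matrix(k)
      Xs <- X * sqrt(w)
      A <- crossprod(Xs)
      rhs <- crossprod(X, w * (eta_k + u / w))
      M <- A + P
      ch <- NULL
      for (jit in c(0, 1e-8, 1e-6, 1e-4)) {
        ch <- tryCatch(chol(M + diag(jit * mean(diag(M)), ncol(M))),
                       error = function(e) NULL)
        if (!is.null(ch)) { if (jit > 0) hess_pd <- FALSE; break }
      }
      if (is.null(ch)) { hess_pd <- FALSE; next }
      Cinv <- chol2inv(ch)
      b_prop <- drop(Cinv %*% rhs)

      crit_old <- -2 * sum(ll0) + pen_value(k, beta[[k]])
      accepted <- FALSE
      b_try <- b_prop
      for (half in seq_len(control$max_halvings)) {
        eta_try <- drop(X %*% b_try)
        etry <- etas; etry[[k]] <- eta_try
        ll_try <- ll_internal(y, family, eta_to_theta(family, etry))
        crit_new <- -2 * sum(ll_try) + pen_value(k, b_try)
        ok <- is.finite(crit_new) &&
          crit_new <= crit_old + 1e-8 * (1 + abs(crit_old))
        if (ok) {
          beta[[k]] <- b_try; etas[[k]] <- eta_try; ll0 <- ll_try
          accepted <- TRUE
          break
        }
        b_try <- (b_try + beta[[k]]) / 2
      }

      if (accepted && cycle <= control$lambda_update_until) {
        bl <- d$blocks[[k]]
        if (!is.null(bl$spline)) {
          bs <- beta[[k]][bl$spline]
          quad <- drop(t(bs) %*% d$S_spline %*% bs)
          trc <- sum(Cinv[bl$spline, bl$spline] * d$S_spline)
          lam_new <- d$S_rank / max(quad + trc, 1e-12)
          ratio <- min(max(lam_new / lambda[[k]]["spline"], 0.1), 10)
          lambda[[k]]["spline"] <- min(max(lambda[[k]]["spline"] * ratio, 1e-7), 1e9)
        }
        for (nm in intersect(c("re", "subject"), names(bl))) {
          idx <- bl[[nm]]
          s2 <- (sum(beta[[k]][idx]^2) + sum(diag(Cinv)[idx])) / length(idx)
          lam_new <- 1 / max(s2, 1e-9)
          ratio <- min(max(lam_new / lambda[[k]][nm], 0.1), 10)
          lambda[[k]][nm] <- min(max(lambda[[k]][nm] * ratio, 1e-7), 1e9)
        }
      }
      Cinv_store[[k]] <- Cinv
    }

    dev <- -2 * sum(ll0)
    pdev <- dev + sum(vapply(params, function(k) pen_value(k, beta[[k]]), 0))
    dev_trace <- c(dev_trace, dev)
    pdev_trace <- c(pdev_trace, pdev)
    lambda_changed <- c(lambda_changed,
                        max(abs(unlist(lambda) - lam_before) /
                              pmax(abs(lam_before), 1e-12), 0))
    if (control$trace) {
      cat(sprintf("cycle %3d  dev %.6f  pdev %.6f\n", cycle, dev, pdev))
    }
    if (is.finite(dev) && abs(dev - dev_prev) < control$dev_tol) {
      conv_count <- conv_count + 1L
    } else conv_count <- 0L
    dev_prev <- dev
    if (conv_count >= 2L) {
      converged <- all(vapply(beta, function(b) all(is.finite(b)), TRUE)) &&
        is.finite(dev) && hess_pd
      break
    }
  }

  ## ----- assemble the fitted-model object ---------------------------------
  re <- list()
  for (k in params) {
    if (!is.null(d$blocks[[k]]$re)) {
      re[[k]] <- list(levels = d$meta$cohort_levels,
                      offsets = stats::setNames(beta[[k]][d$blocks[[k]]$re],
                                                d$meta$cohort_levels),
                      variance = 1 / unname(lambda[[k]]["re"]))
    }
  }
  se_fixed <- lapply(params, function(k) {
    ci <- Cinv_store[[k]]
    if (is.null(ci)) return(NULL)
    idx <- d$blocks[[k]]$fixed
    stats::setNames(sqrt(pmax(diag(ci)[idx], 0)), colnames(d$X[[k]])[idx])
  })
  names(se_fixed) <- params

  structure(list(spec = spec, family = family, feature = spec$feature,
                 coef = beta, blocks = d$blocks, meta = d$meta,
                 S_spline = d$S_spline, lambda = lambda, re = re,
                 se_fixed = se_fixed, converged = converged,
                 n_iter = n_iter, deviance = dev_prev,
                 dev_trace = dev_trace, pdev_trace = pdev_trace,
                 lambda_changed = lambda_changed, hess_pd = hess_pd,
                 n_obs = n, fallback_path = NULL),
            class = "gamharm_fit")
}

#' @export
print.gamharm_fit <- function(x, ...) {
  cat("<gamharm_fit> feature '", x$feature, "', family ", x$family$name,
      ", n = ", x$n_obs, "\n  converged: ", x$converged, " after ", x$n_iter,
      " cycles; deviance ", format(x$deviance, digits = 8), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the fitted distributional parameters for new observations
#'
#' Evaluates each parameter's linear predictor (intercept, sex contrast, age
#' smooth, cohort random intercept) through its link function. Ages outside
#' the fitted knot range use linear extrapolation of the boundary basis and
#' are flagged in the `"extrapolated"` attribute. Cohorts unseen at fit time
#' are an error: the framework has no transfer step for new cohorts.
#'
#' @param fit A `gamharm_fit`.
#' @param newdata Data frame with the spec's age, sex and cohort columns.
#' @param zero_re Set the cohort random intercepts to zero on the link scale
#'   (the harmonised parameters); parameters without a fitted cohort random
#'   effect are carried forward without modification.
#' @return A `tibble` with one column per distributional parameter on the
#'   natural scale; attribute `"extrapolated"` flags out-of-range ages.
#' @export
predict_parameters <- function(fit, newdata, zero_re = FALSE) {
  spec <- fit$spec
  pd <- predict_design(fit$meta, newdata[[spec$age_col]],
                       newdata[[spec$sex_col]], newdata[[spec$cohort_col]])
  out <- list()
  for (k in fit$family$params) {
    bl <- fit$blocks[[k]]
    b <- fit$coef[[k]]
    eta <- rep(b[bl$fixed[1]], nrow(newdata))
    if (length(bl$fixed) > 1) eta <- eta + pd$sexind * b[bl$fixed[2]]
    if (!is.null(bl$spline)) eta <- eta + drop(pd$B %*% b[bl$spline])
    if (!is.null(bl$re) && !zero_re) eta <- eta + drop(pd$Z %*% b[bl$re])
    if (!is.null(bl$subject) && spec$subject_col %in% names(newdata)) {
      subj <- as.character(newdata[[spec$subject_col]])
      m <- match(subj, fit$meta$subject_levels)
      off <- ifelse(is.na(m), 0, b[bl$subject][m])
      eta <- eta + off
    }
    out[[k]] <- invert_link(eta, fit$family$links[[k]])
  }
  res <- tibble::as_tibble(out)
  attr(res, "extrapolated") <- pd$extrapolated
  res
}
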