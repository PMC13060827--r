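#' Cohort-specific centile scores
#'
#' Evaluates each observation's CDF value under its own cohort's fitted
#' conditional distribution (all estimated cohort random effects included).
#' The centile carries the observation's within-cohort, covariate-adjusted
#' rank information forward to quantile mapping. No numerical clipping is
#' applied on this path, so floating-point saturation at 0 or 1 can occur in
#' extreme tails and is caught later by the QC rules.
#'
#' @param fit A `gamharm_fit`.
#' @param table Data frame with the feature and covariate columns.
#' @return Numeric vector of centiles in `[0, 1]`.
#' @export
compute_centiles <- function(fit, table) {
  params <- predict_parameters(fit, table)
  dist_cdf(as.numeric(table[[fit$feature]]), fit$family, as.list(params))
}

#' Harmonised distributional parameters (cohort effects removed)
#'
#' Subtracts each fitted cohort random intercept on its link scale and maps
#' back to the natural scale: identity-scale subtraction for `mu` and `nu`,
#' log-scale subtraction (division after exponentiation) for `sigma` and
#' `tau`. Because the random intercepts are estimated under a zero-mean
#' normal assumption, this replaces each cohort's offset with the
#' population-average effect. Parameters without a fitted cohort random
#' effect are carried forward without modification.
#'
#' @inheritParams compute_centiles
#' @return A `tibble` of harmonised parameters on the natural scale.
#' @export
remove_cohort_effects <- function(fit, table) {
  predict_parameters(fit, table, zero_re = TRUE)
}

#' Quantile-map centiles onto the harmonised distribution
#'
#' Applies the family's quantile function at each observation's centile
#' under the harmonised parameters, returning values on the native
#' measurement scale. Rank ordering within a cohort at fixed covariates is
#' preserved; with all cohort random effects zero the map is the identity.
#' Centiles on or outside (0, 1) yield `NA` here and are flagged by
#' [postprocess_qc()].
#'
#' @param centiles Numeric vector from [compute_centiles()].
#' @param params Harmonised parameters from [remove_cohort_effects()].
#' @param family A `gamharm_family` or name.
#' @return Numeric vector of harmonised values (NA where the centile is
#'   outside the open interval).
#' @export
quantile_map <- function(centiles, params, family) {
  family <- get_family(family)
  out <- rep(NA_real_, length(centiles))
  ok <- is.finite(centiles) & centiles > 0 & centiles < 1
  if (any(ok)) {
    pl <- lapply(as.list(params), function(v) {
      if (length(v) == length(centiles)) v[ok] else v
    })
    out[ok] <- dist_quantile(centiles[ok], family, pl)
  }
  out
}

#' Normative deviation z-scores from centiles
#'
#' The probit transform of the centile. Under a correctly specified model on
#' representative reference data these z-scores follow a standard normal
#' distribution. Centiles at exactly 0 or 1 map to infinite z-scores, which
#' the QC stage sets to missing.
#'
#' @param centiles Numeric vector of centiles.
#' @return Numeric vector of z-scores (possibly infinite at the boundary).
#' @export
centile_to_z <- function(centiles) {
  stats::qnorm(centiles)
}

#' Post-processing quality control of harmonised outputs
#'
#' Applies three rules in order; a record failing an earlier rule is not
#' evaluated by later rules:
#' \enumerate{
#'   \item centiles outside the open interval (0, 1) (exact floating-point
#'     comparison, no epsilon widening): harmonised value and z-score set to
#'     missing, flag `cdf_out_of_range`;
#'   \item harmonised values that are negative (for features declared
#'     non-negative) set to missing, flag `negative_harmonised`, or
#'     non-finite, flag `nonfinite_harmonised`;
#'   \item non-finite z-scores set to missing, flag `nonfinite_z`.
#' }
#'
#' @param centile,y_harmonised,z_score Raw per-observation outputs.
#' @param non_negative Is the feature bounded below at zero? (default TRUE,
#'   as for volumes, thickness and surface area).
#' @return A `tibble` with columns `centile`, `y_harmonised`, `z_score`
#'   (missing where flagged) and `qc_flag` (factor with levels `ok`,
#'   `cdf_out_of_range`, `negative_harmonised`, `nonfinite_harmonised`,
#'   `nonfinite_z`).
#' @export
postprocess_qc <- function(centile, y_harmonised, z_score, non_negative = TRUE) {
  n <- length(centile)
  flag <- rep("ok", n)
  r1 <- !is.finite(centile) | centile <= 0 | centile >= 1
  flag[r1] <- "cdf_out_of_range"
  y_harmonised[r1] <- NA_real_
  z_score[r1] <- NA_real_
  r2neg <- !r1 & non_negative & !is.na(y_harmonised) & is.finite(y_harmonised) &
    y_harmonised < 0
  r2inf <- !r1 & !is.na(y_harmonised) & !is.finite(y_harmonised)
  flag[r2neg] <- "negative_harmonised"
  flag[r2inf] <- "nonfinite_harmonised"
  y_harmonised[r2neg | r2inf] <- NA_real_
  r3 <- !r1 & !r2neg & !r2inf & !is.na(z_score) & !is.finite(z_score)
  flag[r3] <- "nonfinite_z"
  z_score[r3] <- NA_real_
  tibble::tibble(centile = centile, y_harmonised = y_harmonised,
                 z_score = z_score,
                 qc_flag = factor(flag, levels = qc_flag_levels()))
}

qc_flag_levels <- function() {
  c("ok", "cdf_out_of_range", "negative_harmonised",
    "nonfinite_harmonised", "nonfinite_z")
}

#' Fit and harmonise one feature end to end
#'
#' Runs the full per-feature pipeline: sequential-fallback fitting, cohort
#' centiles, cohort-effect removal on the link scale, quantile mapping back
#' to the native scale, probit z-scores, and post-processing QC. The result
#' is deterministic given data, configuration and seed.
#'
#' @param table Data frame in long format (subject, cohort, age, sex,
#'   feature columns).
#' @param feature Response column name.
#' @param non_negative Is the feature zero-bounded? (default TRUE).
#' @param spec_args,seed,control Passed to [fit_with_fallback()].
#' @return A list with elements `fit` (the `gamharm_fit`) and `output`
#'   (tibble: subject, cohort, age, sex, feature, y_raw, centile,
#'   y_harmonised, z_score, qc_flag, family_used).
#' @export
harmonise_feature <- function(table, feature, non_negative = TRUE,
                              spec_args = list(), seed = NULL,
                              control = fit_control()) {
  fit <- fit_with_fallback(table, feature, spec_args = spec_args,
                           seed = seed, control = control)
  out <- harmonise_with_model(fit, table, non_negative = non_negative)
  list(fit = fit, output = out)
}

#' Harmonise a table with an already-fitted model
#'
#' @param fit A `gamharm_fit`.
#' @param table Data frame with the feature and covariate columns.
#' @param non_negative Is the feature zero-bounded?
#' @return The per-observation output tibble (see [harmonise_feature()]).
#' @export
harmonise_with_model <- function(fit, table, non_negative = TRUE) {
  spec <- fit$spec
  cent <- compute_centiles(fit, table)
  hpar <- remove_cohort_effects(fit, table)
  yh <- quantile_map(cent, hpar, fit$family)
  z <- ifelse(is.finite(cent), centile_to_z(pmin(pmax(cent, 0), 1)), NA_real_)
  qc <- postprocess_qc(cent, yh, z, non_negative = non_negative)
  tibble::tibble(
    subject = if (spec$subject_col %in% names(table))
      as.character(table[[spec$subject_col]]) else NA_character_,
    cohort = as.character(table[[spec$cohort_col]]),
    age = as.numeric(table[[spec$age_col]]),
    sex = table[[spec$sex_col]],
    feature = fit$feature,
    y_raw = as.numeric(table[[fit$feature]]),
    centile = qc$centile,
    y_harmonised = qc$y_harmonised,
    z_score = qc$z_score,
    qc_flag = qc$qc_flag,
    family_used = fit$family$name)
}

#' Harmonise several features of one table
#'
#' Loops [harmonise_feature()] over feature columns, deriving a per-feature
#' seed substream from the run seed so results do not depend on feature
#' order of evaluation.
#'
#' @param table Long-format data frame.
#' @param features Character vector of feature column names.
#' @param non_negative Logical, recycled over features.
#' @param spec_args,control See [harmonise_feature()].
#' @param seed Integer run seed.
#' @return A list with `fits` (named list of `gamharm_fit`), `output`
#'   (row-bound per-observation tibble) and `qc_summary` (per-feature flag
#'   counts).
#' @export
harmonise_table <- function(table, features, non_negative = TRUE,
                            spec_args = list(), seed = 1,
                            control = fit_control()) {
  non_negative <- rep_len(non_negative, length(features))
  fits <- list(); outs <- list()
  for (i in seq_along(features)) {
    f <- features[i]
    res <- harmonise_feature(table, f, non_negative = non_negative[i],
                             spec_args = spec_args,
                             seed = substream_seed(seed, i),
                             control = control)
    fits[[f]] <- res$fit
    outs[[f]] <- res$output
  }
  output <- dplyr::bind_rows(outs)
  qc_summary <- output |>
    dplyr::count(.data$feature, .data$qc_flag, .drop = FALSE) |>
    tidyr_pivot(names_from = "qc_flag", values_from = "n")
  list(fits = fits, output = output, qc_summary = qc_summary)
}

# minimal wide pivot (avoids a tidyr dependency for one reshape)
tidyr_pivot <- function(df, names_from, values_from) {
  wide <- stats::reshape(as.data.frame(df), idvar = "feature",
                         timevar = names_from, v.names = values_from,
                         direction = "wide")
  names(wide) <- sub(paste0("^", values_from, "\\."), "", names(wide))
  tibble::as_tibble(wide)
}

# deterministic per-feature seed substreams below 2^31
substream_seed <- function(seed, i) {
  (as.integer(seed) * 1000L + as.integer(i)) %% 2147483647L
}
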