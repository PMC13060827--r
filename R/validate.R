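#' Cohort R-squared increment
#'
#' Fits two nested ordinary least squares models for a feature: a baseline
#' biological model with age (linear or centered degree-3 polynomial) and
#' sex, and an extended model additionally including cohort as a categorical
#' predictor. The increment in R-squared when cohort is added is the
#' proportion of variance attributable to cohort membership beyond age and
#' sex — a magnitude measure of residual batch effect.
#'
#' @param table Data frame with `age`, `sex`, `cohort` columns.
#' @param feature Response column name.
#' @param age_model `"poly3"` (default: centered raw powers up to cubic) or
#'   `"linear"`.
#' @return The increment, a number in `[0, 1]`.
#' @export
cohort_r2_increment <- function(table, feature, age_model = c("poly3", "linear")) {
  age_model <- match.arg(age_model)
  df <- bio_frame(table, feature)
  if (length(unique(df$cohort)) < 2) {
    stop_gamharm("cohort R-squared increment requires at least two cohorts",
                 class = "gamharm_data_error")
  }
  base <- stats::lm(stats::as.formula(paste("y ~", age_terms(age_model), "+ sex")),
                    data = df)
  ext <- stats::update(base, . ~ . + cohort)
  inc <- summary(ext)$r.squared - summary(base)$r.squared
  max(inc, 0)   # nested OLS: mathematically >= 0; guard rounding
}

age_terms <- function(age_model) {
  if (age_model == "poly3") "age_c + I(age_c^2) + I(age_c^3)" else "age_c"
}

bio_frame <- function(table, feature) {
  df <- data.frame(y = as.numeric(table[[feature]]),
                   age = as.numeric(table[["age"]]),
                   sex = factor(table[["sex"]]),
                   cohort = factor(table[["cohort"]]))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$age_c <- df$age - mean(df$age)
  df
}

#' Mean pairwise Kolmogorov-Smirnov statistic across cohorts
#'
#' Regresses age (centered degree-3 polynomial) and sex out of the feature,
#' then computes the exact two-sample KS statistic (supremum of the absolute
#' ECDF difference) for every unique cohort pair on the residuals and
#' averages over pairs. Residualising first isolates distributional
#' differences attributable to cohort rather than to differing age/sex
#' composition. The pooled residualisation (one model across cohorts) is the
#' default; `per_cohort = TRUE` residualises within each cohort instead.
#'
#' @inheritParams cohort_r2_increment
#' @param per_cohort Residualise within each cohort separately.
#' @return The mean pairwise KS statistic in `[0, 1]`; attribute
#'   `"skipped_pairs"` lists pairs skipped for having fewer than two usable
#'   residuals.
#' @export
mean_pairwise_ks <- function(table, feature, per_cohort = FALSE) {
  df <- bio_frame(table, feature)
  if (length(unique(df$cohort)) < 2) {
    stop_gamharm("mean pairwise KS requires at least two cohorts",
                 class = "gamharm_data_error")
  }
  if (per_cohort) {
    df$res <- NA_real_
    for (co in levels(df$cohort)) {
      idx <- df$cohort == co
      df$res[idx] <- stats::residuals(
        stats::lm(y ~ age_c + I(age_c^2) + I(age_c^3) + sex,
                  data = df[idx, , drop = FALSE]))
    }
  } else {
    df$res <- stats::residuals(
      stats::lm(y ~ age_c + I(age_c^2) + I(age_c^3) + sex, data = df))
  }
  cohorts <- levels(droplevels(df$cohort))
  pairs <- utils::combn(cohorts, 2, simplify = FALSE)
  ks <- numeric(0); skipped <- character(0)
  for (pr in pairs) {
    a <- df$res[df$cohort == pr[1]]
    b <- df$res[df$cohort == pr[2]]
    if (length(a) < 2 || length(b) < 2) {
      skipped <- c(skipped, paste(pr, collapse = ":"))
      next
    }
    ks <- c(ks, ks_statistic(a, b))
  }
  structure(mean(ks), skipped_pairs = skipped)
}

# exact two-sample KS statistic from the two ECDFs, evaluated at every
# observed value (tie-safe, unlike the sorted-pooled-sample shortcut)
ks_statistic <- function(a, b) {
  u <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(u) - stats::ecdf(b)(u)))
}

#' Pairwise distributional-moment differences between two cohorts
#'
#' Three direction-free magnitude measures of between-cohort distributional
#' difference: the absolute log SD ratio (scale; invariant to common
#' rescaling of the feature), the absolute difference in moment-based
#' skewness, and the absolute difference in excess kurtosis.
#'
#' @inheritParams cohort_r2_increment
#' @param cohort_pair Character vector of two cohort labels.
#' @return Named numeric vector `abs_log_sd_ratio`, `abs_delta_skewness`,
#'   `abs_delta_excess_kurtosis`.
#' @export
moment_differences <- function(table, feature, cohort_pair) {
  df <- bio_frame(table, feature)
  a <- df$y[df$cohort == cohort_pair[1]]
  b <- df$y[df$cohort == cohort_pair[2]]
  if (length(a) < 4 || length(b) < 4) {
    stop_gamharm("moment differences need at least 4 observations per cohort",
                 class = "gamharm_data_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_gamharm("moment differences undefined with zero SD in a cohort",
                 class = "gamharm_data_error")
  }
  c(abs_log_sd_ratio = abs(log(stats::sd(a) / stats::sd(b))),
    abs_delta_skewness = abs(e1071::skewness(a, type = 1) -
                               e1071::skewness(b, type = 1)),
    abs_delta_excess_kurtosis = abs(e1071::kurtosis(a, type = 1) -
                                      e1071::kurtosis(b, type = 1)))
}

#' Spearman rank correlation with age
#'
#' Rank correlation between each feature and age: robust to non-Gaussian
#' marginals and invariant to strictly monotone transforms of the feature.
#' Ties receive average ranks. A Benjamini-Hochberg q-value is reported
#' across features.
#'
#' @param table Data frame.
#' @param features Character vector of feature column names.
#' @return Tibble with columns `feature`, `rho`, `p_value`, `q_value`.
#' @export
spearman_age <- function(table, features) {
  age <- as.numeric(table[["age"]])
  if (length(unique(age)) < 3) {
    stop_gamharm("Spearman age correlation needs at least 3 distinct ages",
                 class = "gamharm_data_error")
  }
  rows <- lapply(features, function(f) {
    y <- as.numeric(table[[f]])
    ok <- stats::complete.cases(y, age)
    if (stats::sd(y[ok]) == 0) {
      stop_gamharm("feature '", f, "' is constant; Spearman rho undefined",
                   class = "gamharm_data_error")
    }
    ct <- suppressWarnings(stats::cor.test(y[ok], age[ok], method = "spearman",
                                           exact = FALSE))
    tibble::tibble(feature = f, rho = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Sex-effect size and significance per feature
#'
#' Cohen's d with the pooled standard deviation (sign convention:
#' reference-minus-other, where the reference is the lexicographically
#' smaller sex label), a two-sided Welch two-sample t-test, and
#' Benjamini-Hochberg FDR correction across features.
#'
#' @inheritParams spearman_age
#' @return Tibble with columns `feature`, `cohens_d`, `p_value`, `q_value`.
#' @export
sex_effect <- function(table, features) {
  sex <- as.character(table[["sex"]])
  lv <- sort(unique(sex))
  if (length(lv) != 2) {
    stop_gamharm("sex effect requires exactly two sex groups",
                 class = "gamharm_data_error")
  }
  rows <- lapply(features, function(f) {
    y <- as.numeric(table[[f]])
    a <- y[sex == lv[1] & !is.na(y)]
    b <- y[sex == lv[2] & !is.na(y)]
    if (length(a) < 2 || length(b) < 2) {
      stop_gamharm("feature '", f, "' needs >= 2 observations per sex group",
                   class = "gamharm_data_error")
    }
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    d <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
    p <- if (sp == 0) 1 else stats::t.test(a, b, var.equal = FALSE)$p.value
    tibble::tibble(feature = f, cohens_d = d, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Data-retention accounting
#'
#' A record is lost if it was valid (finite) before harmonisation but is
#' missing afterwards. Counts and rates are reported per feature and
#' overall. `pre` and `post` must describe the same row universe.
#'
#' @param pre Data frame of pre-harmonisation feature values (or the raw
#'   table restricted to the feature columns).
#' @param post Data frame of post-harmonisation values with the same
#'   dimensions and column names.
#' @return A list: `per_feature` tibble (`feature`, `valid_pre`, `lost`,
#'   `rate`) and `overall` (`valid_pre`, `lost`, `rate`).
#' @export
retention_report <- function(pre, post) {
  if (!identical(dim(pre), dim(post)) ||
      !identical(sort(names(pre)), sort(names(post)))) {
    stop_gamharm("pre and post tables are misaligned",
                 class = "gamharm_data_error")
  }
  feats <- names(pre)
  rows <- lapply(feats, function(f) {
    vp <- is.finite(as.numeric(pre[[f]]))
    lost <- vp & !is.finite(as.numeric(post[[f]]))
    tibble::tibble(feature = f, valid_pre = sum(vp), lost = sum(lost),
                   rate = if (sum(vp)) sum(lost) / sum(vp) else 0)
  })
  per_feature <- dplyr::bind_rows(rows)
  list(per_feature = per_feature,
       overall = list(valid_pre = sum(per_feature$valid_pre),
                      lost = sum(per_feature$lost),
                      rate = sum(per_feature$lost) /
                        max(sum(per_feature$valid_pre), 1)))
}

#' Full pre/post validation report for a harmonisation run
#'
#' Computes the metric suite on the pre-harmonisation and post-harmonisation
#' data: cohort R-squared increment, mean pairwise KS statistic, Spearman
#' age correlation and Cohen's d for sex (with Welch p and BH q), plus
#' retention accounting.
#'
#' @param pre_table Long-format table with raw feature columns.
#' @param post_table Same table with harmonised values in the feature
#'   columns (NA where QC removed a record).
#' @param features Character vector of feature column names.
#' @return A list: `metrics` (tidy tibble feature x metric x state) and
#'   `retention` (see [retention_report()]).
#' @export
validation_report <- function(pre_table, post_table, features) {
  one_state <- function(tab, state) {
    r2 <- vapply(features, function(f) cohort_r2_increment(tab, f), 0)
    ks <- vapply(features, function(f) as.numeric(mean_pairwise_ks(tab, f)), 0)
    sp <- spearman_age(tab, features)
    sx <- sex_effect(tab, features)
    tibble::tibble(
      feature = rep(features, 4),
      metric = rep(c("cohort_r2_increment", "mean_pairwise_ks",
                     "spearman_rho_age", "cohens_d_sex"), each = length(features)),
      value = c(r2, ks, sp$rho, sx$cohens_d),
      q_value = c(rep(NA_real_, 2 * length(features)), sp$q_value, sx$q_value),
      state = state)
  }
  metrics <- dplyr::bind_rows(one_state(pre_table, "pre"),
                              one_state(post_table, "post"))
  retention <- retention_report(pre_table[features], post_table[features])
  list(metrics = metrics, retention = retention)
}
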