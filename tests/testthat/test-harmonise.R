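test_that("centiles sit at one half at the conditional median and order with y", {
  tab <- make_shash_table(n_per = 600, seed = 301)
  fit <- fit_gamlss(tab, model_spec("SHASH", "y",
                                    shape_re = c(nu = FALSE, tau = FALSE)))
  # rows placed exactly at the fitted conditional median
  nd <- tibble::tibble(age = c(40, 55), sex = c(1, 2), cohort = c("A", "B"))
  pp <- predict_parameters(fit, nd)
  nd$y <- dist_quantile(rep(0.5, 2), fit$family, as.list(pp))
  expect_equal(compute_centiles(fit, nd), c(0.5, 0.5), tolerance = 1e-10)
  # identical covariates: centile order equals raw order
  nd2 <- tibble::tibble(age = 50, sex = 1, cohort = "A",
                        y = sort(rnorm(20, 10, 2)))
  expect_true(all(diff(compute_centiles(fit, nd2)) > 0))
  expect_error(compute_centiles(fit, tibble::tibble(age = 50, sex = 1,
                                                    cohort = "X", y = 1)),
               class = "gamharm_data_error")
})

test_that("cohort-effect removal subtracts exactly on the link scale", {
  tab <- make_shash_table(n_per = 500, seed = 302)
  fit <- fit_gamlss(tab, model_spec("SHASH", "y",
                                    shape_re = c(nu = FALSE, tau = FALSE)))
  pp <- predict_parameters(fit, tab)
  ph <- remove_cohort_effects(fit, tab)
  b_mu <- fit$re$mu$offsets[tab$cohort]
  b_si <- fit$re$sigma$offsets[tab$cohort]
  expect_equal(ph$mu, pp$mu - b_mu, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ph$sigma, pp$sigma * exp(-b_si), tolerance = 1e-12,
               ignore_attr = TRUE)
  # shape parameters without cohort random effects are carried forward
  expect_equal(ph$nu, pp$nu, ignore_attr = TRUE)
  expect_equal(ph$tau, pp$tau, ignore_attr = TRUE)
  # harmonised parameters identical across cohorts at identical covariates
  nd <- tibble::tibble(age = 45, sex = 1, cohort = c("A", "B"))
  phh <- remove_cohort_effects(fit, nd)
  expect_equal(phh$mu[1], phh$mu[2], tolerance = 1e-12)
  expect_equal(phh$sigma[1], phh$sigma[2], tolerance = 1e-12)
})

test_that("zero cohort effects make harmonisation the identity map", {
  tab <- make_shash_table(n_per = 1000, seed = 303,
                          mu_off = c(A = 0, B = 0), sigma_off = c(A = 0, B = 0))
  fit <- fit_gamlss(tab, model_spec("SHASH", "y",
                                    shape_re = c(nu = FALSE, tau = FALSE)))
  for (k in names(fit$re)) fit$coef[[k]][fit$blocks[[k]]$re] <- 0
  out <- harmonise_with_model(fit, tab, non_negative = FALSE)
  rel <- abs(out$y_harmonised - out$y_raw) / pmax(abs(out$y_raw), 1e-9)
  expect_lt(max(rel), 1e-8)
})

test_that("quantile mapping removes injected offsets on each parameter", {
  # location offsets: cohort mean gap collapses
  tab <- make_shash_table(n_per = 2000, seed = 304, mu_off = c(A = -1, B = 1))
  res <- harmonise_feature(tab, "y", non_negative = FALSE,
                           spec_args = list(shape_re = c(nu = FALSE, tau = FALSE)))
  out <- res$output
  gap_pre <- abs(diff(tapply(out$y_raw, out$cohort, mean)))
  gap_post <- abs(diff(tapply(out$y_harmonised, out$cohort, mean)))
  expect_gt(gap_pre, 1.5)
  expect_lt(gap_post, 0.1 * gap_pre)   # >= 90% of the contrast removed

  # scale offsets: residual SD ratio returns to ~1
  tab2 <- make_shash_table(n_per = 2000, seed = 305,
                           mu_off = c(A = 0, B = 0),
                           sigma_off = c(A = -0.25, B = 0.25))
  res2 <- harmonise_feature(tab2, "y", non_negative = FALSE,
                            spec_args = list(shape_re = c(nu = FALSE, tau = FALSE)))
  out2 <- res2$output
  resid_by <- function(v) {
    r <- residuals(lm(v ~ poly(out2$age, 3) + factor(out2$sex)))
    tapply(r, out2$cohort, sd)
  }
  ratio_pre <- resid_by(out2$y_raw)[["B"]] / resid_by(out2$y_raw)[["A"]]
  ratio_post <- resid_by(out2$y_harmonised)[["B"]] / resid_by(out2$y_harmonised)[["A"]]
  expect_gt(ratio_pre, exp(0.5) * 0.9)
  expect_lt(abs(ratio_post - 1), 0.05)

  # skewness offsets handled through the nu random intercept
  tab3 <- make_shash_table(n_per = 2000, seed = 306,
                           mu_off = c(A = 0, B = 0),
                           nu_off = c(A = -0.4, B = 0.4))
  res3 <- harmonise_feature(tab3, "y", non_negative = FALSE,
                            spec_args = list(shape_re = c(nu = TRUE, tau = FALSE)))
  out3 <- res3$output
  sk <- function(v, co) e1071::skewness(v[out3$cohort == co], type = 1)
  gap_pre <- abs(sk(out3$y_raw, "B") - sk(out3$y_raw, "A"))
  gap_post <- abs(sk(out3$y_harmonised, "B") - sk(out3$y_harmonised, "A"))
  expect_lt(gap_post, 0.1 * gap_pre + 0.05)
})

test_that("rank ordering is preserved within cohort at fixed covariates", {
  tab <- make_shash_table(n_per = 500, seed = 307)
  fit <- fit_gamlss(tab, model_spec("SHASH", "y",
                                    shape_re = c(nu = FALSE, tau = FALSE)))
  nd <- tibble::tibble(age = 50, sex = 2, cohort = "B", y = rnorm(200, 11, 2))
  out <- harmonise_with_model(fit, nd, non_negative = FALSE)
  expect_equal(cor(out$y_raw, out$y_harmonised, method = "kendall"), 1)
})

test_that("probit z-scores follow the standard normal under the true model", {
  sim <- sim_benchmark(seed = 5, n_per_cohort = 1250, n_features = 1)
  tp <- true_parameters(sim$truth$features$f01, sim$table)
  cent <- dist_cdf(sim$table$f01, "SHASH", as.list(tp))
  expect_equal(centile_to_z(0.5), 0)
  expect_equal(centile_to_z(0.975), 1.959964, tolerance = 1e-6)
  z <- centile_to_z(cent)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("QC rules fire in order and flag counts are exclusive", {
  qc <- postprocess_qc(centile = c(0.5, 1.0, 0.2, 0.0, 0.8, 0.3),
                       y_harmonised = c(2, 5, -0.3, -1, Inf, 1),
                       z_score = c(0, Inf, -0.8, -Inf, 2, Inf))
  expect_equal(as.character(qc$qc_flag),
               c("ok", "cdf_out_of_range", "negative_harmonised",
                 "cdf_out_of_range", "nonfinite_harmonised", "nonfinite_z"))
  expect_true(all(is.na(qc$y_harmonised[qc$qc_flag %in%
    c("cdf_out_of_range", "negative_harmonised", "nonfinite_harmonised")])))
  expect_true(all(is.na(qc$z_score[qc$qc_flag %in%
    c("cdf_out_of_range", "nonfinite_z")])))
  # negative values are tolerated for features not declared non-negative
  qc2 <- postprocess_qc(0.2, -0.3, -0.8, non_negative = FALSE)
  expect_equal(as.character(qc2$qc_flag), "ok")
  expect_equal(qc2$y_harmonised, -0.3)
  # boundary comparison is exact: a centile just inside survives
  qc3 <- postprocess_qc(1 - 1e-12, 3, centile_to_z(1 - 1e-12))
  expect_equal(as.character(qc3$qc_flag), "ok")
})

test_that("single-cohort end-to-end harmonisation is a near-identity", {
  set.seed(308)
  n <- 800
  tab <- tibble::tibble(subject = as.character(1:n), cohort = "only",
                        age = runif(n, 20, 80), sex = sample(1:2, n, TRUE))
  tab$y <- 8 + 0.05 * tab$age + rnorm(n)
  res <- harmonise_feature(tab, "y", non_negative = FALSE,
                           spec_args = list(shape_re = c(nu = FALSE, tau = FALSE)))
  ok <- res$output$qc_flag == "ok"
  rel <- abs(res$output$y_harmonised[ok] - res$output$y_raw[ok]) /
    pmax(abs(res$output$y_raw[ok]), 1e-9)
  # one cohort: the single shrunk offset is near zero, so y is near-unchanged
  expect_lt(stats::quantile(rel, 0.99), 0.02)
})
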