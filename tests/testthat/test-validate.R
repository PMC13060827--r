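test_that("cohort R2 increment is near zero under the null and matches a
           sum-of-squares oracle under pure cohort shifts", {
  set.seed(401)
  n <- 3000
  tab <- tibble::tibble(cohort = sample(c("A", "B", "C"), n, TRUE),
                        age = runif(n, 20, 80), sex = sample(1:2, n, TRUE))
  tab$y <- 2 + 0.05 * tab$age + 0.3 * (tab$sex == 2) + rnorm(n)
  expect_lt(cohort_r2_increment(tab, "y"), 0.005)

  # cohort offsets only, no covariate effect: increment equals the
  # between-cohort share of variance from the explicit SS decomposition
  tab2 <- tab
  offs <- c(A = -1, B = 0, C = 1)
  tab2$y <- offs[tab2$cohort] + rnorm(n)
  inc <- cohort_r2_increment(tab2, "y")
  grand <- mean(tab2$y)
  ssb <- sum(tapply(tab2$y, tab2$cohort,
                    function(v) length(v) * (mean(v) - grand)^2))
  sst <- sum((tab2$y - grand)^2)
  expect_equal(inc, ssb / sst, tolerance = 0.01)
  expect_gte(inc, 0)
  expect_error(cohort_r2_increment(dplyr::filter(tab, cohort == "A"), "y"),
               class = "gamharm_data_error")
})

test_that("mean pairwise KS hits its exact endpoints and null behaviour", {
  # exact endpoints of the statistic itself
  set.seed(400)
  x <- rnorm(20)
  expect_identical(gamharm:::ks_statistic(x, x), 0)
  expect_identical(gamharm:::ks_statistic(1:3, 10:12), 1)
  # identical cohorts: at most one ECDF step of floating-point jitter from
  # the shared residualisation; disjoint cohorts: exactly one
  base <- tibble::tibble(age = rep(1:10, 2), sex = rep(1:2, 10))
  a <- base; a$cohort <- "A"; a$y <- 0.1 * a$age + rnorm(20, sd = 0.5)
  b <- a; b$cohort <- "B"
  expect_lte(as.numeric(mean_pairwise_ks(dplyr::bind_rows(a, b), "y")),
             1 / 20 + 1e-12)
  b2 <- b; b2$y <- b2$y + 10   # residuals remain disjoint
  expect_equal(as.numeric(mean_pairwise_ks(dplyr::bind_rows(a, b2), "y")), 1)
  # homogeneous random split: statistic below the 95% null quantile
  set.seed(402)
  n <- 1000
  hom <- tibble::tibble(cohort = rep(c("A", "B"), each = n),
                        age = runif(2 * n, 20, 80),
                        sex = sample(1:2, 2 * n, TRUE))
  hom$y <- 0.02 * hom$age + rnorm(2 * n)
  expect_lt(as.numeric(mean_pairwise_ks(hom, "y")), 1.36 * sqrt(2 / n))
  # tie-free case agrees with the stats::ks.test route
  set.seed(407)
  x1 <- rnorm(300); x2 <- rnorm(300, 0.4)
  expect_equal(gamharm:::ks_statistic(x1, x2),
               unname(suppressWarnings(ks.test(x1, x2)$statistic)),
               tolerance = 1e-12)
  # symmetric in cohort labels
  hom2 <- hom; hom2$cohort <- ifelse(hom$cohort == "A", "B", "A")
  expect_equal(as.numeric(mean_pairwise_ks(hom2, "y")),
               as.numeric(mean_pairwise_ks(hom, "y")))
})

test_that("moment differences separate scale from shape and are scale-invariant", {
  set.seed(403)
  x <- rnorm(500, 5, 2)
  tab <- tibble::tibble(cohort = rep(c("A", "B"), each = 500),
                        age = runif(1000, 20, 80),
                        sex = sample(1:2, 1000, TRUE), y = c(x, x))
  expect_equal(unname(moment_differences(tab, "y", c("A", "B"))), c(0, 0, 0))
  tab$y <- c(x, 2 * x)
  md <- moment_differences(tab, "y", c("A", "B"))
  expect_equal(unname(md["abs_log_sd_ratio"]), log(2), tolerance = 1e-10)
  expect_equal(unname(md["abs_delta_skewness"]), 0, tolerance = 1e-10)
  expect_equal(unname(md["abs_delta_excess_kurtosis"]), 0, tolerance = 1e-10)
  # multiplying the whole feature by a constant changes nothing
  tab2 <- tab; tab2$y <- tab2$y * 7.3
  expect_equal(moment_differences(tab2, "y", c("A", "B")), md, tolerance = 1e-10)
  # known-moment check: exponential vs normal at large n
  set.seed(404)
  tab3 <- tibble::tibble(cohort = rep(c("A", "B"), each = 10000),
                         age = 50, sex = 1,
                         y = c(rexp(10000), rnorm(10000)))
  tab3$age <- runif(20000, 20, 80)
  md3 <- moment_differences(tab3, "y", c("A", "B"))
  expect_equal(unname(md3["abs_delta_skewness"]), 2, tolerance = 0.3)
  expect_equal(unname(md3["abs_delta_excess_kurtosis"]), 6, tolerance = 1.5)
  tabz <- tab; tabz$y <- rep(1, 1000)
  expect_error(moment_differences(tabz, "y", c("A", "B")),
               class = "gamharm_data_error")
})

test_that("Spearman age correlation is monotone-invariant and consistent", {
  set.seed(405)
  n <- 4000
  tab <- tibble::tibble(age = runif(n, 20, 80), sex = sample(1:2, n, TRUE),
                        cohort = "A")
  tab$exact <- tab$age
  tab$mono <- exp(tab$age / 20)
  r <- 0.5176381  # Pearson r giving population Spearman rho = 0.5
  tab$noisy <- r * scale(tab$age) + sqrt(1 - r^2) * rnorm(n)
  sp <- spearman_age(tab, c("exact", "mono", "noisy"))
  expect_equal(sp$rho[1], 1)
  expect_equal(sp$rho[2], 1)
  expect_lt(abs(sp$rho[3] - 0.5), 3 / sqrt(n))
  expect_true(all(diff(sp$q_value[order(sp$p_value)]) >= -1e-15))
  tab$flat <- 1
  expect_error(spearman_age(tab, "flat"), class = "gamharm_data_error")
})

test_that("Cohen's d uses the pooled SD with the documented sign convention", {
  tab <- tibble::tibble(sex = rep(1:2, each = 3), y = c(1, 2, 3, 3, 4, 5),
                        age = 1:6, cohort = "A")
  sx <- sex_effect(tab, "y")
  expect_equal(sx$cohens_d, -2)   # means 2 vs 4, pooled SD 1, reference-minus-other
  tab2 <- tibble::tibble(sex = rep(1:2, each = 3), y = rep(c(1, 2, 3), 2),
                         age = 1:6, cohort = "A")
  sx2 <- sex_effect(tab2, "y")
  expect_equal(sx2$cohens_d, 0)
  expect_equal(sx2$p_value, 1)
  # affine invariance of |d|
  tab3 <- tab; tab3$y <- 100 + 7 * tab3$y
  expect_equal(sex_effect(tab3, "y")$cohens_d, sx$cohens_d, tolerance = 1e-12)
})

test_that("BH correction across features recovers planted sex effects", {
  set.seed(406)
  n <- 200; m <- 50; true_idx <- 1:5
  reps <- 40
  recovered <- fp <- numeric(reps)
  for (r in seq_len(reps)) {
    sex <- rep(1:2, each = n / 2)
    tab <- tibble::tibble(sex = sex, age = runif(n, 20, 80), cohort = "A")
    for (j in 1:m) {
      tab[[paste0("f", j)]] <- rnorm(n) + (j %in% true_idx) * 0.8 * (sex == 2)
    }
    sx <- sex_effect(tab, paste0("f", 1:m))
    hits <- which(sx$q_value < 0.05)
    recovered[r] <- length(intersect(hits, true_idx))
    fp[r] <- length(setdiff(hits, true_idx))
  }
  expect_gte(mean(recovered), 4)
  expect_lt(mean(fp), 0.5)
})

test_that("retention accounting counts exactly the records lost to QC", {
  pre <- tibble::tibble(a = rnorm(1000), b = rnorm(1000))
  post <- pre
  expect_equal(retention_report(pre, post)$overall$lost, 0)
  post$a[c(5, 17, 101)] <- NA
  rep <- retention_report(pre, post)
  expect_equal(rep$per_feature$lost, c(3, 0))
  expect_equal(rep$per_feature$rate[1], 0.003)
  expect_equal(rep$overall$lost, 3)
  expect_equal(rep$overall$rate, 3 / 2000)
  expect_error(retention_report(pre, post[1:10, ]),
               class = "gamharm_data_error")
})

test_that("the tidy validation report covers both states and all metrics", {
  sim <- sim_benchmark(seed = 9, n_per_cohort = 150, n_features = 2)
  post <- sim$table
  post$f01 <- post$f01 + ifelse(post$cohort == "cohort1", -0.5, 0.2)
  rep <- validation_report(sim$table, post, c("f01", "f02"))
  expect_setequal(unique(rep$metrics$state), c("pre", "post"))
  expect_setequal(unique(rep$metrics$metric),
                  c("cohort_r2_increment", "mean_pairwise_ks",
                    "spearman_rho_age", "cohens_d_sex"))
  expect_equal(nrow(rep$metrics), 2 * 4 * 2)
  expect_true(all(rep$metrics$value[rep$metrics$metric == "mean_pairwise_ks"] >= 0))
})
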