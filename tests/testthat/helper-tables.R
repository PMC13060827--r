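# Small simulated tables used across test files. All are built in code at
# test time under fixed seeds.

# Two (or more) cohorts with a linear age trend, sex effect and known
# cohort offsets on the location, normal noise.
make_normal_table <- function(n_per = 800, offsets = c(A = -0.8, B = 0.8),
                              sd = 1.5, seed = 101, age_range = c(20, 80)) {
  set.seed(seed)
  labs <- names(offsets)
  tab <- dplyr::bind_rows(lapply(labs, function(lb) {
    tibble::tibble(cohort = lb,
                   age = stats::runif(n_per, age_range[1], age_range[2]),
                   sex = sample(1:2, n_per, TRUE))
  }))
  tab$subject <- as.character(seq_len(nrow(tab)))
  tab$y <- 5 + 0.04 * tab$age + 0.5 * (tab$sex == 2) +
    offsets[tab$cohort] + stats::rnorm(nrow(tab), 0, sd)
  tab
}

# SHASH data with known fixed effects and cohort offsets on chosen
# parameters (link scale).
make_shash_table <- function(n_per = 2000, seed = 202,
                             beta0 = 10, beta1 = 0.6, gamma0 = 0,
                             gamma1 = 0.1, delta0 = 0.3, eps0 = 0.05,
                             mu_off = c(A = -1, B = 1),
                             sigma_off = NULL, nu_off = NULL) {
  set.seed(seed)
  labs <- names(mu_off)
  zero <- stats::setNames(rep(0, length(labs)), labs)
  if (is.null(sigma_off)) sigma_off <- zero
  if (is.null(nu_off)) nu_off <- zero
  tab <- dplyr::bind_rows(lapply(seq_along(labs), function(i) {
    tibble::tibble(cohort = labs[i],
                   age = stats::runif(n_per, 15 + 10 * i, 60 + 10 * i),
                   sex = sample(1:2, n_per, TRUE))
  }))
  tab$subject <- as.character(seq_len(nrow(tab)))
  mu <- beta0 + 0.5 * (tab$age - 50) / 30 + beta1 * (tab$sex == 2) +
    mu_off[tab$cohort]
  sigma <- exp(gamma0 + gamma1 * (tab$sex == 2) + sigma_off[tab$cohort])
  nu <- delta0 + nu_off[tab$cohort]
  tau <- exp(eps0)
  z <- stats::rnorm(nrow(tab))
  tab$y <- mu + sigma * sinh((asinh(z) + nu) / tau)
  attr(tab, "truth") <- list(beta0 = beta0, beta1 = beta1, gamma0 = gamma0,
                             gamma1 = gamma1, delta0 = delta0, eps0 = eps0,
                             mu_off = mu_off, sigma_off = sigma_off,
                             nu_off = nu_off)
  tab
}

random_shash_params <- function() {
  list(mu = stats::runif(1, -3, 3), sigma = stats::runif(1, 0.3, 3),
       nu = stats::runif(1, -1, 1), tau = stats::runif(1, 0.5, 2))
}
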