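# gamharm

Multi-cohort harmonisation and normative modelling of bounded, non-Gaussian
continuous features via hierarchical GAMLSS.

## The problem

Pooling continuous measurements across studies — for instance structural
neuroimaging features (volumes in mm³, cortical thickness in mm, surface
area in mm²) from cohorts with different recruitment, protocols and
scanners — mixes biological signal with systematic between-cohort *batch
effects*. These effects are not confined to the mean: cohorts can differ in
spread, skewness and tail weight, and many features (white-matter
hypointensity volume is the canonical stress case) are zero-bounded and
strongly right-skewed, so Gaussian location–scale corrections such as
classical ComBat can distort trajectories and produce physically invalid
negative values.

`gamharm` is for analysts who need to (i) remove cohort effects from pooled
feature tables on the native measurement scale, (ii) obtain normative
deviation z-scores from the same model, and (iii) quantify how well that
worked.

## The model

Each feature *y<sub>ij</sub>* (individual *i*, cohort *j*) is modelled with a
distributional regression (GAMLSS) in which every parameter of a flexible
parametric family has its own linear predictor. The primary family is the
four-parameter sinh-arcsinh (SHASH) with location μ, scale σ, skewness ν and
tail weight τ:

```
        y_ij ~ SHASH(mu_ij, sigma_ij, nu_ij, tau_ij)
      mu_ij  = beta_0 + b_j^mu    + pb(age_i) + beta_1 sex_i
  log sigma_ij = gamma_0 + b_j^sigma + pb(age_i) + gamma_1 sex_i
      nu_ij  = delta_0 + b_j^nu
  log tau_ij = eps_0   + b_j^tau
```

where `pb(.)` is a penalised B-spline (P-spline) smooth of age and the
`b_j` are cohort random intercepts estimated under a zero-mean normal
assumption. If the full SHASH specification fails to converge, simpler
parameterisations are attempted in a fixed sequence (shape random
intercepts dropped one at a time, then both), then a three-parameter
generalised gamma, then the normal as final fallback.

Harmonisation proceeds in three steps, exact for any family with a
closed-form quantile function:

1. **centile**: `c_ij = F(y_ij | mu_ij, sigma_ij, nu_ij, tau_ij)` under the
   observation's own cohort's fitted distribution;
2. **cohort-effect removal**: every `b_j` is subtracted on its link scale,
   `theta~ = g^-1(g(theta_ij) - b_j)`;
3. **quantile mapping**: `y~_ij = Q(c_ij | mu~, sigma~, nu~, tau~)` returns
   the value to the native scale, preserving within-cohort rank order.

The probit transform `z_ij = Phi^-1(c_ij)` of the same centile is the
normative deviation score; under a correctly specified model on reference
data it is standard normal. A post-processing QC pass sets to missing any
centile outside the open interval (0, 1), any negative or non-finite
harmonised value (for zero-bounded features), and any non-finite z-score.

The validation suite quantifies batch removal (cohort R² increment over a
degree-3 age polynomial + sex baseline; mean pairwise two-sample KS
statistic on residuals), biological preservation (Spearman ρ with age;
Cohen's d for sex with Welch tests and BH-FDR), distributional-moment
contrasts, and data retention.

## Worked example

```r
library(gamharm)

# simulate a 4-cohort lifespan benchmark (2 features, 500 per cohort)
sim <- sim_benchmark(seed = 11, n_per_cohort = 500, n_features = 2)

# fit the hierarchy and harmonise both features
res <- harmonise_table(sim$table, c("f01", "f02"), seed = 11)
res$fits$f01
#> <gamharm_fit> feature 'f01', family SHASH, n = 2000
#>   converged: TRUE after 78 cycles; deviance 5554.673

head(res$output[, c("cohort", "age", "y_raw", "centile",
                    "y_harmonised", "z_score", "qc_flag")], 3)
#>   cohort    age y_raw centile y_harmonised z_score qc_flag
#> 1 cohort1 14.1   14.1   0.957         13.5   1.71  ok
#> 2 cohort1  8.01  11.8   0.133         11.3  -1.11  ok
#> 3 cohort1 19.2   11.7   0.242         11.2  -0.700 ok

# batch-effect removal, before vs after
post <- sim$table
for (f in c("f01", "f02"))
  post[[f]] <- res$output$y_harmonised[res$output$feature == f]
round(c(pre  = cohort_r2_increment(sim$table, "f01"),
        post = cohort_r2_increment(post, "f01")), 5)
#>     pre    post
#> 0.05856 0.00001
round(c(pre  = as.numeric(mean_pairwise_ks(sim$table, "f01")),
        post = as.numeric(mean_pairwise_ks(post, "f01"))), 3)
#>   pre  post
#> 0.223 0.049
```

The first fit converged on the full SHASH specification (fallback path of
length one). Each observation's centile carries its covariate-adjusted rank
within its own cohort; the harmonised value transports that rank onto the
cohort-effect-free distribution, and the z-score is its normative
deviation. Before harmonisation ~5.9% of this feature's variance beyond
age and sex was attributable to cohort; afterwards the increment is at the
numerical noise floor, and the mean pairwise KS statistic on
age/sex-residualised values falls from 0.223 to 0.049.

A command-line interface with `simulate`, `fit`, `harmonise`, `validate`
and `run-all` subcommands is installed at `inst/cli/gamharm` (also exposed
as `gamharm::cli_main()`).

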