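---
title: "Hierarchical GAMLSS harmonisation: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical GAMLSS harmonisation: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamharm)
```

This vignette documents the statistical model behind `gamharm`, the
numerical algorithms used to fit it, and the design choices made where more
than one defensible option existed. It states no empirical claim that the
package's test suite or acceptance script does not itself compute.

## The model

For a feature $y_{ij}$ observed on individual $i$ in cohort $j$, the
working model is a distributional regression in which each parameter of a
parametric family carries its own linear predictor:

$$y_{ij} \sim \mathrm{SHASH}(\mu_{ij}, \sigma_{ij}, \nu_{ij}, \tau_{ij})$$

$$\mu_{ij} = \beta_0 + b_j^{(\mu)} + pb(\mathrm{age}_i) + \beta_1\,\mathrm{sex}_i$$
$$\log\sigma_{ij} = \gamma_0 + b_j^{(\sigma)} + pb(\mathrm{age}_i) + \gamma_1\,\mathrm{sex}_i$$
$$\nu_{ij} = \delta_0 + b_j^{(\nu)}, \qquad
  \log\tau_{ij} = \epsilon_0 + b_j^{(\tau)}$$

The location and scale submodels are identical across all families in the
fallback hierarchy; the shape submodels contain at most an intercept and a
cohort random intercept. The identity link applies to $\mu$ and $\nu$, the
log link to $\sigma$ and $\tau$. All random intercepts $b_j$ are estimated
under a zero-mean normal assumption, which induces shrinkage of small
cohorts' offsets toward zero — the analogue of the empirical-Bayes
regularisation in ComBat-style methods. An optional subject-level random
intercept in $\mu$ (off by default) supports longitudinal tables; the main
pipeline is effectively cross-sectional.

### The SHASH parameterisation

Several sinh-arcsinh variants circulate; the literature the model builds on
does not pin one down. `gamharm` adopts the direct form

$$Y = \mu + \sigma\,\sinh\!\left(\frac{\operatorname{asinh}(Z) + \nu}{\tau}\right),
  \quad Z \sim N(0,1),$$

whose CDF and quantile are closed-form:
$F(y) = \Phi\!\big(\sinh(\tau \operatorname{asinh}(x) - \nu)\big)$ with
$x = (y-\mu)/\sigma$, and
$Q(c) = \mu + \sigma \sinh\big((\operatorname{asinh}(\Phi^{-1}(c)) + \nu)/\tau\big)$.
This form was chosen because (i) exact inverse mapping is what makes
quantile mapping lossless, and (ii) at $\nu = 0, \tau = 1$ it reduces
*exactly* to $N(\mu, \sigma)$ (the parameterisation constant is 1), which
gives the fitter a neutral Normal starting point and the test suite a sharp
identity to verify. Under this convention, increasing $\nu$ shifts mass to
the right (the median is $\mu + \sigma\sinh(\nu/\tau)$) and $\tau < 1$
thickens the tails. Other conventions (e.g. those with $\nu$ entering as
$\tau\epsilon$) differ in the *meaning* of the shape parameters, so fitted
shape values are not directly comparable across software.

### The generalised gamma

The three-parameter fallback uses a Stacy-type form with $\mu > 0$
(location on the natural scale), $\sigma > 0$, $\nu \neq 0$: with
$\theta = 1/(\sigma^2\nu^2)$ and $z = (y/\mu)^\nu$,
$f(y) = |\nu|\,\theta^\theta z^\theta e^{-\theta z} / (\Gamma(\theta)\,y)$.
Its CDF is the regularised incomplete gamma function (`pgamma`), with a
closed-form quantile via `qgamma`; $\nu = 1$ recovers an ordinary gamma
with coefficient of variation $\approx \sigma$. The identity link is kept
on $\mu$, with positivity enforced by step-halving rejection during
fitting, so that $\mu$ stays interpretable as a natural-scale location.

## Fitting: penalised backfitting

The fitter is an RS-type backfitting algorithm. The outer loop cycles over
the distributional parameters; for each, one iteratively reweighted
penalised least-squares update of all coefficients in that parameter's
linear predictor:

* per-observation first and second derivatives of the log-likelihood with
  respect to the linear predictor are obtained by central finite
  differences (step $10^{-4}(1 + |\eta|)$) — exact for no family and
  adequate for all three, which keeps the updater family-agnostic;
* negative second derivatives are floored and capped relative to their
  median to keep the working weights positive and bounded;
* the working response $z = \eta + u/w$ is fitted by a penalised weighted
  least-squares solve (Cholesky, with escalating jitter on failure, which
  is recorded as a non-positive-definite Hessian);
* each proposal is accepted only if the penalised deviance (at the current
  smoothing parameters) does not increase; otherwise the step is halved up
  to 12 times.

**Age smooth.** P-splines with 20 equally spaced interior knots, cubic
basis and a second-order difference penalty — conventional Eilers–Marx
defaults. The knot grid is extended beyond the age range rather than
clamped, so the penalty null space is exactly the affine functions of age
(driving the smoothing parameter to infinity demonstrably degenerates the
smooth to a line, which the tests exercise). The constant direction of the
basis is removed by an orthogonal reparameterisation so the smooth is
identifiable next to the global intercept. At prediction time, ages outside
the fitted range use linear extrapolation of the boundary basis and are
flagged.

**Random intercepts** are ridge-penalised indicator coefficients. The
ridge weight (equivalently the random-effect variance) and the spline
smoothing parameter are updated by local maximum-likelihood EM steps within
the backfitting cycle, with per-cycle change damped to a factor of 10.
Updates stop after cycle 25 (`fit_control(lambda_update_until = )`): once
the penalties are frozen, step-halving guarantees a monotone penalised
deviance, which is the form of the monotonicity property the tests assert.
A blanket monotonicity claim across cycles where the penalties themselves
move would not hold for any local-ML scheme.

**Convergence** is declared when the absolute change in global deviance is
below $10^{-3}$ on two consecutive outer cycles within the iteration cap
(200 by default), with all coefficients finite and every inner Hessian
positive definite. Anything else returns `converged = FALSE`, which the
fallback logic consumes; a non-convergent fit is never an exception.

**Starting values** are the Normal limit: $\mu$ from a lightly ridged
least-squares fit of the location design, $\log\sigma$ from the log
residual SD, $\nu = 0$, $\log\tau = 0$ (for the GG, $\nu = 1$ and
$\sigma$ from the coefficient of variation).

**Fallback hierarchy.** Six specifications in fixed order: SHASH with
shape random intercepts on both $\nu$ and $\tau$; on $\nu$ only; on $\tau$
only; on neither; generalised gamma; normal. Whether $\nu$-only should
precede $\tau$-only is genuinely open; this package fixes the documented
order and records every attempt in the returned `fallback_path`, so the
choice is at least auditable. A GG attempt on a response with non-positive
values fails on support grounds and the hierarchy continues.

**Sex coding**: a 0/1 contrast with the lexicographically smaller label as
reference (simulated tables code sex 1/2, so "sex = 2" is the non-reference
level). The contrast choice is recorded in the fitted model's metadata.

## Harmonisation and QC

The three-step map (centile under the own-cohort fit, link-scale
subtraction of every fitted cohort random intercept, quantile mapping under
the harmonised parameters) is exact whenever the family's quantile function
is. Two numerical policies matter:

* CDF values are **never clipped on the harmonisation path**. Clipping to
  $[\varepsilon, 1-\varepsilon]$ is applied only inside likelihood
  computations if needed; the harmonisation path must see raw values so
  that the open-interval QC rule can fire on genuinely saturated centiles.
* The QC rules are applied in their stated order — centile outside the
  open interval $(0,1)$ (exact floating-point comparison, no epsilon
  widening), then negative/non-finite harmonised values (the negative rule
  only for features declared zero-bounded, the default), then non-finite
  z-scores — and a record failing an earlier rule is not evaluated by
  later ones, which makes per-flag counts unambiguous and lets the
  retention report reconcile exactly against them.

## Validation metrics

* **Cohort R² increment**: nested OLS, baseline age + sex vs + cohort
  indicators. Age enters as centered raw powers up to the cube — centering
  controls conditioning without changing the fit.
* **Mean pairwise KS**: age/sex effects are regressed out with one pooled
  degree-3 polynomial + sex model across cohorts (so the residuals retain
  cohort differences but not biology); per-cohort residualisation is
  available as an option since both readings of "regressed out" are
  defensible. The two-sample statistic is computed exactly from the two
  ECDFs evaluated at every observed value — the sorted-pooled-sample
  shortcut used by some implementations mis-handles ties.
* **Moment contrasts**: absolute log SD ratio (scale-invariant), absolute
  differences of moment-based skewness and excess kurtosis.
* **Spearman ρ with age** (average ranks for ties) and **Cohen's d** for
  sex with the pooled SD, reference-minus-other sign, two-sided Welch
  tests, and Benjamini–Hochberg correction across features.

## The synthetic benchmark

Real multi-cohort feature tables cannot be redistributed, so the package
ships a seeded generator with known ground truth. The default benchmark —
the study condition for the package's end-to-end checks and for
`scripts/acceptance.R` — is four cohorts of 2000 observations with
overlapping but distinct age ranges (8–30, 18–60, 38–80, 52–95 years;
overlap is what makes cohort and age effects jointly identifiable),
balanced sexes, and 20 SHASH features with cycled nonlinear age
trajectories (inverted-U, linear decline, exponential), sex effects of
0.43–1.0 conditional-SD units on location, and zero-sum cohort offsets
drawn per feature and rescaled to exact spreads: SD 0.5 on $\mu$ (in units
of the conditional SD $e^{\gamma_0}$ — the natural reading of
"feature-SD units" when $\gamma_0 = 0$), SD 0.2 on $\log\sigma$, and SD
0.2 on $\nu$ for every second feature. Offsets are centered to sum to zero
across cohorts, matching the zero-mean random-effect convention. The
offset-free twin (`null_offsets = TRUE`) redraws nothing: it zeroes the
offsets while consuming the random streams identically, so pre/post
comparisons against generating truth are paired and free of simulation
noise.

A separate generator (`make_wmh_like()`) produces a zero-bounded,
strongly right-skewed, leptokurtic feature with an exponential mean age
trajectory — the exponential of a linear age trend plus SHASH noise on the
log scale — emulating white-matter-hypointensity-like stress cases without
ad-hoc truncation.

What the generator does *not* emulate: scanner- or site-level structure
within cohorts, within-subject longitudinal correlation (beyond the
optional subject intercept), missing-data mechanisms, and cross-feature
covariance. Passing tests therefore demonstrate correctness of the
machinery under the model's own assumptions, not robustness to every
real-data pathology.

### Problem sizes

The packaged checks use the benchmark at its full size (4 × 2000 × 20,
about a minute of fitting), plus smaller single-feature simulations
(typically 2000–5000 rows) for parameter recovery, calibration and
offset-removal checks — sizes at which Monte-Carlo error is comfortably
inside the asserted tolerances.

## Known limitations

* Per-feature fitting only; multivariate covariance across features is not
  modelled, so joint relationships may change even when every marginal is
  harmonised.
* No transfer step: cohorts unseen at fit time cannot be harmonised
  against a frozen model.
* The distribution-selection hierarchy is heuristic (convergence-based),
  not an information-criterion model selection.
* Numeric-derivative weights trade a little speed and asymptotic SE
  precision for family-agnostic robustness; the reported fixed-effect SEs
  come from the final penalised information and are approximate.
* Families beyond SHASH / generalised gamma / normal (discrete,
  zero-inflated, Box–Cox) are out of scope.
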