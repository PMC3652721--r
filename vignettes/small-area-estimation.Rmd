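---
title: "Model-based small-area estimation of childhood obesity prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based small-area estimation of childhood obesity prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National health surveys can estimate childhood obesity prevalence
reliably for the nation and for states, but not for the small areas —
census block groups, most counties — where prevention programs are
actually planned. Direct survey estimates for such areas rest on a
handful of respondents (or none) and are too noisy to use.
Model-based small-area estimation (SAE) borrows strength across areas:
an individual-level risk model with area covariates and area random
effects is fitted to the survey, and prevalence for any small area is
then *predicted* by combining the fitted risk surface with census
counts of that area's demographic make-up (post-stratification).

`saeprev` implements this workflow end to end for a binary obesity
outcome among children aged 10–17, together with a synthetic-data
generator that emulates the structure of a state-stratified national
children's health survey, so every stage can be exercised and tested
without restricted survey microdata or commercial census products.

## The model

For child $i$ in zip code $z$, county $c$, state $s$, obesity status
$y_i \in \{0,1\}$ follows a multilevel logistic model

$$
\operatorname{logit}\Pr(y_i = 1) =
\mathbf{x}_i^\top \boldsymbol\beta + u_{s} + v_{c}, \qquad
u_s \sim N(0, \sigma^2_{\text{state}}), \quad
v_c \sim N(0, \sigma^2_{\text{county}}),
$$

where $\mathbf{x}_i$ dummy-codes age group (10–14 vs 15–17), sex,
race/ethnicity (8 categories), the zip code's median-household-income
octile, its lifestyle segmentation class (12 categories) and
urbanization class (11 categories), and the county's income octile and
6-level urban–rural class — 50 coefficients including the intercept,
with declared reference levels carrying coefficient 0. Four
random-intercept structures are of interest: state, county, zip code,
and nested state + county.

### Laplace-approximated maximum likelihood

The marginal likelihood integrates the random intercepts out; the
package maximizes its Laplace approximation

$$
\ell(\boldsymbol\beta, \sigma^2)
= \ell_{\text{pen}}(\boldsymbol\beta, \hat{\mathbf u}, \sigma^2)
- \tfrac12 \log\det\!\big(Z^\top W Z + D^{-1}\big)
- \tfrac12 \sum_t q_t \log \sigma^2_t ,
$$

where $\hat{\mathbf u}$ is the conditional mode of the random
intercepts, $W$ the logistic IRLS weights at the mode, $D$ the
random-effect covariance and $q_t$ the number of areas of term $t$.
`fit_laplace()` proceeds in two phases:

1. *Initialization.* For trial variances, a joint Newton iteration
   maximizes the penalized log-likelihood over
   $(\boldsymbol\beta, \mathbf u)$ simultaneously (with step-halving),
   and the variance is profiled on the log scale.
2. *Exact Laplace ML.* A quasi-Newton (L-BFGS-B) pass maximizes the
   Laplace objective over $(\boldsymbol\beta, \log\sigma^2)$ jointly,
   with the modes re-solved at every evaluation and an *analytic*
   gradient: the envelope theorem handles the penalized part, and the
   log-determinant term is differentiated through the IRLS weights
   ($\partial w_i/\partial\eta_i = w_i(1-2\mu_i)$) including the
   implicit shift of the modes. The gradient is verified against
   numerical differentiation in the test suite's development history
   and the fit against an independent adaptive Gauss–Hermite
   quadrature oracle in the shipped tests.

Phase 2 matters: the phase-1 fixed effects (the joint penalized mode,
as in PIRLS-style implementations) can differ from the true Laplace
maximum-likelihood estimates by more than 0.01 on the log-odds scale,
which is material when validating against quadrature at tight
tolerance.

Numerical choices: variances are optimized as $\log\sigma^2$ on
$[\log 10^{-8}, \log 25]$, which enforces positivity; an optimum at
the lower bound is reported as $\sigma^2 = 0$ with a boundary flag
(variance components of prevalence models are legitimately tiny and
non-significant). Convergence uses a relative objective change below
$10^{-8}$ and a gradient infinity-norm below $10^{-5}$, with a cap of
200 iterations per loop. IRLS weights are floored at $10^{-12}$;
`log(1+e^x)` uses the standard overflow-safe form. Design columns for
category levels never observed in the sample (or aliased with other
columns) are detected by QR rank and reported as `NA` coefficients;
downstream prediction skips the affected cells and logs them rather
than failing. Perfectly separated data raise a diagnostic error
suggesting penalization.

Fixed-effect standard errors come from inverting the joint observed
information at the optimum (the conventional GLMM choice, matching
`lme4` closely); variance-component standard errors from the
numerically differentiated profile information of $\log\sigma^2$,
delta-transformed, and `NA` at the boundary. Wald $z$ tests supply the
coefficient p-values in the exported summary table.

### Adequacy and selection

For each random structure the package fits a *null* model (intercept
and random effects only) and the *full* covariate model;
`variance_explained()` reports
$100\,(\sigma^2_{\text{null}} - \sigma^2_{\text{full}})/\sigma^2_{\text{null}}$
per random term, computed from unrounded variances. The adequacy rule
(`is_adequate()`) requires at least 40% explained — inclusive at the
threshold — for every random term; `select_model()` picks the
converged full model with the smallest AIC
($-2\hat\ell + 2\,\#\text{parameters}$, variance components counted),
breaking ties toward fewer parameters, then declaration order.

## Prediction: post-stratification with coefficient transfer

The predictive model is obtained by **refitting** the reduced term set
— intercept, sex, age group, race/ethnicity, neighborhood income
octile and lifestyle class, with a state random intercept — rather
than subsetting the full fit's coefficients; exclusions (county
covariates, urbanization) reflect their non-significance once the
retained terms are controlled for, and a refit is the coherent
"final model" for prediction. Neighborhood coefficients estimated at
the zip-code level are applied unchanged to block-group covariates
(*coefficient transfer*), the assumption under test in the validation
protocol. State random intercepts enter prediction at their
empirical-Bayes modes.

For block group $b$, each demographic cell (sex × age group × race,
32 cells) gets a predicted risk through the inverse logit of its
linear predictor; the block-group SAE is the census-count-weighted
average of its cell risks, and county, state, and national SAEs are
count-weighted averages of block-group SAEs.

### Monte-Carlo intervals

Coefficient uncertainty is propagated by simulation: each fixed effect
is drawn independently from $N(\hat\beta_j, \widehat{se}_j)$, 1000
draws by default, and the full post-stratified prevalence is recomputed
per draw. The 95% interval is the 2.5th/97.5th percentile of the draws
(percentiles respect the $[0,1]$ scale, unlike a normal
approximation), and the coefficient of variation is the MC standard
deviation over the point estimate. Three deliberate choices, each
switchable in principle but fixed as defaults:

* draws are independent across coefficients (no covariance matrix) —
  this understates joint uncertainty slightly and is the conventional
  reading of simulating "coefficients and their standard errors";
* the intercept is drawn along with the slopes;
* state random intercepts are held at their modes across draws, so
  random-effect uncertainty is *excluded* from the intervals.

Aggregated intervals are re-derived draw-wise: each draw's block-group
prevalences are averaged with census weights and percentiles taken over
the aggregated draws — never by averaging interval endpoints. All
draws are generated up front under the seed, so results are identical
regardless of the internal chunk size, and byte-stable across runs.

Summary tables report N, min, quartiles, median, max, mean and IQR of
interval widths (percentage points) and CVs per geography level, with
conventional (type-7) quartiles: the hand-checkable convention in which
widths $\{1,\dots,5\}$ give median 3 and IQR 2.

## Validation protocol

Direct survey estimates are design-weighted proportions
$\sum w_i y_i / \sum w_i$ with linearized standard errors
$\sqrt{\sum w_i^2 (y_i-\hat p)^2} / \sum w_i$, which reduce to
$\sqrt{\hat p(1-\hat p)/n}$ under equal weights. Weights are treated
as fixed; no finite-population correction or stratum/PSU structure is
modeled (the survey's variance design is not reproduced here — a
documented limitation). Direct estimates are *reliable* when based on
at least 30 children with relative standard error strictly below 0.3;
zero estimates are excluded (relative SE undefined).

Model-based county SAEs are compared with reliable direct estimates by
paired t-test, quartiles of the per-county differences (percentage
points), and a count of counties whose model MC interval and direct
normal interval ($\pm 1.96\,SE$) fail to overlap. A
correlation-versus-minimum-sample-size curve computes the Pearson
correlation over counties with at least $m$ sampled children for
$m \in \{15, 30, 50, 100, 150, 200\}$ by default; entries with fewer
than 3 counties are undefined.

**A warning about the reliability screen.** The relative-SE rule is
outcome-dependent: for borderline county sizes, a *low* observed
prevalence inflates the relative SE and gets the county dropped, so the
retained direct estimates are selected upward. In simulations with a
correctly specified model, reliable counties averaging 30–80 children
showed a systematic model-minus-direct difference near −1.7 percentage
points that disappears entirely when only the sample-size rule is
applied. The calibration checks in the test suite therefore run at the
survey's state sample size (865 children per state over 4 counties),
where reliable counties are large enough that the screen essentially
never binds on the prevalence draw; users comparing against screened
direct estimates at smaller scales should expect this selection
artifact.

## The synthetic-data generator

`generate_geography()` builds a nested state ⊃ county ⊃ {zip code,
block group} frame; zip codes and block groups are parallel sub-county
units. Area covariates (income octile, lifestyle class, urbanization
class; county income octile and urban–rural class) are drawn uniformly
over their category sets, independently across areas. Counties carry a
log-normal size weight governing both survey allocation and block-group
child counts, so county sample sizes vary realistically; states carry
a nominal child population (log-normal around 100{,}000) from which
inverse-sampling-fraction survey weights follow. `true_model()`
couples a coefficient table — by default the published full-model
estimates, with state variance 0.0530 — with realized mean-zero normal
state and county intercepts. `simulate_survey()` draws a fixed number
of children per state (865 by default, the emulated survey's mean
state sample), assigns counties proportionally to size, zip codes
uniformly within county, demographics from configurable marginals
(uniform by default; the survey's joint demographic margins are not
public), and outcomes as Bernoulli draws from the true risks.
`generate_population_cells()` produces Poisson cell counts per block
group × sex × age × race. Within-state sampling is simple random
sampling of children — an assumption, since the emulated survey's
within-state design is not published.

What the generator deliberately does **not** emulate: spatial
adjacency (the model uses only membership); systematic differences in
covariate *composition* between states or counties (covariates are
iid across areas); the survey's telephone-frame weighting; and any
real prevalence geography. Two consequences matter for interpreting
test results. First, with iid covariates the state-level null variance
is almost entirely the true random-intercept variance, so the
percentage of state-level variance explained by covariates in
synthetic runs is near zero — unlike surveys of real states, which
differ systematically in income and lifestyle composition. Second,
passing calibration tests demonstrates the estimator and protocol are
implemented correctly, not that the model is correctly specified for
any real population. Block-group covariates are drawn independently of
their county's zip codes by default (an optional knob copies them from
a random same-county zip), because the zip-to-block-group coefficient
transfer is precisely the assumption the pipeline exercises, not one
the generator should bake in.

## Problem sizes used in the shipped checks

The test suite and acceptance script run scaled-down versions of the
emulated study, chosen as the package's standard desk-scale
conditions: 51 states with 4 counties each, 5 zip codes and 8 block
groups per county (1,632 block groups); 400 or 865 children per state
depending on the check; 20 replicates for recovery and calibration
simulations; 1,000 MC draws for intervals (100,000 where a quantile is
compared to its closed form). The engine-vs-quadrature comparison uses
instances of at most 8 areas and 40 observations, screened to the
variance regime of area-level prevalence models (method-of-moments
logit spread below 0.35) and to identifiable fixed effects — outside
that regime the Laplace approximation itself, not its implementation,
departs from exact quadrature.

## Pipeline and provenance

`run_simulate()`, `run_fit()`, `run_predict()` and `run_evaluate()`
bind the stages into a reproducible run driven by a validated YAML
configuration (`load_run_config()`; unknown keys are rejected, every
field checked against its operation's preconditions). All outputs are
plain UTF-8 CSV (full precision, "." decimal) or JSON; each stage
writes a `provenance.json` sidecar carrying the configuration's MD5
hash, the seed, the package version and per-file checksums — the
sidecar, rather than in-file annotation, keeps the CSVs plainly
readable. A fixed seed reproduces every output byte-identically.
`inst/cli/saeprev.R` wraps the stages for shell use
(`simulate`, `fit`, `predict`, `evaluate`, `run-all`), single-threaded
by contract.

## Known limitations

* Intervals exclude random-effect and model-selection uncertainty and
  draw coefficients independently; they are honest about coefficient
  noise, not full posterior uncertainty.
* The design-based SEs ignore the survey's complex design.
* States absent from the training survey predict at the population
  average (state effect 0).
* The reliability screen's selection effect (above) biases screened
  direct-estimate comparisons at small county sizes.
* Nested structures support exactly state + county-within-state;
  crossed random effects, random slopes, and survey-weighted
  pseudo-likelihood fitting are out of scope.
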