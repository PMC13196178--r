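---
title: "Simulation-based sample size calculations for clinical prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based sample size calculations for clinical prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a clinical prediction model (CPM) is developed on a small dataset, its
risk predictions degrade: calibration drifts, discrimination drops, net
benefit is lost, and individual predictions become unstable. Classical
sample-size formulas for CPM development target a single criterion (usually
expected shrinkage) under unpenalised logistic regression. `predsize`
implements a more general, simulation-based calculation: given

1. a **case-mix** — the joint distribution of candidate predictors in the
   target population,
2. a **reference model** — a working "true" logistic model
   $\operatorname{logit}(p_i) = \alpha + \delta(\beta_1 x_{1i} + \dots +
   \beta_P x_{Pi})$ whose performance defines the benchmark, and
3. a **model-development strategy** — any supervised method mapping a
   development dataset to a risk prediction function,

it anticipates, for a candidate development sample size $n$, the posterior
distribution of every performance and degradation metric of interest, and
the *assurance probability* that one realised dataset of that size will
deliver a model meeting chosen criteria.

**Model degradation** is (performance of the developed model) minus
(performance of the true model), both evaluated in the same large target
population. The true model's calibration slope is 1 and its MAPE is 0 by
construction, so degradation in those metrics is simply `slope - 1` and
`mape`.

## The simulation loop

`run_simulation()` proceeds in phases:

- **Set-up.** Generate the target-population design matrix once (default
  100,000 rows — large enough that evaluation error is negligible for all
  reported metrics while keeping one replicate around 0.2 s on a single
  core). Resolve the reference model: either supplied explicitly, or
  calibrated from relative weights to a target c-statistic and prevalence
  (below). Compute the population's true risks $p_i$ and simulate outcomes
  $y_i \sim \text{Bernoulli}(p_i)$ once.
- **Replicates.** For each of `n_sims` replicates (default 1000): draw a
  development dataset of size $n$ (fresh predictor rows from the generator,
  outcomes from the reference model), fit the strategy, predict every
  individual in the target population, and compute the metrics: c-statistic,
  calibration slope and calibration-in-the-large, MAPE and RMSPE, Cox–Snell
  and Nagelkerke $R^2$, net benefit at each threshold, the relative value of
  sample information $\text{RVSI} = 100 \times NB_{model}/NB_{max}$, the
  winner-strategy net benefit, and the degradations.
- **Summaries.** Per-metric mean, 2.5/97.5 percentiles, Monte Carlo
  standard error, and the assurance probability for each configured target
  (e.g. $P(0.9 \le \text{slope} \le 1.1)$, $P(\text{RVSI} \ge 90)$).

A failed strategy fit (for instance a one-class outcome at very small $n$)
flags the replicate and the run continues; more than 20% failures aborts the
run. Flagged replicates are *included* in summaries — resampling them would
bias the instability results toward stability.

### Reproducibility

One master seed fans out into named substreams (population draw,
per-replicate development draw, strategy internals, outcome simulation), so
identical configurations give bit-identical replicate tables, and swapping
the strategy does not perturb the data draws.

### Prediction instability

Per-individual summaries (95% interval width of the risk draws, an
effective sample size $\bar p(1-\bar p)/\operatorname{var}$, and the
misclassification probability against a threshold) are tracked on a fixed
random subsample of the target population (default 1000 individuals).
Storing the full 100,000 × 1000 prediction matrix would cost ~800 MB for no
extra statistical information about the population-level summaries; the
subsample keeps memory flat while the per-individual quantities remain
exact for those individuals. The effective-sample-size formula treats the
draws as if they were a binomial sample of that size; it is capped (and
flagged) when the draw variance is numerically zero.

## The case-mix generator

The built-in generator emulates standardised predictors with a logistic
outcome model. Defaults follow the working assumptions of the applied
analyses the package is designed around:

- continuous predictors are standard normal (mean 0, sd 1),
- binary and categorical predictors are thresholded latent normals,
- predictors are conditionally independent unless a latent-scale
  correlation matrix is supplied, in which case a Gaussian copula (latent
  multivariate normal transformed to the marginals) induces dependence.
  Categorical variables with more than two levels are cut from the same
  latent normal at the quantiles of their level probabilities — a choice of
  ours, since only marginals are typically available.

What the generator does **not** emulate: skewed or heavy-tailed marginals,
nonlinear predictor–outcome relationships, measurement error, and missing
data (out of scope throughout). Passing tests under the generator therefore
demonstrates the machinery and the qualitative orderings (degradation
growing as $n$ falls, penalisation trading calibration spread for bias,
deep trees degrading more than shallow ones); exact agreement with results
computed on a *real* case-mix is expected only up to this approximation.
In our checks against published pre-eclampsia results (reference model with
10 parameters, c-statistic 0.76, prevalence 0.68), population-level means
agree to about 0.01–0.02 (e.g. mean calibration slope 0.88 here vs 0.89
there at $n = 456$) while band probabilities such as
$P(0.9 \le \text{slope} \le 1.1)$ can differ by a few hundredths more,
being sensitive to the exact spread of the slope distribution.

Real datasets can be supplied as CSV via `load_casemix()` (missing cells
are an error, never imputed); a finite case-mix pool is split into a
population and a disjoint development pool, sampled without replacement.

## Calibrating the reference model

With only relative predictor weights available, `calibrate_reference()`
finds $(\alpha, \delta)$ so that the model attains a target prevalence and
c-statistic on the population: an outer bisection on $\delta$ with, at each
step, an inner root-find on $\alpha$ for the prevalence. The c-statistic of
a candidate $(\alpha, \delta)$ is computed from the risks alone by the
exact expected-concordance formula

$$C = \frac{\sum_{i \ne j} p_i (1-p_j)\,[\mathbb{1}(p_i > p_j) +
\tfrac12 \mathbb{1}(p_i = p_j)]}{\sum_{i \ne j} p_i (1-p_j)},$$

evaluated in $O(n \log n)$ by sorting. Using the expectation instead of
outcomes drawn once makes the objective deterministic and strictly
monotone in $\delta$, so the bisection cannot be derailed by Monte Carlo
noise. Tolerance is 0.002 on both targets with at most 50 outer
iterations; unattainable targets (e.g. C = 0.99 from a single binary
predictor) are reported with the best achieved values.

Uncertainty in the reference model is expressed as a `reference_mixture()`:
each replicate draws one model, which defines both the population truth
(risks and outcomes regenerated for that replicate) and the development
generator, so "degradation against the true model" remains exact per
replicate. A one-component mixture is collapsed to its single model, making
the two configurations bit-identical under matched seeds.

## Strategies

All regression strategies standardise predictors on the development sample
and store the scaling; coefficients are folded back to the original scale
so prediction is one linear-predictor evaluation.

- `fit_logistic_mle()` — unpenalised ML logistic regression. Separated or
  non-converged fits are *kept* and flagged: dropping them would understate
  instability at small $n$.
- `fit_logistic_uniform_shrinkage()` — multiplies the ML slopes by the
  heuristic factor $S = (\chi^2_{LR} - P)/\chi^2_{LR}$ and re-estimates the
  intercept with the shrunken linear predictor as an offset. At small $n$,
  $S$ can be negative; the sign-flipped model is retained and flagged
  (which is exactly what produces the heavy-tailed slope distributions seen
  at $n = 75$).
- `fit_penalized_cv()` — ridge/lasso via `glmnet`, penalty chosen by
  10-fold cross-validated binomial deviance over a 100-value log-spaced
  grid (`lambda.min.ratio = 1e-6` so the grid spans fully-shrunk to
  near-unpenalised); folds stratified by outcome.
- `fit_bayes_penalized()` — exact Bernoulli likelihood with shrinkage
  priors (below), sampled by adaptive random-walk Metropolis–Hastings
  (compiled); burn-in 5000, thinning 10, 1000 retained draws by default.
  The fitted CPM's point predictions use posterior-mean coefficients
  (configurable to posterior-mean risks; the two differ only slightly for
  these models, and coefficient means keep the fitted model a single
  logistic equation).
- `fit_random_forest()` (probability forest, 100 trees, depth 3 or 15) and
  `fit_gradient_boosting()` (logistic loss, 100 trees, depth 15, learning
  rate 0.1 — recorded in the fit metadata since boosting defaults vary
  across implementations).
- `oracle_strategy()` — returns the reference model itself; every
  degradation must vanish, which the test suite uses to validate the
  engine end to end.

## Shrinkage priors and the unit-information approximation

The full simulation is expensive for Bayesian penalised regression. The
fast path decomposes the (flat-prior) posterior covariance of a logistic
MLE into sample size and Fisher's **unit information**

$$\mathbf I = \mathbb E\!\left[\frac{e^{\mathbf x' \boldsymbol\beta}}
{(1 + e^{\mathbf x' \boldsymbol\beta})^2}\, \mathbf x \mathbf x'\right],$$

averaged over the case-mix rows, so the anticipated posterior at any $n$ is
$\text{MVN}(\boldsymbol\beta_{ref},\, n^{-1}\mathbf I^{-1})$ — computed
once, then sampled directly (`sample_unpenalized_posterior()`). For
penalised regression, the exact likelihood is replaced by that MVN density
evaluated at the reference coefficients ("the data is the reference
coefficient vector") and combined with shrinkage priors
(`mh_shrinkage_posterior()`):

- intercept: $N(0, 10^6)$;
- ridge: $\beta_j \sim N(0, \lambda^2)$ with
  $\lambda^2 \sim \text{inverse-gamma}(0.01, 0.01)$ — shape–rate by
  default, switchable, since the two conventions genuinely differ here;
- lasso: $\beta_j \sim \text{Laplace}(0, \sqrt{\lambda^{-2}})$ (so larger
  $\lambda$ means stronger shrinkage) with
  $\lambda^2 \sim \text{gamma}(1, \text{scale } 1/1.78)$, i.e. rate 1.78.

The sampler is a joint Gaussian random walk on
$(\alpha, \boldsymbol\beta, \log \lambda^2)$, adapted toward 25%
acceptance in batches of 50 during burn-in only (adaptation frozen
afterwards, preserving detailed balance for the retained draws). Burn-in
defaults to 10,000 here (5000 in the full-simulation strategy — both appear
in the source analyses, so both are defaults in their own context).
A lag-1 autocorrelation above 0.3 after thinning triggers a warning, not an
error. With the penalty fixed at an enormous value the sampler must (and in
tests does) reproduce the direct MVN posterior.

The approximation leans on asymptotic ML theory: at $n = 456$ under the
worked setup it tracks the full simulation closely; at $n = 75$
discrepancies (especially in the calibration-slope distribution) are
expected and documented rather than asserted away.

## Closed-form starters

`starter_sizes()` implements the two classical criteria used as starting
points: precise overall-risk estimation,
$n = \lceil 1.96^2\, \phi(1-\phi) / (w/2)^2 \rceil$ (335 at prevalence
0.68, width 0.1), and the calibration-slope criterion
$n = \lceil P / ((S-1)\ln(1 - R^2_{CS}/S)) \rceil$ with the anticipated
c-statistic converted to a Cox–Snell $R^2$ by simulation: outcomes at the
anticipated prevalence, a binormal linear predictor with separation
$\sqrt 2\,\Phi^{-1}(C)$, risks via Bayes' rule, and $R^2_{CS}$ from the
model-vs-null Bernoulli log-likelihoods ($10^6$ draws; stable to about
0.001). At $C = 0.76$, prevalence 0.68, $P = 10$, $S = 0.9$ this chain
returns $n \approx 456$ (about 310 events). Reported expected events are
`round(n * prevalence)`; note that at $n = 335$ and prevalence 0.68 this is
228, not the 241 sometimes quoted alongside that criterion — we report the
computed value.

## Numerical choices and edge cases

- Risks are clipped to $[10^{-8}, 1-10^{-8}]$ before any logit (tree
  ensembles emit exact 0/1).
- A model with (numerically) constant predictions gets calibration slope 0
  with a flag — the convention that lets fully-shrunk lasso fits appear at
  the bottom of the slope distribution rather than as missing values.
- Calibration curves use a natural cubic spline (3 df) on the logit of the
  predicted risk.
- Net benefit in the population uses the simulated outcomes (the
  "evaluation dataset" form); an expectation form using true risks is
  available to cut Monte Carlo noise but is off by default.
- Winner selection among {model, treat all, treat none} uses the
  development-sample net benefit with ties broken in that order of
  precedence.
- The minimum-$n$ search (`sweep_sample_sizes()`) is grid-based with no
  interpolation: the metric–$n$ curves are noisy and candidate sizes are
  usually a small discrete set (e.g. 75, 335, 456, 1000).

## Known limitations

- Missing data, class-imbalance resampling, and neural-network strategies
  are out of scope.
- The Gaussian-copula generator cannot represent dependence structures
  beyond a latent correlation matrix.
- The unit-information approximation degrades at small effective sample
  sizes and in high dimensions relative to events.
- Exploratory predictors with unknown effects should enter the reference
  model with weight 0 (conservative), while still being offered to the
  strategy as candidates.

## Problem sizes used in the test suite

Unit and property tests run on populations of 2,000–20,000 with tens of
replicates — the sizes at which each property is already sharply testable.
The acceptance checks of the applied-example quantities use the full study
conditions (population 100,000; 1000 replicates for the frequentist
strategies, 200 for Bayesian ridge), chosen to keep the Monte Carlo
standard error of each reported mean well below its comparison tolerance.
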