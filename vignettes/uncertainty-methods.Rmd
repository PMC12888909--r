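---
title: "Quantifying individual-level uncertainty from missing risk factors"
author: "riskuq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual-level uncertainty from missing risk factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskuq)
```

## The problem

Multifactorial breast-cancer risk models combine family history,
questionnaire risk factors (QRFs), mammographic density (MD), a polygenic
score (PGS) and rare pathogenic variants (PVs) into one absolute-risk
estimate. In practice most women have only a fraction of these measured.
Risk calculators still return a point estimate — implicitly an average over
whatever was not measured — and that average can sit in the moderate band
(3–8% ten-year risk) while the risks the woman could actually turn out to
have, once her missing factors are measured, span all bands. `riskuq` makes
that conditional distribution explicit.

The quantity of interest is the distribution of
$r(x_{\mathrm{obs}}, X_{\mathrm{mis}})$ where $X_{\mathrm{mis}} \sim
P(x_{\mathrm{mis}} \mid x_{\mathrm{obs}})$: the risk the individual would be
assigned after measuring everything, viewed from today. Its mean is the
usual point estimate ("mean risk over unmeasured covariates"); its 2.5% and
97.5% quantiles form the 95% uncertainty interval (UI); the mass it puts on
each risk band is the probability of ending up in that band; and comparing
band membership before and after measurement gives the probability of
reclassification.

## The imputation engine

Missing covariates are drawn by multivariate imputation by chained
equations (MICE), fitted to a reference cohort and assuming data are
missing at random (MAR). One conditional model is fitted per covariate,
with all other covariates as predictors:

| kind | model | draw |
|---|---|---|
| continuous | linear regression on the transform scale | normal |
| continuous-positive | linear regression on `log(x)` | log-normal |
| zero-inflated (alcohol) | logistic zero part + linear model on `log` of positives | Bernoulli zero, else log-normal |
| binary | logistic regression | Bernoulli |
| categorical / ordinal (incl. 9-category PV) | multinomial logistic | single categorical draw |

Because PV status is a single 9-level draw (no PV, or one of eight genes),
each completed profile carries at most one pathogenic variant by
construction — the rare-disease assumption.

Each of the $M$ Monte Carlo samples is an independent short chain:
missing entries are initialised by draws from the observed marginals (not
mean-fill, which would collapse the first-iteration variance), then the
variables are revisited in schema declaration order for `n_iter` iterations.
A fixed visit order keeps runs reproducible; the joint draws are
order-insensitive once the chain has mixed.

*Proper* imputation: before every conditional draw the model parameters are
themselves drawn from their asymptotic sampling distribution —
$\beta^* \sim N(\hat\beta, \hat V)$, and for Gaussian parts
$\sigma^{2*} = \hat\sigma^2 \nu / \chi^2_\nu$ — so the Monte Carlo spread
reflects estimation uncertainty in the imputation models as well as genuine
covariate variability. A bootstrap alternative was considered and rejected
as more expensive for no accuracy gain at cohort sizes of interest. Two
draw modes exist internally: per-row (every sample has its own parameter
draw; used for the index-individual distributions) and per-dataset (one
draw shared across rows; used where a single completed dataset is wanted,
e.g. the observed-vs-imputed diagnostic, and inside the nested
marginalisation below, where it cuts memory traffic by two orders of
magnitude at negligible cost to a quantity that is itself an average).

Convergence is monitored with the Gelman–Rubin potential scale reduction
factor: the $M$ samples are partitioned into `n_chains` groups, the mean and
SD of each imputed variable are traced across iterations per group, and

$$\hat R = \sqrt{\frac{\frac{n-1}{n} W + \frac{B}{n}}{W}}$$

with $W$ the mean within-chain variance and $B$ $n$ times the variance of
chain means. Defaults `n_iter = 10`, `n_chains = 4` are ample for these
low-dimensional conditionals; $\hat R$ has floor $\sqrt{(n-1)/n}$, returns
`Inf` for internally constant but disagreeing chains and 1 when all chains
are identical constants. `compare_observed_imputed()` contrasts observed
and imputed distributions (KS statistic for continuous variables,
total-variation distance for discrete ones); under MCAR the two should
agree, under MAR they legitimately differ.

Separation is a real concern with rare PV categories at desk-scale cohort
sizes: multinomial fits always carry a small ridge (`nnet` weight decay),
binary logistic fits fall back to ridge-penalised IRLS when unpenalised
IRLS diverges, and near-singular information matrices are floored at the
eigenvalue level before Cholesky factorisation of the parameter covariance.

## The absolute-risk model

The risk engine is deliberately simple: a log-additive relative-risk model
over a calibrated baseline hazard. Segregation-analysis models marginalise
family history through an explicit pedigree likelihood; here family history
is a 3-level covariate (0 / 1 / 2+ affected first-degree relatives) with
its own log relative risk. The uncertainty framework is agnostic to the
inner risk model, so this stand-in preserves everything the Monte Carlo
machinery exercises while remaining fully self-contained.

Hazards are per-year and piecewise constant on an integer age grid
(20–80 by default; registry incidence tables come this way), and the
within-year competing-risk split is exact:

$$\text{risk} = \sum_{t=a}^{a+h-1} S(t)\,
  \frac{\lambda_t}{\lambda_t+\mu_t}\bigl(1 - e^{-(\lambda_t+\mu_t)}\bigr),
  \qquad S(t) = e^{-\sum_{s<t}(\lambda_s+\mu_s)}.$$

This reproduces the constant-hazard closed forms exactly (a property the
test suite asserts), is monotone in the horizon, and returns values in
$[0,1)$. A zero horizon returns 0; ages off the grid are an error.

Calibration: in a multiplicative model the population-average hazard is the
baseline times the cohort-mean relative risk, so `calibrate_baseline()`
divides the baseline by that mean. Risk effects carry no age interaction,
so the constant is identical at every age; it is nevertheless stored as a
per-age vector so age-varying calibration remains a drop-in extension.

Category boundaries: the NICE bands are quoted as <3%, 3–8%, >8%, so both
cut-points belong to the moderate band; `classify()` fixes this convention
and the tests pin it.

## Uncertainty summaries

* Point estimate: the arithmetic mean of the $M$ risks, matching the "mean
  over unmeasured covariates" convention of risk calculators that
  internally marginalise missing factors.
* UI: equal-tailed empirical quantile interval using the
  linear-interpolation (type-7) quantile convention, fixed and documented
  so results are bit-reproducible. A highest-density interval was
  considered and left as future work: the equal-tailed interval directly
  matches "the range in which the risk would lie with 95% probability" and
  is order-statistic based (permutation invariant, equivariant under
  monotone shifts). At `level = 0` both endpoints collapse to the median by
  convention.
* Category probabilities: exact empirical frequencies, summing to 1.
* `pgs_sweep()` pins the (missing) PGS at $\Phi^{-1}(p/100)$ for
  percentiles 10, …, 90 and recomputes the distribution over the remaining
  missing factors; under a positive per-SD PGS effect the point estimates
  are monotone and, with multiplicative effects, the UI widens as the
  percentile grows.

## Stepwise measurement and reclassification

`stepwise_measurement()` simulates measuring factor groups in a chosen
order (default QRF → MD → GF; GF bundles PGS and PV). Each of $M$
trajectories draws the stage-$k$ group from its conditional distribution
given the observed profile and all previously drawn groups — implemented by
imputing all currently-missing variables jointly and *keeping only* the
stage-$k$ group, which yields exactly the right conditional marginal — and
holds it fixed thereafter. Covariates not yet "measured" at a stage are
left missing when predicting that stage's risk; some marginalisation rule
is then needed, and the package uses a nested Monte Carlo mean over
`M_inner` (default 100) inner imputations of the still-missing covariates,
mirroring the point-estimate convention above. Analytic marginalisation
would be possible for factors whose relative-risk distribution has a
closed-form mean but is not attempted in general.

Bookkeeping identities are exact, not statistical: per-stage memberships
sum to 1, each transition matrix row sums to the previous stage's
membership and each column to the next stage's. The final stage conditions
on all groups regardless of order, so final memberships are
order-invariant up to Monte Carlo error, while intermediate stages may —
and should — differ between orders. The reclassification probability is
one minus the probability of remaining in the baseline point-estimate's
category after measuring through the chosen stage.

Classification of an inner Monte Carlo *mean* is a threshold decision on a
noisy quantity: with risks near a cut-point, `M_inner` controls how often a
trajectory is banded incorrectly (standard error of the inner mean scales
as $1/\sqrt{M_\mathrm{inner}}$). The toy systems used in the test suite
place all conditional mean risks several inner standard errors away from
the cut-points, so this discretisation noise is negligible there; for real
profiles near a threshold, raise `M_inner`.

## The synthetic cohort generator

`simulate_cohort()` draws latent standard-normal scores with a
user-supplied correlation matrix (Gaussian copula) and maps each margin to
its declared distribution: normal (age at menarche), log-normal (BMI, MD),
zero-inflated log-normal (alcohol, with a point mass at abstention),
Bernoulli (HRT and OC use), multinomial (parity; PV with the population
model's carrier frequencies), standard normal (PGS). Family history is not
a copula margin: it is drawn from a sequential logistic model on the PGS
and carrier status, so that measuring genetics changes the conditional
relationship between family history and risk — the qualitative behaviour
that makes stepwise genetic measurement informative.

What the generator emulates: the mixed-type, correlated covariate structure
that a chained-equations engine must handle, with realistic shapes
(skewness, zero inflation, rarity). What it does not emulate: real
cohort-calibrated effect sizes and correlations (all defaults are
illustrative), age structure of a recruitment cohort, measurement error, or
missingness that is informative beyond MAR. Passing tests therefore
demonstrate the correctness of the machinery under a correctly specified
generator — not the accuracy of any particular risk number for real
populations, which would require the full pedigree-based model and cohort
data.

Two generator defaults deserve a note. Carrier frequencies are placed at
the upper end of the rare range (0.15%–0.6% per gene, each well under the
1% "rare" ceiling) so that reference cohorts of a few thousand individuals
contain every PV category — a multinomial model cannot be fitted for a
level that never occurs, and the fitter refuses such cohorts explicitly;
several genes are rarer in reality. Missingness mechanisms are limited to
MCAR and MAR because the imputation framework itself assumes MAR; MNAR
sensitivity analysis is out of scope.

## Defaults and problem sizes

| parameter | default | rationale |
|---|---|---|
| `M` | 1000 | Monte Carlo samples per distribution; the study convention for individual uncertainty distributions |
| `M_inner` | 100 | inner marginalisation of unmeasured groups; see threshold note above |
| `n_iter` | 10 | chained-equation cycles; low-dimensional conditionals mix fast (R-hat checked) |
| `n_chains` | 4 | chain groups for diagnostics |
| UI level | 0.95 | reporting convention |
| thresholds | 0.03, 0.08 | NICE 10-year bands |
| age grid | 20–80 | index examples use age 40, horizon 10 |
| reference cohort | n = 5000 | large enough that every PV level is observed and fits are stable, small enough for interactive use |

The test and acceptance suites size their Monte Carlo runs at
M = 10,000 for enumeration-oracle comparisons (3-standard-error bands),
n = 5000 cohorts for the Gaussian-conditional recovery check, and 500
masked individuals at M = 500 for the UI coverage experiment; these sizes
give comfortable statistical margins for the properties being checked.

## Known limitations

* The risk engine is a documented simplification: no pedigree likelihood,
  no ovarian cancer, no age-varying or ethnicity-specific effects.
* Only missing-data uncertainty is quantified. Parameter uncertainty of
  the risk model itself and model-misspecification uncertainty are
  deliberately out of scope and would require different machinery.
* Imputation families are main-effects models on the declared transform
  scales; strongly interactive or non-monotone dependencies in a real
  cohort would need richer conditionals (no predictive-mean matching, no
  multilevel structure).
* The family-history covariate is a first-degree-relative count; detailed
  pedigree configurations (ages at diagnosis, second-degree relatives) are
  not represented.
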