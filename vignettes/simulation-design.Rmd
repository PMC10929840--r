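---
title: "Design of the simulation study: imputing a systematically missing gait-speed variable in a four-study IPD meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of the simulation study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdmi)
```

## The problem

Individual participant data meta-analysis (IPDMA) pools subject-level
data across studies. When a predictor is *systematically missing* —
never measured in one of the studies — every standard within-study
imputation model is unidentified there, and the analyst must borrow the
predictor's relationship to the other variables from the remaining
studies. With only a handful of large studies, the choice of borrowing
strategy matters.

`ipdmi` implements a Monte Carlo simulation framework for exactly this
setting, modelled on a four-cohort aging study in which the 3-level
gait-speed category (≤0.8, 0.8–1.2, >1.2 m/s) is entirely unmeasured in
one cohort of n = 1,402 out of 7,930 subjects. Three multiple-imputation
strategies are compared on their ability to recover the true adjusted
log odds ratios of gait speed on 5-year mortality:

* **FCS** — fully conditional specification: a multinomial logistic
  imputation model fitted on the appended complete-gait studies, with
  study indicator variables.
* **MVN** — joint multivariate-normal imputation of the gait dummy
  columns by data-augmentation MCMC.
* **CQI** — conditional quantile imputation: per-study association
  models, averaged across studies, inverted through the conditional
  cumulative distribution at a uniform draw.

A complete-case comparator (drop the masked study) is also available.

## Data-generating mechanism

Each replicate draws, per study, an `n × 7` matrix of latent normals
with a study-specific correlation matrix, and discretises each column by
inverse-CDF thresholding at the study's marginal category frequencies —
a Gaussian copula on the category scale. Mortality is then drawn from a
Bernoulli with log-odds given by a fixed 13-coefficient logistic model
(intercept −0.786; gait contrasts −0.599 and −1.237, i.e. odds ratios
0.55 and 0.29; plus indicator effects for MMSE, ADL, IADL,
comorbidities, sex and age). Only after the outcome is generated is gait
set to missing in the flagged study, so the masked study's outcomes
genuinely depend on its hidden gait values.

Two design choices deserve emphasis:

* **Standardised latent scale.** Discretisation by inverse CDF depends
  only on the standardised latent value, so means and variances of the
  latent normals are fixed at 0 and 1 and each study is parameterised by
  a 7×7 *correlation* matrix alone. This makes the generator independent
  of unavailable study-level covariance estimates while producing
  distributionally equivalent categorical output.
* **Synthetic correlation fixtures.** The empirical per-study
  covariance structure of the real cohorts is not public. The package
  ships clearly labelled synthetic stand-ins
  (`inst/extdata/latent_corr_*_synthetic.csv`): one base matrix with
  clinically signed correlations (|r| between 0.10 and 0.40 among gait,
  disability, cognition, comorbidity and age; near zero with sex),
  scaled by 1.0 / 0.9 / 1.1 across the three complete-gait studies to
  emulate between-study variation. The masked study's unobservable gait
  correlations default to the element-wise mean of the other studies'
  gait rows, mirroring how its gait *marginals* are set to the
  arithmetic mean of the observed ones. All four matrices are
  positive-definite (smallest eigenvalue ≥ 0.53) and user-overridable
  via the config file. Because these fixtures are not the real
  covariance structure, performance numbers from this generator
  reproduce the *qualitative* behaviour of the methods (and the
  near-unbiasedness of CQI) rather than the exact published table
  cells.

The sex indicator codes female = 1 (category 2), so the −0.725
coefficient encodes lower female mortality; the coding is configurable
but fixed here as the default.

What the generator does **not** emulate: continuous gait speed in m/s
(only the 3-level category is modelled), within-study sporadic
missingness, measurement error, and any real-data deviation from the
copula dependence structure. Passing tests therefore certify the
estimators' behaviour *under this mechanism*, not on the original
cohort data.

## The three imputation methods

All methods produce M completed datasets; M ≥ 2 is enforced because
Rubin's rules need a between-imputation variance.

**FCS.** With a single incomplete variable the FCS Gibbs cycle
collapses to one conditional model, so the implementation is a
single-pass fit: multinomial logistic regression of gait on all
covariates, the outcome, and study indicators, over the appended
complete-gait rows. Properness comes from redrawing the coefficient
vector from its asymptotic normal distribution N(θ̂, V̂) before each
imputation. The masked study has no estimable study effect; by default
it is predicted at the reference study level, with an option
(`fcs_study_effect = "average"`) to use the mean of the fitted study
effects. This inestimability is precisely the weakness that systematic
missingness creates for appended-data FCS, and plausibly drives its
small upward bias on the first gait contrast.

**MVN.** The replicate is encoded as a numeric working matrix (gait as
two dummy columns, all other categoricals dummy-coded, outcome and
study indicators included, mirroring the FCS predictor set). A
data-augmentation chain alternates drawing the missing gait dummies
from their conditional normal (I-step) and drawing the mean and
covariance from a normal–inverse-Wishart posterior (P-step). The prior
is proper but weak — identity scale matrix, p + 2 degrees of freedom,
mean precision κ₀ = 0.01 — chosen to avoid the improper-posterior edge
cases a Jeffreys prior can hit when a block of rows is entirely missing
in two columns. The chain default is 200 burn-in iterations and 25
iterations between retained states; with a 2-column missing block the
chain mixes quickly and these defaults are conservative. Continuous
dummy draws are mapped to categories by score argmax
(`(1 − d₂ − d₃, d₂, d₃)`, ties toward the lower category); a stochastic
rounding mode is available. The joint-normal model is of course
misspecified for dummies — that misspecification is part of what the
simulation measures.

**CQI.** Step I fits the gait association model (multinomial logistic
on all covariates plus the outcome, no study indicators) separately in
each complete study. Step II averages the coefficient vectors
element-wise with inverse-variance weights (variance of the average =
inverse summed precision; a simple-mean mode is available) and predicts
conditional category probabilities for the masked study's subjects.
Step III imputes each value by inverting the cumulative predicted
distribution at a uniform draw. As printed, step III redraws only the
uniform, which understates parameter uncertainty; the default here
redraws the averaged coefficients from N(θ̄, v̄) per imputation
(`draw_parameters = TRUE`), with a literal fixed-θ̄ mode for
sensitivity runs. The multinomial (nominal) model family matches the
FCS imputation model, so method differences are attributable to the
cross-study borrowing strategy rather than the model family.

## Analysis and performance measures

Each completed dataset is analysed by the *two-stage common-effect*
approach: the 13-parameter mortality model is fitted by maximum
likelihood in each study, each coefficient is combined across studies
by inverse-variance weighting, and the M meta-analytic estimates are
pooled across imputations by Rubin's rules
(T = W̄ + (1 + 1/M)·B, CI via Rubin's classical degrees of freedom;
normal quantiles when B = 0). Meta-analysis within imputation precedes
pooling across imputations; with fixed weights the reverse order gives
identical point estimates (asserted in the test suite), and variances
differ only slightly. Studies without imputed cells are identical
across the M copies and are fitted once.

Across R replicates the package reports, per method and per gait
contrast: average estimate, average model-based SE (the plain mean of
SEs, as defined for this design; a root-mean-square option exists),
bias, relative bias as 100·|bias|/|β| (the signed version is stored
alongside), empirical SE, and 95% CI coverage, each with Monte Carlo
standard errors (empirical SE/√R for the bias; 100·√(p(1−p)/R) for
coverage). Replicates in which any study fit fails to converge are
flagged, excluded, and counted through `R_effective`; with the default
cohort sizes such failures essentially never occur.

## Numerical choices and degenerate inputs

* Multinomial fits use a ridge (weight decay) of 1e-6 by default,
  guarding against separation in small simulated studies without
  materially biasing coefficients at these sample sizes.
* Non-positive-definite user correlation matrices are rejected with the
  offending study named; `nearest_pd_corr()` offers an explicit,
  warning-emitting projection for users who want a repair.
* Inverse-CDF discretisation uses half-open bins `(c_{k−1}, c_k]`, so
  boundary values fall in the lower bin and zero-probability categories
  simply vanish.
* Category coding is 1-based with level 1 the reference everywhere.
* One master seed drives everything: per-replicate child seeds are
  pre-derived from it, so any replicate can be re-run alone and results
  are identical under any number of parallel workers.

## Problem sizes in the shipped checks

The simulation defaults mirror the study design (R = 1,000 replicates,
M = 100 imputations). The packaged tests and the acceptance script use
a scaled run — R = 100, M = 20, full cohort sizes — which the package
treats as its standard desk-scale reproduction: Monte Carlo errors are
roughly 3× those of the full design, and the acceptance checks compare
against published values within multiples of the run's own Monte Carlo
SE. Unit and property tests use further scaled-down profiles (10–25% of
the cohort sizes) where the property under test does not depend on the
full n.

## Known limitations

* The correlation fixtures are synthetic; exact reproduction of the
  published performance table is not expected, and the MVN coverage
  figure in particular is sensitive to unstated implementation choices
  (category rounding, study-indicator handling) in the original
  analysis.
* Only one systematically missing categorical variable is supported;
  sporadic missingness, multiple incomplete variables and
  random-effects meta-analysis are out of scope.
* The per-study averaging in CQI uses diagonal (element-wise)
  inverse-variance weights, ignoring within-fit covariances between
  coefficients.
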