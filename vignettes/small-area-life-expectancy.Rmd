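---
title: "Small-area life expectancy and spatial Durbin error modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area life expectancy and spatial Durbin error modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractlife)
```

## What the package computes

`tractlife` implements a two-stage analysis of geographic health
disparities at the census-tract scale. The first stage estimates life
expectancy at birth ($e_0$) for each tract from an abridged mortality
schedule, with a sampling standard error that supports reliability
screening of small areas. The second stage relates the tract-level $e_0$
surface to social-determinant covariates through a spatial Durbin error
model (SDEM), a local-spillover spatial regression estimated by maximum
likelihood. A seeded synthetic-data generator reproduces the statistical
structure this analysis assumes — a tract lattice, spatially
autocorrelated covariates, an SDEM-generated outcome, and age-structured
Poisson mortality — so the whole pipeline can be exercised and validated
without any external data.

## Stage 1: abridged life tables

### Model

Tract mortality is summarized on a 19-interval abridged age schedule:
under 1 year, 1–4, sixteen five-year intervals, and an open-ended 85+
group. For each interval $i$ of width $n_i$ with deaths $D_i$ and
person-years $PY_i$, the death rate is $m_i = D_i / PY_i$ and the
probability of dying within the interval is

$$q_i = \frac{n_i m_i}{1 + n_i (1 - a_i) m_i},$$

where $a_i$ is the average fraction of the interval lived by those dying
in it. The survivorship, person-years-lived and expectation columns
follow the standard recursions from a radix of 100,000; the open
interval has $q = 1$ and contributes $L = l / m$, the expectation of an
exponential tail at the terminal rate. A closed-form variance for $e_0$
accumulates each interval's binomial-style uncertainty,

$$\widehat{\mathrm{Var}}(e_0) = \sum_{i\,\mathrm{closed}}
  \frac{l_i^2\,[(1-a_i)n_i + e_{i+1}]^2\,q_i^2(1-q_i)/D_i}{\ell_0^2}
  \;+\; \frac{(l_{\mathrm{open}}/\ell_0)^2}{m_{\mathrm{open}}^2 D_{\mathrm{open}}},$$

with the final term accounting for sampling error in the terminal rate.
The literature names this family of estimator "adjusted Chiang II" but
does not pin down one canonical variance for the open interval; we chose
the terminal-rate adjustment above and validate it against a parametric
bootstrap (deaths resampled as Poisson, $e_0$ recomputed) rather than
asserting it: on realistic synthetic tracts with a few hundred deaths
the ratio of the closed form to the bootstrap standard deviation stays
within a factor of 1.25 (see the test suite and `scripts/acceptance.R`,
which recompute this ratio from scratch).

### Parameters and conventions

* `a_fraction` — defaults to 0.5 in every interval, i.e. deaths are
  spread evenly through each age interval. Demographic practice
  sometimes uses a smaller infant fraction (e.g. 0.1 for the under-1
  interval); the schedule accepts per-interval values, but the even
  spread is the package default because it is the assumption the
  screening thresholds below were designed around.
* Radix 100,000 — the demographic convention; all columns scale with it
  and $e_0$ is invariant to it.
* Confidence intervals are normal, $e_0 \pm z_{1-\alpha/2}\,SE$, at 95%
  by default. Nothing in the method fixes this level; it is a reporting
  choice.
* Person-years come from a single census-style population count
  multiplied by the study window (default 5 years).

### Reliability screening

Small-area $e_0$ estimates are unstable when exposure is thin. A tract
is excluded when any of the following holds over the study window:
fewer than 50 total deaths, fewer than 5,000 total person-years, or a
standard error above 2 years. The inequalities are strict: a tract with
exactly 50 deaths, exactly 5,000 person-years and an SE of exactly 2.0
is retained. All failed criteria are reported per tract, and the screen
can be bypassed (`apply_filters = FALSE`) for sensitivity runs over
every tract.

### Degenerate inputs

Three edge cases are handled explicitly rather than patched with
floors. An empty closed stratum (no deaths *and* no person-years) is
treated as rate zero, so sparsely populated age groups do not poison the
table. Deaths with zero exposure are an error — there is no finite rate
to report. And if survivors reach the open interval while its observed
rate is zero, the table cannot be closed; the tract is rejected (the
pipeline marks it `degenerate`) instead of substituting an arbitrary
tail rate, because any substitute would be pure invention and these
tracts fail the death-count screen anyway in practice. If an extreme
closed-interval rate pushes $q$ above 1 it is clamped to 1, which zeroes
the remaining survivorship — probabilities stay valid on pathological
synthetic inputs.

## Stage 2: the spatial Durbin error model

### Model

With $y$ the vector of tract life expectancies, $X$ the covariate
matrix, and $W$ a row-standardized queen-contiguity weights matrix,

$$y = \alpha + X\beta + WX\theta + u, \qquad u = \lambda W u +
\varepsilon, \qquad \varepsilon \sim N(0, \sigma^2 I).$$

$\beta$ are local (direct) effects, $\theta$ the effects of the
neighborhood average of each covariate (indirect), and $\lambda$
captures residual spatial autocorrelation. Because the spatial
multiplier applies only to the disturbance, spillovers are local: the
total impact of a covariate is simply $\beta_k + \theta_k$, and no
significance measure attaches to the sum. This local-spillover
specification avoids the global feedback of models with a spatial lag of
$y$, keeping coefficients directly interpretable.

### Estimation

Estimation concentrates the likelihood over $\lambda$. For a candidate
$\lambda$, $A = I - \lambda W$ whitens both sides; $\gamma = (\alpha,
\beta, \theta)$ is the least-squares solution of $Ay$ on $AZ$ with $Z =
[1, X, WX]$, $\hat\sigma^2 = RSS/n$, and the profile log-likelihood is

$$\ell(\lambda) = -\tfrac{n}{2}(\ln 2\pi + 1 + \ln\hat\sigma^2)
  + \ln|I - \lambda W|,$$

with the log-determinant evaluated from the eigenvalues of $W$,
computed once per lattice through the symmetric similarity transform
$D^{-1/2} A D^{-1/2}$ (guaranteeing a real spectrum). The admissible
interval is $(1/\omega_{\min} + 10^{-6},\, 1 - 10^{-6})$. A bounded
golden-section/parabolic search locates the maximum; because the profile
is very flat at its top, the maximizer is then polished with two
parabolic-vertex steps on a fixed $10^{-3}$ stencil, which averages out
floating-point noise and makes $\hat\lambda$ reproducible to better than
$10^{-8}$ across numerically equivalent datasets (translated outcomes,
rescaled covariates). Estimates at the boundary of the admissible
interval are reported with a warning rather than silently accepted.

Coefficient standard errors are conditional on $\hat\lambda$,
$\hat\sigma^2[(AZ)'AZ]^{-1}$ — the cross-information between $\lambda$
and $\gamma$ is asymptotically zero for error models, and this matches
the common practice of the field's estimators. The standard error of
$\hat\lambda$ itself comes from the numerical curvature of the profile.
p-values are standard normal (ML asymptotics), starred at the inclusive
thresholds 0.05 / 0.01 / 0.001. The reported $R^2$ is the squared
Pearson correlation between the observed outcome and the trend
prediction $Z\hat\gamma$ — a pseudo-$R^2$; the definition is recorded in
every diagnostics file because other definitions (variance ratios,
likelihood-based) give different numbers. The model AIC is
$2(k+2) - 2\ell$, counting the $k$ regression coefficients plus
$\lambda$ and $\sigma^2$. Model comparison against the spatial error
model without the lag block uses the likelihood-ratio test
($\chi^2$ with df equal to the number of dropped columns) and AIC.

### Spatial weights

Queen contiguity considers tracts neighbors when their boundaries share
at least one point. For polygon input the predicate matches boundary
vertices exactly (with an optional snap tolerance for messy coverages,
default 0 — appropriate for topologically clean tract files where
shared boundaries share vertices). Weights are row-standardized,
$w_{ij} = 1/|N(i)|$, so each lag is a neighborhood mean. Islands (tracts
with no neighbors) are kept in the structure as zero rows and reported;
the pipeline drops them before estimation by default, because a zero row
makes $\lambda W$ uninterpretable for that tract, and dropping with a
logged warning is more transparent than silent inclusion. After
reliability filtering the adjacency is rebuilt on the retained tracts —
neighbor sets are intersected with the retained set and the weights
re-standardized — so the row-stochastic contract holds in the analysis
matrix; every analysis neighbor is necessarily a neighbor in the
original coverage.

### Diagnostics

Multicollinearity is screened with variance inflation factors
($1/(1-R_k^2)$, flag above 10) and pairwise Pearson correlations (flag
above 0.7 in absolute value). The screen is advisory: correlated pairs
are listed, and the study configuration names the columns the analyst
excludes. Residual spatial autocorrelation is tested with global
Moran's I. The pipeline computes it on the whitened innovations
$\hat\varepsilon = (I - \hat\lambda W)(y - Z\hat\gamma)$, not on the raw
trend residuals: under the model the latter are autocorrelated by
construction ($u$ contains the spatial error process), so only the
innovations can be expected to pass. Inference is by random permutation
(999 draws by default, seeded), two-sided on $|I|$ with the add-one
rule $p = (\#\{|I_{perm}| \ge |I_{obs}|\} + 1)/(B + 1)$; permutation was
chosen as the default because it is assumption-light, and the normal
approximation under randomization is available as an alternative.
Normality (moment-based Jarque–Bera) and heteroscedasticity
(squared-residual-on-fitted slope) checks are advisory.

## The synthetic-data generator

The generator emulates the data structure the analysis assumes, at desk
scale:

* a rectangular lattice of unit-square tracts under queen contiguity
  (real tract coverages are irregular; the lattice preserves the
  neighborhood structure that matters to the estimator, not the
  geometry);
* covariates $x_j = (I - \rho_x W)^{-1} \eta_j$ with $\rho_x = 0.6$ by
  default, standardized — smooth spatial fields like the
  social-vulnerability proportions they stand in for;
* an outcome drawn exactly from the SDEM equation ("direct" mode), with
  defaults $\alpha = 80.75$ years (a typical tract-level life expectancy
  level), $\beta = (1, -0.5)$, $\theta = (0.3, 0)$, $\lambda = 0.5$,
  $\sigma = 1$ year — effect sizes chosen so that direct effects,
  lagged effects and error autocorrelation are all individually
  detectable on a 30×30 lattice;
* mortality counts $D \sim \mathrm{Poisson}(m \cdot PY)$ with a Gompertz
  baseline $m(a) = a_0 e^{ba}$ ($a_0 = 5\times10^{-5}$ per person-year,
  $b = 0.085$ per year of age — a hazard doubling roughly every 8 years,
  yielding $e_0$ in the low-to-mid 80s), covariates acting
  proportionally on the log rate, and exposure from a fixed declining
  age pyramid over a base population of 5,000 per tract and a 5-year
  window (a few hundred deaths per tract, the regime the reliability
  thresholds target). The open interval's rate is evaluated at a
  midpoint age of 90 — some fixed choice is needed to close the
  Gompertz schedule, and results are insensitive to it at these death
  counts.

Two outcome modes are deliberate: "direct" (outcome straight from the
SDEM equation) gives sharp parameter-recovery tests of the estimator;
"mechanistic" (outcome computed as $e_0$ from the simulated mortality)
exercises the whole pipeline end to end but attenuates effects with
life-table sampling noise. The default for recovery studies is direct,
because it separates estimator correctness from life-table noise.

What the generator does **not** emulate: irregular tract geometry and
the long-tailed degree distributions of real coverages, migration,
age-misreporting, under-registration, covariate measurement error, and
any resemblance to a specific state's covariate distributions. Passing
tests therefore demonstrate the correctness of the estimators under the
model's own assumptions, not the validity of those assumptions for any
particular real dataset.

The bundled fixtures are `tiny` (5×5, quick end-to-end), `recovery`
(30×30, parameter recovery) and `filterable` (6×6 with tracts engineered
to fail each reliability criterion — 49 total deaths; 4,995
person-years; thin exposure giving SE > 2 — plus a boundary tract with
exactly 50 deaths that must survive the strict screen). Every generator
is a pure function of its configuration and seed, and fixtures
regenerate byte-identically.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script validate at sizes chosen to
estimate each property precisely while staying desk-scale: 2,000
bootstrap replicates for the SE ratio (1,000 in the acceptance script),
50 replicate fits on the 30×30 lattice for parameter recovery and CI
coverage (30 in the script), 1,000 iid-noise replicates with 999
permutations each for the Moran size check, and 100 strong-effect plus
500 null replicates on a 15×15 lattice for likelihood-ratio power and
size (60/200 in the script). At these sizes the binomial margin on a
5% rejection rate is about ±1.8 percentage points at 99% confidence,
which is the band the checks use.

## Known limitations

* The life-table variance treats interval death probabilities as
  independent binomials; overdispersion (e.g. clustered deaths) would
  make the closed form anticonservative.
* Coefficient standard errors conditional on $\hat\lambda$ ignore the
  (asymptotically vanishing) $\lambda$–$\gamma$ cross-information; at
  small $n$ the coverage of intervals can dip slightly below nominal.
* The queen predicate relies on shared vertices; coverages digitized
  with mismatched boundary vertices need a positive snap tolerance.
* The analysis is ecological: tract-level associations between
  covariates and life expectancy need not hold for individuals.
* No small-area smoothing (hierarchical or Bayesian) is applied to the
  life expectancy estimates; screening discards rather than stabilizes
  thin tracts.
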