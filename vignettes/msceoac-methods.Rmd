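---
title: "Methods: the multistage clonal expansion model of OAC via Barrett's oesophagus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multistage clonal expansion model of OAC via Barrett's oesophagus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msceoac)
```

## The model

Oesophageal adenocarcinoma (OAC) in this package arises exclusively through
Barrett's oesophagus (BE), in two coupled stages.

**BE onset.** Conversion of normal squamous epithelium to BE is a
single-conversion event with age-dependent hazard
$$\nu(t) = \nu_0 \, m_{\text{cohort}} \, \bigl[1 + (RR - 1)\, p_{\text{GERD}}(t)\bigr],$$
where $\nu_0$ is a baseline conversion rate per year, $m_{\text{cohort}}$ a
birth-cohort multiplier, $p_{\text{GERD}}(t)$ the age- and sex-specific
prevalence of symptomatic gastro-oesophageal reflux disease, and $RR \ge 1$
the relative risk of conversion for GERD versus non-GERD individuals
(default $RR = 5$, swept over 2--6 in sensitivity analyses). The GERD
subgroup has rate $RR \,\nu_0 m$, the non-GERD subgroup $\nu_0 m$, and the
population rate is exactly their prevalence-weighted mixture. Unconditional
BE prevalence is $1 - e^{-\Lambda(t)}$ with $\Lambda = \int_0^t \nu$.

**Post-BE clonal expansion.** A BE segment of length $L$ (cm) carries
$N(L) = c \cdot L$ independent stem cells ($c$ = `cells_per_cm`). Each stem
cell acquires a first hit at rate $\mu_0$ per year and persists; one-hit
cells acquire a second hit at rate $\mu_1$, each spawning the founder cell
of a premalignant clone. Premalignant cells divide at $\alpha_P$, die or
differentiate at $\beta_P$, and transform at $\mu_2$, spawning the founder
of a malignant clone while the parent persists. Malignant cells divide at
$\alpha_M$, die at $\beta_M$, and trigger clinical detection at $\rho$ per
cell per year, so a clone of $n$ cells is detected at rate $n\rho$
(size-based detection). All rates are per cell per year.

The probability that a single cell of each type produces no detected cancer
within $\tau$ years satisfies the backward system
$$S_M' = \beta_M - (\alpha_M + \beta_M + \rho) S_M + \alpha_M S_M^2,$$
$$S_P' = \beta_P - (\alpha_P + \beta_P + \mu_2) S_P + \alpha_P S_P^2 + \mu_2 S_P S_M,$$
$$S_1' = \mu_1 S_1 (S_P - 1), \qquad S_0' = \mu_0 S_0 (S_1 - 1),$$
with all initial values 1. The "parent persists, spawns" semantics (a
mutation event adds a daughter of the next type without removing the
parent) is what makes the mutation terms multiplicative
($\mu\, S_{\text{parent}} S_{\text{child}}$ rather than replacing the
parent). $S_M$ alone has constant coefficients and therefore a closed-form
Riccati solution through the roots of
$\alpha_M x^2 - (\alpha_M + \beta_M + \rho) x + \beta_M$; the test suite
uses that closed form, written independently of the solver, as an oracle.

**Segment mixture and population hazard.** A whole segment survives as
$S_0(\tau)^{N(L)}$ by stem-cell independence; the exponent is kept
continuous rather than rounded. Marginalising over the Beta($a$, $b$)
length law on $[0, L_{\max}]$ by 16-node Gauss--Legendre quadrature gives
$S_{BE}(\tau) = E_L[S_0(\tau)^{N(L)}]$, with the derivative computed
analytically as $E_L[N S_0^{N-1} S_0']$. Mixing over the BE onset age then
yields the population quantities
$$S_{\text{pop}}(t) = e^{-\Lambda(t)} + \int_0^t \nu(s)\, e^{-\Lambda(s)}\, S_{BE}(t-s)\, ds,$$
$$h_{\text{OAC}}(t) = \frac{\int_0^t \nu(s) e^{-\Lambda(s)} \bigl(-S_{BE}'(t-s)\bigr) ds}{S_{\text{pop}}(t)},
\qquad
p^{cf}_{BE}(t) = \frac{\int_0^t \nu(s) e^{-\Lambda(s)} S_{BE}(t-s)\, ds}{S_{\text{pop}}(t)},$$
the hazard of first OAC detection and the prevalence of cancer-free BE,
both among persons alive and cancer-free at age $t$. Because every case
passes through BE, the annual progression rate among prevalent cancer-free
carriers is identically $h_{\text{OAC}}/p^{cf}_{BE}$.

In the limit where all division and death rates vanish and the four
remaining rates ($\mu_0, \mu_1, \mu_2, \rho$) are small, the per-cell
hazard grows as $\tau^3$ — the classical multistage (Armitage--Doll)
power-law with four rare events — which the tests verify as a log--log
slope of 3 within $\pm 0.05$.

## The stochastic simulator as oracle

`simulate_cohort()` runs an exact event-driven (Gillespie) simulation of
the identical semantics: BE onset by inversion of the tabulated
$\Lambda(t)$, segment length from the Beta law, then aggregated-propensity
event steps over the one-hit, premalignant and malignant compartments
(total rate = count $\times$ per-cell rate, exponential waiting times)
until detection or the censoring age. Clones are tracked as counts, not
lineage trees, which preserves exactness for every quantity this package
reports. Each individual draws from a counter-seeded xoshiro256++
substream, so cohorts are reproducible and histories do not depend on
simulation order or cohort size. A safety cap (default $10^7$ events per
individual) turns runaway supercritical simulations into an error rather
than a silent truncation.

Because the simulator shares no code with the analytic engine beyond the
parameter containers, agreement between empirical cumulative incidence /
BE prevalence and $1 - S_{\text{pop}}$ / $p^{cf}_{BE}$ (within 3 binomial
standard errors at ages 50--80, for supercritical, subcritical and
fast-detection parameter sets) is the package's primary correctness
evidence for the hazard assembly, whose closed form is otherwise
unavailable.

The simulator draws BE onset directly from the requested subgroup's
$\nu(t)$ (population mixture, GERD, or non-GERD) and records the subgroup
label. It does not sample an individual GERD onset age: a prevalence curve
alone does not identify an individual-level GERD incidence process, and
using the mixture hazard keeps simulator and analytic engine exactly
like-for-like.

## Calibration and uncertainty

Registry-style incidence tables (sex, cohort, age bin, cases,
person-years) are fitted by Poisson maximum likelihood with
$\lambda = \text{PY} \times h(\text{bin midpoint})$; midpoint evaluation
is an $O(\Delta^2)$ approximation to the bin-average hazard and is the
default for speed. Only rate combinations are identifiable from incidence
alone, so the default free set is small — $\nu_0$ (optionally
sex-stratified) and $\mu_2$, with growth, detection and segment parameters
fixed from configuration; `fit_spec()` exposes the choice. Optimisation is
Nelder--Mead (Brent in one dimension) on the log-parameter scale with
five seeded multi-starts drawn log-uniformly within a factor-of-10 band,
and a relative tolerance of $10^{-8}$ on the log-likelihood; fits are
bit-reproducible given the seed.

Nested stratifications are compared by likelihood-ratio tests
($2\Delta\ell$ against the $\chi^2$ upper tail). Parameter uncertainty
uses draws from the asymptotic normal approximation on the log-parameter
(estimation) scale, with covariance the inverse observed information from
a numerical Hessian — the log scale makes positivity automatic, which is
why draws are truncated-free; a nonparametric bootstrap over table rows is
the logged fallback if the information matrix is singular. Prediction
intervals re-run the projection per draw and take percentile bounds.

## Projection

`expected_cases()` multiplies census person-years by
$h_{\text{OAC}}(\text{age} + 0.5)$ for the matching sex and birth cohort
(cohort = year $-$ age floored to its decade; cohorts outside the fitted
range clamp to the nearest with a warning), summed over ages 40--90 by
default. Within-year depletion is ignored (incidence $\approx$ hazard
among the alive cancer-free), the standard registry convention with error
$O(h^2)$. BE carrier counts weight person-years by $p^{cf}_{BE}$, and the
attributable fraction is capped at 1 when the model over-predicts the
observed count, with the excess reported separately — over-prediction
means the BE pathway accounts for all observed cases, not more than all.

## Synthetic data and the demo configuration

All study-shaped inputs are generated in code: logistic GERD prevalence
curves $p(t) = p_{\max}/(1 + e^{-k(t - t_0)})$ tabulated on ages 0--100;
census-style person-year tables with a plateau-then-linear-decline age
pyramid; Poisson-sampled incidence tables on 5-year bins over ages 40--89
(registry-like granularity); and Bernoulli screening-yield cohorts. Every
generator is deterministic given its seed.

The packaged demo configuration is a synthetic ground truth chosen once so
the model's outputs have realistic orders of magnitude: cancer-free BE
prevalence near 1--2% by age 60 in men (a few tenths of a percent in
women, via a 4:1 male:female $\nu_0$), lifetime OAC risk near 1%, GERD
relative risk 5, Beta(2, 6) segment lengths on $[0, 10]$ cm (mean 2.5 cm)
at 100 stem cells/cm, and cohort multipliers rising from 0.5 (1900s) to
1.2 (1970s). The division rates ($\alpha_P = 2$, $\alpha_M = 3$ per year)
are deliberately demo-scale — smaller than the ~10/yr used in the
carcinogenesis literature — so the exact event-driven oracle remains
cheap at the $10^5$-cohort sizes the validation uses; the analytic engine
itself has no such constraint. These values are not any published
calibration, and none of the package's conclusions depend on them: every
test is against an internal oracle or a generating truth, not against
external data.

What passing tests therefore show is internal consistency — the analytic
hazards, the exact simulator, the likelihood machinery and the projection
arithmetic all describe the same stochastic process — plus correct
statistical calibration (LRT type-I error, interval coverage, parameter
recovery) under correctly specified synthetic data. They do not show that
the demo rates describe any real population: real registry data bring
model misspecification (secular trends, diagnostic drift, competing
mortality) that the generators intentionally do not emulate.

## Numerical choices

* Backward ODEs: `deSolve::ode` (lsoda), rtol $10^{-8}$ / atol $10^{-10}$;
  solutions clipped to $[0, 1]$ after a $10^{-6}$ sanity band, with an
  error naming the offending component beyond it.
* Age/tau grid: uniform, default 0.1 years to age 100. The outer onset
  integrals are trapezoid sums evaluated as FFT convolutions with endpoint
  half-weight corrections ($O(n \log n)$); the grid step controls the
  $O(\Delta^2)$ quadrature error. Calibration-heavy simulations use a
  0.25--0.5-year step, which changes fitted hazards well below the Poisson
  noise at the table sizes used.
* $S_{\text{pop}}$ floor $10^{-12}$: the conditional quantities divide by
  $S_{\text{pop}}$, and falling below the floor raises an error rather
  than returning garbage.
* Segment quadrature: 16-node Gauss--Legendre against the Beta density,
  weights normalised to sum to exactly 1 (for integer shape parameters the
  rule is already exact; normalisation guards non-integer shapes).
* Hazard at age 0 is pinned to 0 and $p^{cf}_{BE}(0) = 0$, the exact
  limits of the mixture.
* Degenerate inputs: zero onset gives identically zero hazard and
  prevalence; zero detection gives all survival probabilities 1; an
  all-zero incidence table drives $\hat\nu_0$ to its lower bound.

## Problem sizes used by the validation suite

Simulator--analytic agreement uses $10^5$ individuals per parameter set
(three sets). Parameter recovery uses 2 sexes $\times$ 3 cohorts at
$10^7$ person-years per stratum. The LRT type-I simulation uses 200
replicates of 2 sexes $\times$ 1 cohort at $2 \times 10^7$ person-years —
large enough per stratum that the $\chi^2$ asymptotics the test checks
actually apply (at much smaller strata the finite-sample rejection rate
drifts above nominal, which is a property of small counts, not of the
implementation). End-to-end coverage uses 20 replicates at $10^6$
person-years per stratum with 200 parameter draws each. At these table
sizes the maximum-likelihood estimate of $\mu_2$ carries roughly 15%
sampling scatter because $\nu_0$ and $\mu_2$ both scale the hazard and are
separated only by curve shape; this is a statistical identifiability
limit, visible in the likelihood itself, not an optimiser artefact.

## Known limitations

* No competing mortality, no dysplasia grading states, no spatial clone
  geometry, no surveillance or intervention effects.
* Cohort effects enter only as multipliers on $\nu_0$; period effects and
  diagnostic drift are out of scope.
* GERD enters through prevalence and a fixed relative risk; symptom
  duration, severity and medication effects are not modelled. The GERD
  subgroup applies $RR$ at all ages (the upper band of the heterogeneous
  reality).
* Midpoint bin evaluation and the incidence$\approx$hazard convention bias
  results only at second order in the bin width and hazard respectively,
  but both become visible if bins are made very wide or hazards large.
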