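---
title: "Quantifying prolonged hospital stay from nosocomial infections: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prolonged hospital stay from nosocomial infections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nilos)
```

## The model and its assumptions

`nilos` works in the simplest multistate model that can separate
pre-infection from post-infection hospital time: three states —
0 (admitted, uninfected), 1 (nosocomial infection, NI), 2 (discharge or
death, a combined absorbing endpoint) — with constant transition hazards
λ01, λ02, λ12 in units of events per day. Three assumptions do all the
work:

* **Time homogeneity.** Each hazard is constant over the stay. Waiting
  times are then exponential, sojourn means are reciprocal rates, and
  every estimand below has a closed form. Real hazards usually vary with
  time since admission; this simplification buys transparency and exact
  algebra at the cost of realism (see Limitations).
* **Markov property.** The future depends only on the current state, not
  on when it was entered. Under constant hazards this is automatic
  (memorylessness), and it is what makes the landmark contrast equal at
  every landmark day.
* **Combined endpoint.** Discharge alive and in-hospital death are
  merged. This is defensible when the target is length of stay and its
  costs, but any LOS analysis should be read alongside a mortality
  analysis; separating the two endpoints needs a four-state model that
  is out of scope here.

The mean total length of stay decomposes as
$\overline{LOS} = \frac{1}{\lambda_{01}+\lambda_{02}} +
\frac{\lambda_{01}}{\lambda_{01}+\lambda_{02}}\cdot\frac{1}{\lambda_{12}}$,
and whenever infection slows discharge (λ12 < λ02, with λ01 > 0) it is
bracketed: $1/\lambda_{02} < \overline{LOS} < 1/\lambda_{12}$.

## The four estimands

```{r estimands}
h <- hazards(124 / 6442, 632 / 6442, 124 / 1527)
c(a1 = a1(h), a2 = a2(h), a3 = a3(h), a4 = a4(h))
```

* **A1 = 1/λ12** — the retrospective contrast: mean LOS of eventually
  infected minus eventually uninfected patients, strata formed at the
  end of stay. It is always positive, even at hazard ratio
  λ12/λ02 ≥ 1, because the pre-infection stay of infected patients is
  counted as if caused by the infection (time-dependent, a.k.a.
  immortal-time, bias). It is implemented because it is ubiquitous in
  the literature and the package exists partly to show what is wrong
  with it.
* **A2 = 1/λ12 − 1/λ02** — attributable LOS per infected patient: the
  post-infection sojourn against the stay in a hypothetical world whose
  infection hazard is switched off.
* **A3 = mean LOS − 1/λ02** — population-attributable LOS: the same
  comparison averaged over everyone, infected or not. In product form
  A3 = risk(NI) × (1/λ12) × (λ02−λ12)/λ02: the patient-level excess
  diluted by the infection risk.
* **A4 = (λ02/λ12 − 1)/(λ01+λ02)** — change in residual LOS: condition
  on the state occupied at a landmark day s and compare mean remaining
  stay of currently infected versus currently uninfected patients.
  Under time homogeneity the contrast is the same for every s and also
  equals sojourn1 − mean LOS.

A2–A4 share the sign of λ02 − λ12 and obey A3 + A4 = A2;
`direction_diagnostics()` checks the sign equivalences and
`relationship_table()` evaluates all twelve pairwise differences and
ratios both from the estimand values and from their closed forms in the
hazards, flagging ratios with a zero denominator as undefined rather
than returning infinity.

## Estimation

The maximum-likelihood estimators under constant hazards are the
incidence densities: events divided by person-days at risk in the origin
state. `aggregate_counts()` reduces a long-format event history (one row
per transition interval, columns `id,from,to,entry,exit`) to the six
sufficient statistics; `estimate_hazards()` divides; `fit()` composes
the whole pipeline. Intervals are half-open with `exit > entry`
strictly: zero-length sojourns are unidentifiable under the exponential
model and break path validation, so they are rejected with an error
naming the patient. Censoring (`to = "cens"`) contributes person-days
but no event; the worked example cohort is complete, so censoring
appears only in tests.

**Undefined rather than NaN.** A cohort with no post-infection
discharges gives λ̂12 = 0, and every quantity that needs 1/λ12 is then
reported as an explicit undefined outcome (`NA` value plus an
`undefined` flag in the report), never as a silent `NaN` or `Inf`.
λ01 = 0 is the one permitted zero: risk, odds, mean LOS and A3 have
well-defined limits (A3 → 0) and return them.

## Uncertainty

The source analysis reports no variance for any estimand; the interval
machinery is this package's own addition and the reports label it as
such. Two designs are offered:

* **Patient-level bootstrap** (`bootstrap_ci()`, default B = 1000,
  level 0.95): resample patients — whole paths, never rows — with
  replacement, re-estimate, take percentile intervals. The estimands are
  ratios of dependent hazard estimates, so this is the honest default
  for them. Replicates on which a quantity is undefined (e.g. no
  infected patients resampled) are counted and reported per quantity,
  not dropped silently; an interval is itself undefined only if every
  replicate was. Resampling uses R's default Mersenne-Twister generator
  seeded once, so a fixed seed reproduces intervals bit for bit.
* **Delta-method Wald intervals on the log scale**
  (`hazard_ci_delta()`): for the three hazards only, using
  se(log λ̂) = 1/√events — a cheap large-sample alternative where the
  bootstrap would be overkill.

## The simulator and what it does (not) emulate

`simulate_cohort()` draws cohorts from the model itself: per patient an
exponential state-0 exit time at rate λ01 + λ02, a routing draw to
state 1 with probability λ01/(λ01+λ02), and, if infected, an
exponential state-1 sojourn at rate λ12. Draws are inverse-transform
exponentials (−log u / rate) in one fixed, documented order — all n
state-0 exit uniforms, then all n routing uniforms, then one sojourn
uniform per infected patient in patient order — chosen so the output is
vectorisable yet bit-stable under refactoring for a given seed.
`simulate_hypothetical_world()` is the same sampler with λ01 forced to
zero: the counterfactual population behind A2 and A3.

The simulator plays two roles. As the fixture generator it supplies
arbitrarily large, perfectly specified cohorts for the tests. As the
*correctness oracle* it furnishes an empirical counterpart for each
closed form, wired together in `validate_estimands_mc()`:

* infected fraction vs risk(NI);
* retrospective stratified difference vs A1;
* mean state-1 sojourn minus hypothetical-world mean LOS vs A2;
* real-world minus hypothetical-world mean LOS (two worlds, independent
  seeds) vs A3;
* landmark residual difference at s ∈ {2, 5, 10} days vs A4, the three
  landmarks doubling as a memorylessness check.

The Monte-Carlo tolerance convention is |empirical − closed form| ≤
3 × MC standard error, with the SE estimated from the simulated sample
itself (binomial for the fraction, stratum-variance formulas for the
differences). The test suite runs the oracle suite at n = 3×10^4 and
the acceptance checks at n = 10^6 patients, where the checks take on the
order of a minute; smaller deterministic tests use hand-built two- or
three-row histories.

What the generator deliberately does **not** emulate: time-varying or
covariate-dependent hazards, staggered admissions and calendar time,
interval-censored infection times, clustering/frailty, and separate
discharge and death destinations. Passing oracles therefore certify the
algebra and the sampling machinery under the model's own assumptions —
they say nothing about how well constant hazards describe any real
cohort. The landmark oracle likewise validates only the time-homogeneous
case, where the contrast is constant in s; it does not reproduce
finite-sample landmark-aggregation estimators used on real data.

## Numerical choices

* Identity checks (A3 + A4 = A2, the relationship table's two routes,
  A4 = sojourn1 − mean LOS) use relative tolerance 1e−10: both sides are
  computed from the same doubles, so anything looser would hide real
  bugs and anything tighter chases rounding noise.
* Reports retain unrounded values and add roundings at the conventional
  reporting precision — 2 decimals for days, 3–4 for rates and ratios —
  so comparisons with published tables are unambiguous. Tabled estimands
  are always computed from unrounded counts, never from rounded hazards.
* At the knife edge λ12 = λ02 the attributable estimands are exactly
  zero in floating point when the equality is exact; sign diagnostics
  treat magnitudes below 1e−12 of the estimand scale as zero so that
  rounding noise cannot flip a reported direction.
* Ratio entries with a zero denominator estimand, and estimands whose
  required hazard is zero, are reported as undefined, as above.
* Bootstrap percentile intervals use `stats::quantile` type 7 (R's
  default); with B = 1 the interval degenerates to the single
  replicate's value.

## Problem sizes in the checks

Chosen to make 3-SE Monte-Carlo comparisons decisive while keeping the
whole suite desk-scale: oracle equivalence at n = 10^6; goodness of fit
of the state-0 exit distribution at n = 10^5; pipeline closure at
n = 5×10^4 with bootstrap-SD error bars; parameter recovery over 200
cohorts of n = 756 (the worked example's size) with B = 500 bootstrap
replicates and nominal 95% coverage of A4 assessed against a
3-standard-error binomial band.

## Limitations

Everything inherits the model's assumptions: constant hazards, a single
combined endpoint, no covariates. The estimators are plug-in closed
forms, not general nonparametric multistate estimators, so they should
be read as the time-homogeneous special case; regression adjustment,
time-inhomogeneous and semi-Markov extensions, and separate
discharge/death endpoints are explicitly out of scope. The bootstrap is
nonparametric in the patients but still evaluates the model's closed
forms on each replicate, so its intervals quantify sampling noise, not
model misspecification.
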