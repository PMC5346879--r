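---
title: "Comparing size and maturation models for paediatric clearance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing size and maturation models for paediatric clearance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clscale)
```

## The model family

Clearance in a growing child reflects two processes: organ size, captured
by allometric weight scaling `(WT/70)^b`, and functional maturation,
which multiplies the size prediction by a factor that climbs from near
zero in very preterm neonates towards 1. The standard parameterisation
fixes `b = 0.75` and uses a sigmoid-Emax (Hill) function of
postmenstrual age:

$$CL = CL_{70}\cdot\left(\frac{WT}{70}\right)^{0.75}\cdot
\frac{PMA^{Hill}}{PMA_{50}^{Hill}+PMA^{Hill}}$$

`clscale`'s catalogue holds this model (id "1") together with the other
published structures it is compared against: pure allometry with
estimated or fixed exponents (2–4), linear and exponential age terms
developed in neonatal datasets (5–8), an estimated-exponent sigmoid
variant (9) and a fully fixed glomerular-filtration variant (9b,
exponent 0.632, Hill 3.33, PMA50 55.4 weeks), asymptotic and PNA-driven
maturation (10–12), stepwise exponents by age or weight band (13–15) and
exponents that decay continuously with weight or age (16–18). Every
model is normalised to a 70 kg adult: the first parameter is always
`CL70`, the typical mature clearance in L/h, which is what makes
parameters comparable across structures and drugs.

Units are fixed throughout: weight in kg, postnatal age (PNA) in years,
gestational (GA) and postmenstrual age (PMA) in weeks, with
`PMA = GA + PNA * 365.25/7`. One day is `1/365.25` years.

Design choices in the catalogue that the printed model descriptions
leave open:

- **Step-band edges** (models 13–15) are inclusive below: exactly 3
  months uses exponent 1.2, exactly 2 years uses 1.0, exactly 5 years
  uses 0.9, exactly 9 kg uses 1.25, exactly 16.5 kg uses the low-weight
  exponent. The 5-years-inclusive choice is what reproduces the
  published child value of the stepwise model.
- **Non-positive predictions.** The linear maturation structures (6, 7)
  can predict CL ≤ 0 for very preterm covariates. `evaluate_cl()`
  returns such values unclipped, with a warning and a `nonpositive`
  flag; the fitting objective scores those parameter points as `+Inf`.
  Clipping would hide exactly the behaviour the comparison is meant to
  expose.
- **Model 9b discrepancy.** Evaluating the printed 9b structure at its
  published `CL70 = 5.59` gives 0.21 L/h for the reference neonate,
  not the published 0.34 L/h. We document rather than resolve this: no
  re-arrangement of the printed constants we tried reproduces the value,
  and the package reports what the equation computes.

## Data handling

Study-level records (one row per reported mean clearance) arrive in a
simple CSV dialect (`read_cl_data()`). The imputation rules mirror how
literature-extracted tables are assembled: mid-range ages collapse to
their midpoint (flagged), GA defaults to 40 weeks when unreported
(flagged), missing weights are filled from a weight-for-age reference
(flagged), and birth weight stands in for current weight in neonatal
studies. Imputation never overwrites an observed value. The inclusion
filters drop gentamicin records above 50 years of age (renal decline
would otherwise contaminate the adult anchor) and any record pooled over
a wide age range; `apply_filters()` returns both partitions so the
exclusion log is always reconstructible.

The age groups for the stratified comparison are a gapless partition:
neonates (0–28 days), infants (>28 days to <2 years), children (2 to
<12 years), adolescents (12–18 years), adults (>18 years). The printed
group labels ("23.9 months", "11.9 years") leave micro-gaps; we read
them as open upper bounds at 2 and 12 years because the likelihood
decomposition requires every record to belong to exactly one group.

The packaged weight-for-age and birthweight-for-GA tables are
**synthetic references**: piecewise-linear, sex-averaged curves anchored
to the reference children (3.5/9/18/39 kg at 0/1/5/12 years). They are
pluggable (`growth_function` arguments) so a user can substitute a
published growth model.

## Estimation

Because clearance is positive and approximately log-normal, the residual
model is exponential: `CL_obs = CL_pred * exp(eps)`,
`eps ~ N(0, sigma2)`, giving

$$-2LL = \sum_i \log 2\pi + \log\sigma^2 +
\frac{(\log CL_{obs,i}-\log CL_{pred,i})^2}{\sigma^2}.$$

The `log(2*pi)` constant is included so absolute −2LL has its textbook
definition; every AIC difference is unaffected. `fit_cl()` minimises
−2LL jointly over the structural parameters and `sigma2` with `nlminb`
on a transformed scale: positivity-constrained parameters and `sigma2`
are log-transformed, while genuinely sign-free parameters (the linear
age slopes of models 5–8, the weight exponent of the exponent in model
16) stay untransformed. Multistart (default 20 launches) jitters the
starting point by U(0.5, 2) multiplicatively on positive parameters and
±0.5 additively on unconstrained ones, under a caller-supplied seed; the
default `CL70` start back-allometrises the observed clearances so both
low-clearance (gentamicin-like) and high-clearance (midazolam-like) data
start in the right decade.

Standard errors come from the central finite-difference Hessian of −2LL
(relative step `1e-4`, step-halving on non-finite entries):
`cov = 2 * solve(H)` on the estimation scale, delta-method-transformed
to natural-scale SEs for reporting. Computing the Hessian on the
estimation scale keeps it well conditioned and is exactly the scale the
parametric sampler needs; reporting natural-scale SEs mirrors how the
estimates themselves are quoted. A singular Hessian yields a converged
fit with SEs marked unavailable. A near-perfect fit drives `sigma2` to
its floor (`1e-12`) and is flagged; no covariance is attempted there.

AIC is `−2LL + 2p`. By default `p` counts structural parameters plus
the residual variance; a `"structural"` convention is available to match
reports that call the standard model a three-parameter model. Applied
uniformly, the choice cancels in every comparison. The age-group
decomposition evaluates each record's −2LL contribution at the *global*
estimates, sums within groups (they add back to the global value to
machine precision) and adds `2p` per group — the `2p` term likewise
cancels in differences, which are the quantity of interest.

## Uncertainty, dosing, predictive checks

`sample_parameters()` draws from the multivariate normal of the
estimates on the estimation scale and back-transforms, so draws respect
positivity without truncation. `typical_cl_ci()` evaluates the model
per draw for one individual; the reported `point` is the plug-in
prediction at the estimates, with the simulated median alongside
(the two differ only by back-transformation curvature). Draws giving
undefined or non-positive clearance are invalid; above 2.5% invalid
draws the 95% interval is declared non-constructible — at that point a
2.5th percentile no longer exists, the same failure mode that makes
intervals unreportable for heavily parameterised exponent models whose
uncertain parameters can change sign. Percentiles use linear
interpolation between order statistics (`quantile` type 7).

Steady-state dosing follows from clearance alone:
`dose = CL * Css / WT` in ug/kg/h, with a default target of 250 ug/L
(the lower end of the midazolam sedation window), rounded to the
clinical titration step (25 ug/kg/h in neonates, 50 above; midpoints
round up).

Visual predictive checks simulate `CL_pred * exp(eps)` at every observed
covariate point (no binning — the model has no between-subject
variability term, so residual noise is the only source of spread) and
take 2.5/50/97.5 percentiles. The lognormal closed form
(median = `CL_pred`, band ratio = `exp(2*1.96*sigma)`) serves as a
cross-check in the tests. The default display is log-log, which spreads
the neonatal weight decade.

## The synthetic study generator

`simulate_cl_study()` emulates the structure of the literature-extracted
tables: per-age-group record counts, neonatal gestational ages U(37, 42)
weeks (U(24, 37) for the preterm fraction — we read the preterm draw as
bounded at 37 weeks so the fraction parameter actually controls the
preterm share), neonatal weights from the birthweight-for-GA reference,
older ages uniform within group bounds with GA fixed at 40, weights from
weight-for-age with ~15% log-normal jitter, and clearances from a chosen
catalogue model with multiplicative log-normal noise. The default
configuration is a gentamicin-like study: 66 records, ~40% neonates
(26/12/10/8/10 across the five groups), adults capped at 50 years,
generated from model 1 at its published gentamicin estimates
(`CL70 = 5.97`, `Hill = 4.19`, `PMA50 = 45.1`, `sigma2 = 0.075`). These
defaults are the study conditions, not tuning knobs.

What the generator does *not* emulate: the unknown joint covariate
distribution of the real tables, between-study heterogeneity,
reporting/rounding error in extracted means, and unequal study sizes
(records are unweighted by subject count in fitting, since the
comparison it reproduces describes no weighting; `n` is retained for
sensitivity analyses). Passing recovery and calibration tests on
generated data therefore demonstrates correctness of the machinery under
the stated error model, not robustness to real-data pathologies.

`recovery_experiment()` wraps generate → refit → summarise: relative
bias and 95% Wald coverage per parameter. Replicate fits start from the
generating values with multistart jitter, which probes estimation
uncertainty rather than global search (the optimiser's global behaviour
is tested separately against an exhaustive grid oracle). Problem sizes
in the shipped tests — 100 replicates of 66 records for recovery, ~1000
records for VPC calibration, 80×80×60 grids for the oracle — were chosen
as the smallest designs where the Monte-Carlo error is comfortably
inside the asserted bands.

## Refitting published datasets

The real study-level tables this package models live in journal
supplementary material and are not redistributed. `refit_published()`
runs the full pipeline (read → impute → filter → fit → ΔAIC) on a
user-transcribed CSV and returns a structured `available = FALSE` result
when the file is absent, so downstream reports skip the refit rather
than fail.

## Known limitations

- No between-study random effects: each record is treated as an
  independent observation of typical clearance, as in the comparison
  this package reproduces.
- Wald intervals and the multivariate-normal parameter sampler both rest
  on local quadratic behaviour of the likelihood; for weakly identified
  five-parameter exponent models the intervals can be badly calibrated —
  which is precisely what the non-constructibility reporting surfaces.
- The growth references are synthetic stand-ins adequate for imputation
  and simulation, not clinical growth standards.
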