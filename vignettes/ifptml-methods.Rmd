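---
title: "Methods: information-fusion perturbation-theory modelling of longitudinal anticoagulation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-fusion perturbation-theory modelling of longitudinal anticoagulation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Warfarin has a narrow therapeutic index and large between-patient
variability, driven by demographics, co-medication and pharmacogenetics
(chiefly CYP2C9, which controls clearance, and VKORC1, which controls
target sensitivity). During anticoagulation after cardiac surgery the
international normalized ratio (INR) is measured repeatedly and the daily
dose is titrated towards a target band — here 1.8–2.5. This package
models such longitudinal follow-up data: every INR measurement of every
patient becomes one *case*, described by its recent dose history, clinical
covariates and categorical labels, and the modelling question is either
regression (predict the INR) or classification (will the INR be *Within*
the band or *Out* of it).

The package implements the full chain as composable, data-frame-first
functions: a synthetic cohort generator, the information-fusion (IF) case
table, perturbation-theory operators (PTOs), linear discriminant scoring
plus a standard ML battery, and the evaluation metrics.

## The scoring model

The linear model family has the general form

$$
f(v_{ij})_{calc} = a_0 + a_1\,\alpha\, f(v_{ij})_{ref}
 + \sum_{s} a_{c,s} \sum_{k} a_{k,s}
 \left( v_k - \alpha \langle v_k(\mathbf{s}_j) \rangle \right)^{q\,r}
$$

where $v_k$ are continuous inputs, $\mathbf{s}_j$ is the case's vector of
categorical labels, $\langle v_k(\mathbf{s}_j)\rangle$ is the *moving
average* of $v_k$ over training cases sharing a label (the group
expectation), and $f(v_{ij})_{ref}$ is the prior probability that the case
is in the desired class given its labels. The hyperparameters are a
switch $\alpha$, a moment power $q$ and a distance power $r$; three
presets define the package's three data levels:

| level | $\alpha$ | $q$ | $r$ | features |
|-------|----------|-----|-----|----------|
| `raw` | 0 | 1 | 1 | the original variables $v_k$ |
| `ma`  | 1 | 1 | 1 | first-order deviations $\Delta v_k(\mathbf{s}_j) = v_k - \langle v_k(\mathbf{s}_j)\rangle$, one per (variable, partition), plus $f_{ref}$ |
| `ed`  | 1 | 2 | 1/2 | second-order Euclidean distances $\lVert\Delta v_k(\mathbf{s}_j)\rVert$ over variable groups, plus $f_{ref}$ |

The coefficients $a_0, a_1, a_{k,s}, a_{c,s}$ are *model* weights, not
preprocessing weights: `build_features()` emits unweighted deviations and
distances, and the fitting algorithm (LDA or any battery member)
determines the coefficients. This is the only reading under which a
discriminant fit "determines the coefficients", and it keeps
preprocessing purely unsupervised apart from the frozen group means.
Intermediate $(\alpha, q, r)$ combinations are constructible through
`pt_config()` but unvalidated; only the three presets are exercised by
default.

## The synthetic cohort generator

No compatible public dataset exists at the visit level, so the package
ships a generator (`sim_params()`, `simulate_cohort()`) whose *marginal*
structure matches a published cardiac-surgery cohort summary: 246
patients, roughly 3&nbsp;000–3&nbsp;300 INR measurements, visit gaps of
6.7 ± 7.8 days (rounded positive normals, minimum 1 day), sex 63.8% male,
CYP2C9 \*1/\*1 : \*1/\*3 = 92.3 : 7.7, VKORC1 AA/AG/GG = 85.5/13.8/1.2
(renormalised — the printed percentages sum to 100.5), age 58 ± 13 y,
height 164.7 ± 8.8 cm, weight 63.9 ± 11.8 kg, and a mean administered
dose near 2.12 mg/d arising endogenously from titration.

The dose–response core is a deliberate design choice, not an estimate
from any real data:

* effective exposure $E$ = exponentially weighted sum of the previous 63
  daily doses, weights $2^{-d/h}$ normalised over the window. The
  half-life $h$ defaults to 2 days, giving the few-day onset lag that
  motivates "day-3 dose before the INR" predictors;
* INR $= \max(0.8,\; b + \beta\, G\, E / \text{weight} + \varepsilon)$,
  with baseline $b = 1.0$ (a normal unanticoagulated INR),
  $\varepsilon \sim N(0, 0.25)$ (a realistic blend of assay and
  biological noise), and $G$ the product of genotype multipliers
  (VKORC1 AA 1.25, AG 1.0, GG 0.8; CYP2C9 \*1/\*1 1.0, \*1/\*3 1.35 —
  signs follow the known pharmacology: AA carriers and \*3 carriers need
  lower doses);
* $\beta = 35$ INR·kg/(mg/d) was chosen once so that a typical patient
  (weight 64 kg, $G \approx 1.25$) reaches the band's interior at roughly
  2 mg/d, the cohort's reported mean dose scale;
* titration is a bang-bang clinician-feedback rule: below the band
  +0.25 mg/d, above it −0.25 mg/d, inside hold, effective the day after
  the visit. This reproduces the negative genotype→dose correlation of
  real cohorts without a pharmacokinetic engine.

Labs are stationary per-patient baselines plus visit noise, measured at
every in-hospital visit (first 14 days) and with probability 0.2
afterwards — this yields the irregular laboratory sampling that the
imputation stage exists for. Co-medications are per-patient Bernoulli
assignments with fixed daily doses, acute drugs confined to the
in-hospital window.

What the generator does *not* emulate: INR overshoot dynamics and dose
loading, informative dropout, adverse events, time-varying labs with
clinical trends, or any mechanistic vitamin-K physiology. Tests passing
on this cohort therefore demonstrate that the pipeline recovers structure
*of the kind it assumes*, not that the fitted models transfer to real
patients.

## Information fusion conventions

* The target interval is closed on both ends: a boundary INR of exactly
  1.8 or 2.5 is clinically in range, so `label_output()` maps it to
  `Within`.
* Day 1 is the first dosed day; `pod` (postoperative days, with surgery
  at treatment start) equals the visit day.
* The dose window is fixed at 63 days (`Dose01..Dose63` = dose 1..63
  days before the INR; `TreatDay01..TreatDay63` = consecutive days the
  level had been held). Early-course lags before the first dose are
  padded with zeros rather than dropped, keeping a fixed arity of 126 for
  every model.
* Genotype labels stay raw category strings (`"*1/*3"`, `"AA"`); they
  only ever define partitions and are never ordinally encoded.
* Imputation is last-observation-carried-forward within patient, then
  reference-table mean; the reference defaults to the table itself but
  should be the training table when transforming validation data.
* The scheme (`partition_scheme()`) is configuration, not code: the
  column roster of a real dataset is registered by the user rather than
  hard-coded, since published variable lists are not enumerated to the
  last column.

## Leakage and back-off

Group means are fitted on the training table only (`fit_group_means()`)
and frozen; validation and prediction rows are always transformed with
training-time expectations. Unseen labels — a genotype combination never
observed in training — back off to the global training mean
(`min_group_size` defaults to 1, i.e. any observed label is trusted).

The reference prior `f_ref` defaults to *joint* conditioning on the full
label vector with back-off to the global prevalence when fewer than 10
training cases match. Ten is small enough that common cells keep their
own prevalence and large enough to avoid degenerate 0/1 estimates from
singleton cells; the conditioning set is configurable because it is a
genuine modelling choice.

## The discriminant and the battery

`fit_lda()` is the two-class linear discriminant with pooled within-class
covariance, written in-package because its fitted coefficients *are* the
model family's realisation. Numerical choices: the pooled covariance gets
a ridge of `1e-6 × mean(diag(S))` (escalated tenfold, up to 1e-2, only if
the solve fails), because deviation features of the same variable across
partitions are near-collinear by construction; constant columns are
dropped with a warning and duplicated columns keep their first copy; the
decision threshold is score 0 with `Within` positive, since the
discriminant's intercept already centres the boundary between the class
means (with a log-prior offset). `fit_calibration()` supplies a logistic
map to posterior probabilities when probabilities rather than scores are
needed. The discriminant's chi-square is Bartlett's transform of Wilks'
lambda via Hotelling's $T^2$.

`forward_stepwise()` uses F-to-enter with p < 0.05 on the 0/1 class
indicator (the classical stepwise-discriminant equivalence), determinstic
first-maximum tie-break by column order, and an always-included expert
set — mirroring the practice of forcing pharmacologically established
variables (e.g. CYP2C9 status) into the model regardless of univariate
significance.

The ML battery (`fit_ml()`) is a set of thin adapters over established
implementations — `lm`/`glm`, `nnet`, `e1071` SVM and naive Bayes,
`caret` nearest neighbours, `randomForest` (bagging = a forest with
`mtry = p`) — each seeded for exact refit. The adapters never mutate the
feature table. Aliased coefficients from collinear features in the linear
fits are treated as dropped terms at prediction.

Three reference coefficient sets for the three data levels are bundled as
`builtin_model()`; they are kept verbatim for worked-example and
regression-test purposes, with term names mapped into this package's
feature namespace.

## Evaluation conventions

* Correlation is Pearson's, on (observed, predicted).
* RAE and RRSE normalise by deviations from the mean of the *same*
  evaluation set, the standard definition.
* Predicted bias is $100(\hat y - y)/y$ %, with the closed band
  $[-20, 20]$ counted as ideal; the three bins always sum to 100.
* The confusion-table chi-square uses 1 df and no continuity correction.
* The default split is case-level, fraction 0.75 (which maps 3261 cases
  to a 2446-row training set), seed mandatory. Case-level splitting of
  longitudinal data is optimistic — visits of one patient land on both
  sides — so a patient-level mode is provided and recommended when
  honest generalisation to new patients is the question.
* The univariate screen is advisory only; it routes continuous×continuous
  to Pearson, categorical×continuous to Mann–Whitney/Kruskal–Wallis,
  continuous×class to the rank-sum test and categorical×class to the
  chi-square test, flags p < 0.05, and applies no multiplicity
  correction.

## Problem sizes used by the test-suite

The operator identities run on a 30-case fixture against a naive
double-loop oracle; LDA recovery runs on the full default cohort (246
patients, ~3&nbsp;200 cases, ~1&nbsp;300 `ma` features); the stepwise and
permutation checks use constructed fixtures of 100–500 rows and 20
repeats; the screen's type-I calibration uses 200 pure-noise variables
(400 null tests) on an ~1&nbsp;000-case cohort; reproducibility checks
use 60-patient cohorts with a 10-day window. These sizes were chosen as
the smallest at which each property is statistically decidable.

## Known limitations

* The generator's response model is linear in exposure; it cannot create
  the INR overshoots that make real titration hard, so classification
  errors here are mostly one-sided (subtherapeutic early course).
* `ed`-level features with non-preset powers ($q$ odd, negative
  deviations, fractional $r$) can produce NaN; only the three presets are
  guaranteed.
* The battery adapters use library defaults plus a seed; no hyperparameter
  search is performed.
* With joint `f_ref` conditioning over many partitions most cells back
  off to the global prevalence; use `f_ref_mode = "partition"` when a
  single strong partition is known.
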