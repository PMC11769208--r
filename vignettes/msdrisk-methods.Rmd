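---
title: "Multicriteria long-term MSD risk prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicriteria long-term MSD risk prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msdrisk)
```

## The problem

Healthcare workers who lift and transfer patients accumulate load on the
neck, shoulders and elbows over years of repetitive handling. `msdrisk`
implements a prognostic model of the probability of developing a
musculoskeletal disorder (MSD) in each of those regions over 5-, 10- and
15-year horizons. The model deliberately combines two kinds of evidence:

* **population prevalence**: large cross-sectional studies give the base
  probability of an MSD as a function of age, and
* **individual motion data**: joint angle and moment time series recorded
  during lifting (typically from inertial motion capture) characterize how a
  particular worker moves — their range of motion, peak and cumulative joint
  loading, and left/right asymmetry.

## The model

For one body region, the probability of the disorder scenario is

$$p = Q \cdot \sum_{i=1}^{n} X_i, \qquad X_i = a_i \, q_i,$$

where $Q$ is the baseline probability at the evaluated age, $a_i$ is the
*element likelihood* of criterion $i$ (a dimensionless ratio: above 1 raises
risk relative to the population average, below 1 lowers it), and
$q_i = B_i / \sum_k B_k$ is the *weight coefficient* derived from integer
weight scores $B_i$. Because $\sum q_i = 1$, a subject whose every
likelihood equals 1 has $p = Q$ exactly: the model is a multiplicative
perturbation of the population baseline, anchored at neutrality. The
normalization $\sum q_i = 1$ is also the model's self-check
(`verify_normalization()`).

Three criterion kinds are supported:

* **categorical** — the subject belongs to exactly one level (sex;
  physical-readiness group: scores 1–6 low, 7–8 medium, 9–10 high);
* **proportional** — exactly two levels blended by continuous shares,
  $a = a_1 c_1 + a_2 c_2$ with $c_1 + c_2 = 1$ (side symmetry from the
  left/right split of cumulative moment; lifting technique from the share of
  work done with vs without an ergonomic belt);
* **parametric** — the likelihood is computed per subject as the ratio of a
  motion metric to its population mean (range of motion, maximum moment,
  cumulative moment). Cumulative moment — the time-integral of the absolute
  joint moment — carries a double weight score, since it is the proxy for
  chronic exposure.

### Baseline curves and the time shift

Baseline prevalence is modeled as an upward-opening quadratic in age,
$y = a_2 x^2 + a_1 x + a_0$: with aging, both declining capacity and
accumulated load raise risk at an accelerating rate. The package ships one
canonical curve per region (see `msd_baseline_curves()`). A horizon-$T$
prognosis evaluates the curve at the subject's age plus $T$; `shift_curve()`
implements this as a coefficient substitution so that the shifted curve
evaluated at the current age equals the original at age $+T$. Since all
three curves have $a_1, a_2 > 0$, prognosis probability is strictly
increasing in the horizon — the package asserts this invariant on its
outputs.

`fit_baseline()` refits curves from the packaged prevalence study records
(five studies, n = 212–1914, weighted by sample size) by weighted least
squares. The original extrapolation behind the canonical curves is
under-determined — plausible weighted fits do not reproduce them, and one
study (mean age 47, neck prevalence 0.390) sits well below the canonical
curve's 0.50 at that age — so refits report their deviation from the
canonical coefficients in diagnostics and never silently replace them.

### Rounding modes

Published criteria tables display 3-decimal values that are not mutually
consistent: one table prints $2/7$ as 0.285 (so its displayed column sums
to exactly 1.000), a second prints the last $2/9$ as 0.223 for the same
reason, and a third leaves 0.222 everywhere so its displayed column sums to
0.999. The engine therefore computes in full precision by default
(`exact`) and treats rounding purely as presentation: `display3` rounds
half-even to 3 decimals, and `table_match` additionally adds the rounding
defect of the displayed sum to the last largest coefficient, which is the
convention the sum-to-one tables follow. Printed element-factor cells are
reproduced by `display3`/`table_match` products; full-precision results
should always be computed in `exact` mode.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `horizons` | 5, 10, 15 | years | standard reporting horizons for occupational prognosis |
| `valid_age_range` | 20–75 | years | the range over which baseline curves are considered calibrated; outside it evaluation warns |
| likelihood clip | 0.1–3.0 | ratio | a single corrupt trial cannot blow up the factor sum; configurable |
| parametric weighting | 1:1:2 | — | cumulative moment doubled as the chronic-exposure metric (`composite_parametric_score()`, and the weight scores of the packaged tables) |
| sex-difference denominator | female mean | — | differences are reported as male relative to female; configurable by recomputing from the profiles |

The packaged elbow baseline curve exceeds probability 1 near age 60, inside
its nominal range; it ships as published, `evaluate_baseline()` clips with a
warning, and profile rows carry a `clipped` flag.

One packaged likelihood deserves a flag: the neck table's *high*
physical-readiness likelihood is 0.161, an order of magnitude below every
other likelihood (≈0.9–1.1) and plausibly a transcription error for
≈1.06. It ships as published; the packaged JSON carries a note, and highly
fit subjects will show visibly depressed neck risk under the default table.

## The synthetic-data generator

`generate_cohort()` and `generate_trials()` exist so that every pipeline
stage is testable without access to recorded motion data. The cohort
defaults state the reference study's population: 44 subjects, 16 male / 28
female (allocated exactly, not stochastically), age 28 ± 12 years truncated
to [18, 70], height 175.11 ± 11.58 cm, weight 75.30 ± 12.58 kg, three
scenarios (no patient assistance, patient assisting, ergonomic belt) with
three trials each. The readiness-score distribution is triangular peaking
at 7 — a wide spread across fitness groups; the exact shape is not
published, so this is a one-time modeling choice. Each subject draws from
an independent substream of the master seed, so enlarging a cohort never
reshuffles existing subjects.

Trials are parametric curves, not biomechanical simulation: angle and
moment follow $\sin^2$ profiles from neutral pose to neutral pose, with
peak moment proportional to body weight (0.5 / 1.1 / 0.7 N·m/kg for neck /
shoulder / elbow), a fixed 0.94 / 1.06 left/right load asymmetry, and
multiplicative trial noise (CV 0.05). Injected effects default to a 1.1
male range-of-motion multiplier and a 0.9 belt moment multiplier — the
source study reports no effect sizes for these contrasts, so the defaults
are order-of-magnitude choices and are labeled as such. What a green test
on synthetic data establishes is therefore *structural*: ratios injected by
construction are recovered by the estimation path, neutral cohorts
reproduce the shifted baselines exactly, and the pipeline is deterministic.
It does not establish that real lifting kinematics look like $\sin^2$
pulses, nor validate the published likelihood values themselves.

## Numerical and design choices

* **Cumulative moment integrates $|M|$** (trapezoid rule): signed
  integration would let flexion and extension cancel, understating
  exposure. Only ratios enter the model, so the per-trial vs per-shift
  normalization cancels; absolute values are reported per trial.
* **Per-subject averaging before ratio-taking**: parametric metrics average
  over a subject's repeated trials and scenarios; profiles are per subject,
  not per trial. Features are then held constant over the forecast horizon
  (the model's stated "technique does not change" assumption, implemented
  literally).
* **Clipping**: $p = Q \sum X$ can exceed 1 for large factor sums; the
  product is clipped into [0, 1] and flagged, never silently.
* **Extreme scenarios and dynamic impact**: because $\sum X$ is additive,
  per-criterion extremes are attained independently, so bounds need no
  combinatorial search (tests verify against exhaustive enumeration anyway).
  The *dynamic-parameter impact* is defined here as the parametric share of
  the factor-sum spread,
  $\sum_{\text{parametric}} q_i (a^{max}_i - a^{min}_i) \big/ \sum_{\text{all}} q_i (a^{max}_i - a^{min}_i) \times 100$.
  This is one plausible operationalization of an under-specified published
  statistic; the definition string travels with every result so numbers are
  never compared across definitions unknowingly.
* **Scenario pooling**: the technique criterion has two levels (belt /
  no belt) while recordings have three scenarios; the two beltless
  scenarios pool into `no_belt` (`technique_level()`), and the default
  subject exposure mix is 2/3 no-belt, 1/3 belt, matching the recording
  design. Both are configurable.
* **Degenerate inputs**: a single-criterion table is legal ($q = 1$);
  both-zero side moments are a degenerate-input error; duplicate study ages
  make the quadratic fit rank-deficient and error out; age below 0 is an
  error while age outside the calibrated range only warns (the model
  extrapolates freely, as its source does).

## Known limitations

* The criteria weights and likelihoods ship as published configuration;
  they are demonstrative, not validated effect estimates.
* Cohort-level headline statistics (cohort means, sex gaps, extreme-scenario
  brackets) depend on the original study's raw motion recordings, which are
  not distributed; the package reproduces the model mechanics and printed
  table anchors, not those aggregates.
* The baseline curves are cross-sectional prevalence, not longitudinal
  hazard; the time shift is a prevalence extrapolation, not survival
  analysis.
* No inverse dynamics: joint moments must be supplied (or synthesized); the
  upstream musculoskeletal model that produced them is out of scope.
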