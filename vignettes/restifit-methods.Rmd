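---
title: "Methods: piecewise kinetic models and feature-based analysis of organoid restitution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piecewise kinetic models and feature-based analysis of organoid restitution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restifit)
```

## The modeling problem

After single-cell photodamage in a gastric organoid, three quantities are
tracked over time: the GFP-actin signal of the cells neighboring the wound
(RLU, baseline-normalized), the damaged area (µm²), and the distance of the
dead cell's nucleus from the damage site (µm). Organoids are heterogeneous,
so trajectories cannot be averaged naively; instead each organoid is reduced
to a vector of 13 kinetic features by fitting simple hybrid models — linear
ODEs whose rate constants are switched on and off by discrete timing events.
The feature vectors are then the unit of all downstream statistics.

The central assumption is independence: each channel is modeled as its own
first-order process. Nothing mechanistic couples actin to repair or
exfoliation inside the models — any association between the processes is
left for the downstream machine-learning stage to discover from the fitted
features. A second assumption is that one damage-repair cycle contains
exactly one actin minimum and one actin peak, and one detachment event; cells
that do not show this structure at the sampling resolution are flagged as
non-conforming and excluded rather than forced through the model.

## Sub-models and closed forms

Every regime of every sub-model is a linear relaxation toward an attractor,
so the piecewise solution is a chain of exponentials, continuous at the
switch times:

* Actin: decay from the baseline `act0` toward `act_min` at rate
  `act_depoly1` until `t_min`; saturating rise toward the *theoretical*
  ceiling `act_max` at rate `act_poly` until `t_max`; relaxation to the
  steady state `act_ss` at rate `act_depoly2` afterwards. `act_max` is an
  attractor, not an observed level — the fitted value generally exceeds the
  observed peak because the rise is cut off at `t_max`.
* Damaged area: `DA(t) = da0 · exp(−k_repair t)`.
* Dead-cell distance: linear drift `dcd0 + k_stay·t` until `t_detach`, then
  relaxation toward the fixed point `dcd_max + k_stay/k_run` at rate
  `k_run`. When `k_run = 0` the post-detachment regime degenerates; the
  implementation returns the continued linear drift instead of dividing by
  zero.

The switching is exact (hard events), not smoothed: the closed forms anchor
each regime at the previous regime's terminal value, and the numerical
cross-check (`integrate_numerically()`, built on `deSolve::lsoda` at
`rtol = 1e-10`) restarts integration at every event time. The test suite
holds the two routes to within `1e-6` absolute over randomized parameter
draws; in practice they agree to about `1e-8`.

One dimensional note: the equations use `k_repair` and `k_run` as
first-order rates (1/min), while the conventional reporting units are
µm²·min⁻¹ and µm·min⁻¹. The package computes with the equations' dimensional
logic and echoes the reporting units in the units sidecar
(`write_units_sidecar()`).

## Feature extraction and fitting

Timing and level features are read directly from the data
(`extract_timing_features()`): the peak is the global maximum, the minimum
is the global minimum among samples before the peak, ties break to the
earliest time, and `act_ss` is the mean of the last 3 samples (window
configurable). These features are therefore resolved only to the sampling
interval — a `dt`-wide uncertainty that is inherent to direct extraction,
not to the optimizer.

`t_detach` is not directly visible, so it is located by an exhaustive
two-segment changepoint search (`detect_detachment()`): for every candidate
breakpoint on the observed grid, a straight line is fitted before and a
saturating exponential after, and the candidate minimizing the summed
squared error wins. An optimum on the first or last admissible candidate
raises a boundary flag (e.g. a cell that never detaches). The search is
deterministic and oracle-checkable, which is why it was chosen over
heuristic curvature detectors.

Rate constants are fitted per regime by least squares on the closed-form
segment solutions, using an in-package differential-evolution optimizer
(`de_optimize()`, DE/rand/1/bin, population 30, up to 300 generations,
F = 0.8, CR = 0.9, seed 42 by default, early stop when the population's
objective spread falls below `1e-10`). Bounds are `[0, 50]` min⁻¹ for rates
and `[peak, 5 × peak]` for `act_max`. Because the best member is never
discarded, the returned objective can only improve on the initial
population. Determinism is part of the contract: the optimizer runs in a
private RNG scope, so identical inputs and configuration give bit-identical
feature vectors.

Two numerical choices matter here:

* **Variable projection.** For a fixed rate the segment model
  `offset + C·exp(−k(t − t₀))` is linear in `offset` and `C`, so those are
  solved exactly inside the objective and the evolutionary search is one- or
  two-dimensional. This is faster and much better conditioned than searching
  all coefficients jointly.
* **Interior samples only.** Each regime is fitted on the samples strictly
  between the extrema, not including them. The extremum sample sits up to
  one grid step away from the true switch time and is the most contaminated
  by the neighboring regime; anchoring the segment solution there measurably
  biases the rates (about 1–5% on a noiseless 0.1-min grid), while
  interior-sample fitting with a free offset recovers them to better than
  `1e-5` relative. The extracted `act_min`/`act_ss` levels are still
  reported from the data directly.

Degenerate segments collapse explicitly: when the zero-rate (flat) model
explains a segment at least as well as the fitted exponential, the rate is
reported as exactly 0 rather than an arbitrary unidentifiable value. A
segment with fewer than two interior points yields `NA` plus a flag, and any
sub-model failure flags the organoid without aborting the cohort
(`fit_cell()` / `fit_cohort()`).

As an optimizer-independence check, `k_repair` has a closed-form competitor:
the log-linear regression slope (`loglinear_repair_rate()`). On noiseless
data the evolutionary estimate matches it to `1e-4`.

## Synthetic cohorts

`generate_cohort()` emulates the statistical structure the analysis assumes:
per-organoid parameters drawn independently around the control reference
statistics (`control_reference()`), multiplicative treatment effects on
configured target parameters, optional linear coupling of the behavior
parameters to `t_max`, and additive Gaussian observation noise per channel,
with area and distance clipped at zero. The published summary gives only
mean ± SD per parameter, not a distributional family; we use a normal
truncated at a small positive floor for transparency (a moment-matched
lognormal is available for strictly positive rates). Internal consistency is
enforced at draw time: `t_min` is drawn below `t_max`, `act_min` below the
baseline, and `act_min ≤ act_ss ≤ act_max`.

Defaults, chosen once as field-realistic: grid 0–20 min at `dt = 0.5`
(covering the full three-stage actin response at control-typical timing,
with the tail long enough for `act_ss` and the dead-cell plateau), `act0 =
1` RLU (baseline-normalized fluorescence), `da0 = 100` µm², `dcd0 = 0`, and
noise sd 0.05 RLU / 2 µm² / 0.2 µm — a few percent of each channel's dynamic
range. Treatment presets (`treatment_presets()`) encode qualitative drug
directions (the myosin-inhibitor pair acting on `k_stay` and `t_detach` at
two strengths, a Rac1 inhibitor boosting `k_repair`, a Cdc42 inhibitor
slowing repair and delaying the actin peak) with illustrative magnitudes.

The coupling device (`coupling_spec()`) overwrites each selected behavior
parameter with `intercept + slope·t_max + ε`; the residual sd is
`|slope|·sd(t_max)/snr`, so `snr = 3` plants a 3:1 signal. Note the corollary:
a zero slope makes the coupled response exactly deterministic. Coupling is a
*generative testing device* — it lets the forest stage be validated against a
known planted signal — not a claim about mechanism.

What the generator deliberately does not emulate: photobleaching and imaging
drift, non-Gaussian or heteroscedastic measurement error, correlations
between parameters other than the configured coupling, missing frames, and
multi-cell damage. Passing recovery tests on synthetic cohorts therefore
demonstrates the estimator's correctness under the model's own assumptions,
not robustness to every artifact of real microscopy. Under full
between-organoid heterogeneity, roughly a quarter of simulated cells have
`t_min` or the initial decay time constant below the 0.5-min sampling
interval; these are genuinely unresolvable at that cadence and exit through
the non-conforming flag, mirroring how fast events are lost in real imaging.

## Downstream analyses

*Percent change and chord edges.* Group aggregation uses means of the
per-organoid fitted features (configurable to medians); missing values are
excluded pairwise. "Strongest effect" is the most positive and the most
negative *signed* percent change; ties resolve deterministically to the
first feature/drug in column order. Each drug and each parameter therefore
contributes one or two edges.

*PCA.* All 13 features are standardized and decomposed with
`stats::prcomp`; constant columns are dropped with a warning. The loadings
matrix is orthonormal, and explained variance ratios are non-increasing and
sum to one.

*Random forest.* The eight actin features predict each of the five behavior
features on a pooled (treatments + controls) cohort, with a seeded 75/25
train/validation split and a 100-tree `randomForest` at default `mtry`.
Hyperparameters are pinned rather than left to library defaults so results
are reproducible across versions. Importance is the impurity-decrease (Gini)
measure, rescaled so the top predictor reads 100; R² is reported on both
splits. The planted-signal test is the package's testable surrogate for
real-data forest claims: with behavior features coupled to `t_max` at 3:1
signal-to-noise (n = 150 per group), the forest must reach R² ≥ 0.8 in
training and ≥ 0.3 in validation and rank `t_max` at importance 100 for
every coupled response. The forest analysis runs on feature tables; in the
acceptance setting it consumes the generator's ground-truth table, since the
planted coupling lives in the features themselves and re-fitting would only
add estimation noise.

## Problem sizes and tolerances used in validation

The validation suite fits noiseless zero-variance cohorts (n = 3, grid
0–20 min at `dt = 0.1`) and requires every one of the 13 features back
within max(1%, one grid step); a heterogeneous noiseless cohort (n = 60,
same grid) must recover group means within twice the standard error plus one
grid step for timing features. Monte-Carlo noise calibrations use 50
replicates: at 0.05 RLU actin noise the median relative error of
`act_depoly2` stays below 10% (measured ≈ 5%), and at 0.2 µm distance noise
the detachment time is located within two grid steps in median. Oracle
equivalence is checked on 100 random draws per sub-model at `1e-6`.

## Known limitations

* Timing features are grid-quantized; sub-interval event times cannot be
  recovered by design.
* The three channels are fitted independently; no information is shared, so
  a corrupted channel degrades only its own features but cannot be rescued
  by the others.
* The changepoint search assumes exactly one detachment; staged or reversed
  detachment is flagged at best.
* Percent-change edges carry no significance testing — they are descriptive
  summaries of group means.
* `act_max` is identified only through the rise segment's curvature; for
  nearly linear rises (rate near zero) it is weakly determined and bounded
  by the configured ceiling.
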