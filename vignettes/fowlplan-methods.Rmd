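---
title: "fowlplan: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fowlplan: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fowlplan)
```

## Overview

`fowlplan` is a decision-support tool for steering a cage of native chickens
to a target live weight by a target date. Two regressors are trained on
daily cage records: a **daily live-weight model** on the 7-feature vector
(age; 24-h mean temperature and relative humidity; per-bird feed allowance;
24-h maxima of CO, H₂S, NH₃) and an **interval total-feed model** on
(start weight, target weight, remaining days). A closed loop allocates the
forecast feed total across days, constrains it operationally, simulates the
weight trajectory and corrects the total proportionally until the simulated
terminal weight lands within tolerance of the target.

This vignette records the modelling assumptions, the defaults that matter,
and the choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The synthetic world

No farm dataset ships with the package; a seeded generator emulates the
statistical structure of a small cage trial so every stage is testable.

* **Growth.** Cage-mean weight follows a Gompertz curve
  $W(t) = A\,e^{-b e^{-kt}}$ with additive Gaussian cage-level observation
  noise. The Gompertz form is the standard parametric choice for poultry
  growth; the generator makes no claim that real birds follow it exactly —
  it supplies a smooth, saturating, strictly increasing truth that tree
  ensembles should recover. Breed presets: Guzao $A = 2600$ g, Huangjin
  $A = 3000$ g, Red Junglefowl $A = 3300$ g with doubled noise (faster
  growth and more within-breed variability); $b = 4.2$ puts hatch weight
  near $A e^{-b} \approx 39$–50 g, and $k \approx 0.036$ d⁻¹ reaches
  market-class weights at 11–15 weeks. All overridable.
* **Scale.** Defaults are 3 batches × 77 rearing days per breed, i.e. 231
  daily cage-level records per breed, with one 4-bird cage per breed per
  batch. The trial the package emulates reports 231 records per breed
  without stating their batch composition; 3 × 77 is this artifact's
  emulation choice and is configurable.
* **Environment.** Temperature and RH are sinusoidal daily cycles with
  jitter. Each gas trace is a positive daily cycle rescaled so the per-day
  maximum equals a uniform draw from a configured range (defaults: NH₃
  maxima 0.3–4.0 ppm, H₂S 0.2–4.5 ppm, CO near zero). Those per-day max
  ranges are the only distributional facts stated about the source
  environment, so the generator reproduces exactly them and invents as
  little else as possible.
* **Intake.** Per-bird intake ramps monotonically (default 57 → 145 g/day),
  rescaled so the whole-period FCR equals `fcr_target` (default 3.3, the
  mid-range of reported native-chicken grower FCRs). Initial cage weights
  are drawn within ±4 % of the curve so replicate cages start within the
  ±5 % assignment check used in practice.
* **What a green test does not establish.** The generator has no disease,
  mortality, sex effects, behaviour, seasonal drift, sensor failure or
  between-cage heterogeneity beyond noise. Recovery of the synthetic truth
  shows the pipeline is correct, not that the models generalize to real
  farms.

## Preprocessing and leakage control

* Age is integer days since batch start (day 0 = batch start).
* Environmental summaries aggregate the half-open window
  $(t - 24\,\mathrm{h},\, t]$ ending at the fixed morning weighing
  (default 08:00; the source protocol fixes a morning weighing but not the
  clock time of the cut). An empty window yields a missing summary that is
  mean-imputed later.
* Imputation (training mean / mode) and min–max scaling
  $z = (x - x_{\min}) / (x_{\max} - x_{\min} + \varepsilon)$ are fitted on
  training rows only. $\varepsilon = 10^{-8}$ (the source only says "small
  positive constant"); it also makes constant features map to 0 instead of
  dividing by zero. A z-score variant is provided because the feedforward
  net standardizes by training moments; min–max is the default elsewhere.
* The 9:1 temporal split takes the last $\lceil 0.1\,n \rceil$ records of
  each batch; this per-batch ceiling rule is what reproduces 207/24 on
  231 records. Blocked CV cuts each batch into $k$ contiguous temporal
  blocks; repeats shift the interior cut points by a seed-derived offset so
  validation blocks stay contiguous (no shuffled folds, no leakage from
  adjacent days).
* Interval training pairs for the total-feed model are all within-cage day
  pairs $(s, e)$ with length in a configured band (default 7–60 days,
  stride configurable), target $\sum_{i \in (s, e]} f_i$; how the original
  model's training pairs were formed is unstated, so this construction is
  the artifact's own. Pairs with non-increasing weight are skipped and
  counted.

## Learners

The regressor contract (`train_regressor`, `predict`, seed-deterministic)
is the interface; the learner families ship in-package because the target
environment provides no tree-ensemble or neural-network library:

* **extra-trees** (default): full-sample trees, every candidate feature
  gets one uniform random threshold, best variance reduction wins. Preset:
  300 trees, depth 6, min split 2.
* **random-forest**: bootstrap + exhaustive best-split search. Preset 300 /
  6 / 5.
* **gradient-boosting**: stagewise trees on residuals with shrinkage.
  Preset 600 trees, depth 6, learning rate 0.05.
* **feedforward-net**: 64–32 ReLU MLP, Adam (η = 0.001), L2 λ = 0.001,
  batch 32, up to 2000 epochs with early stopping (patience 20, tol 1e-4)
  on a random 10 % validation split. Dropout and batch normalization are
  omitted: no rate is specified anywhere, and with ~200-row training sets
  L2 + early stopping is the conventional regularizer.

In-sample metrics on smooth monotone cage trajectories are near-perfect
(R² ≈ 0.999) for tree ensembles — they memorize the curve. That mirrors the
reporting convention of the source trial and should be read with the same
caution: the temporal test tail measures extrapolation, where depth-bounded
trees saturate at the largest trained leaf and R² collapses. The pipeline
reports both scopes side by side rather than hiding either.

## Attribution

`mc_shapley` estimates Shapley values by permutation sampling. The value
function is the interventional expectation over the full background set:
at each step of a sampled permutation the explained row's features replace
the background columns and the model prediction is averaged over all
background rows. Consequences: per-permutation contributions telescope, so
local accuracy ($\sum_j \phi_j = f(x) - \bar f_{bg}$) holds exactly at any
permutation count, and the only Monte-Carlo error is over permutations —
which is what makes the 1 % agreement with an exhaustive subset-enumeration
oracle achievable at ~2000 permutations for $p \le 3$–4. The environmental
analysis fits extra-trees models on exactly the 5 environmental features per
breed and averages the per-breed summaries ("breed-balanced" mean). The IQR
reported is across explained samples of the absolute per-sample values; the
source table does not state its convention, so this assumption is
documented rather than claimed.

## The scheduler

Defaults (all configurable): tolerance ε = 10 g, J_max = 20 (named but not
valued in the source; 10 g is well under daily gain, 20 iterations is ~3×
what the contraction needs), daily ration bounds 10–250 g, ±10 % day-to-day
band (stated operationally), daily-gain clip band 0–80 g/day ("a reasonable
band", unquantified; 80 g/day is above any observed native-chicken daily
gain, so the clip only removes model artifacts).

Open points resolved as package design choices:

* **Constraint enforcement** (source silent): alternating projection —
  clip to bounds, forward/backward passes clipping relative steps into the
  band, rescale to restore the total; ≤ 50 rounds or error naming the
  binding constraint. Feasibility requires
  `daily_min·n ≤ F_r ≤ daily_max·n`. The operator is idempotent and
  conserves the interval total to 1e-6 relative.
* **Reallocation after the proportional update**: every day is multiplied
  by the same factor, then constraints re-enforced — allocation shape is
  preserved whenever constraints are inactive.
* **Unreachable targets**: the proportional update is clamped into the
  feasible total range, so the loop parks at the bound and returns its best
  iterate with `converged = FALSE` instead of erroring.
* **Environmental forecast** for future days: climatology — the mean of
  the trailing 7 observed days per variable; a user-supplied forecast table
  overrides.
* **Gain clipping feeds forward**: each day's clipped weight is the anchor
  for the next day's gain (the alternative — clipping against raw model
  outputs — is available by disabling the band, which returns raw
  predictions).
* **Arithmetic profile** default: first term a = 1 with the common
  difference chosen so the last raw term is twice the first; only the shape
  matters because the sequence is rescaled to the interval total.

Convergence: for a strictly increasing terminal response with a root in the
feasible range the update is a contraction near the fixed point (for
$w_{end} = w_0 + c\sqrt{F}$ the factor is $(w_{target} + w_0) / (2
w_{target}) < 1$), and the tests verify convergence within J_max = 20 at
ε = 10 g over an order of magnitude of response slopes, against an
independent fixed-point oracle.

## Economics

`partial_budget` computes ΔFeed = ΔFCR · W_g · N and Saving = ΔFeed · P_f at
full precision; display rounding (feed 2 dp; money 1 dp below 1000,
integer part above) is separate and never feeds back. Two conventions are
worth noting. First, the published commercial-scale illustration prints an
intermediate ΔFeed of 225.7 kg whose own inputs multiply to 255.75 kg — the
adjacent monetary value (3580 NTD) matches the correct product, so the
package computes the product and does not reproduce the misprint. Second,
the headline FCR reduction (4.39 %) only arises from the 2-decimal-rounded
FCRs (0.15 / 3.42); `fcr_contrast` reports that convention as the headline
and stores the full-precision reduction (4.35 %) alongside.

## Numerical notes and limitations

* All randomness flows through per-operation seeds (split deterministically
  into sub-streams); identical seeds give byte-identical output tables.
* `allocate_profile` makes the last day absorb the floating-point residual
  so interval totals are exact, not just close.
* R² against zero-variance observations is reported `NA` with a warning,
  never ±∞.
* Model artifacts serialize to versioned JSON (trees as arrays, net weights
  as matrices) — text-only, no binary formats.
* Known limitations: no mortality/sex/disease modelling; the scheduler is
  an offline decision-support tool, not a real-time controller; nutrient
  composition is fixed (only the daily quantity is scheduled); published
  per-breed accuracy tables from the unreleased farm data are not
  reproducible and are not claimed.
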