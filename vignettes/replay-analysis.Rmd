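---
title: "Inferring time-compressed forward memory replay from temporal-order-judgement latencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring time-compressed forward memory replay from temporal-order-judgement latencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tojreplay)
```

## The problem

In a temporal-order-judgement (TOJ) experiment a subject watches a short
naturalistic video composed of two concatenated clips (an event boundary in
the middle), waits through a retention delay, and then picks which of two
probe frames appeared earlier. If the subject answers by *replaying* the
encoded episode serially from its start, reaction time (RT) should grow
with the video position of the frame it ultimately selects; the slope of
that growth measures the speed of replay relative to perception. `tojreplay`
implements the full latency-analysis pipeline for such experiments: a
LATER rise-to-threshold account of the latency distributions, a
representational-similarity analysis (RSA) that pits replay models against
each other, reciprocal-latency regressions, and the derived summary
statistics — all driven, when no real data are supplied, by a synthetic
trial generator that reproduces the factorial task design.

## The trial data model

A trial table (`trial_table()`) stores one row per TOJ trial: the video
geometry (duration 8–12 s, 25 frames/s, boundary frame where Clip 2
begins), the two probe frames, the chosen frame, correctness, RT, and the
design factors — Boundary (within/across context), Play order, Temporal
distance (TD; 25 levels from 25 frames = 1000 ms rising in 3-frame steps
to 97 frames = 3880 ms), and Exposure. Frame indices are 0-based
internally; `load_trials()`/`write_trials()` accept a `one_based` flag
because ordinal frame numbering is common in published materials.

Two derived quantities recur downstream:

* **Chosen-frame location** is normalized to `[0, 1]` as
  `chosen_frame / (n_frames - 1)` so regression slopes are comparable
  across videos of different length. Raw-frame units would be an equally
  defensible choice; normalization is ours, made once.
* **Temporal similarity** `TS = delay2 / delay1` is the ratio of the two
  probes' retention intervals at the moment of testing (test clock
  defaults to video end + 2 s retention delay). TS lies in (0, 1); values
  near 1 mean nearly equally old traces, hence harder discrimination.

`filter_rt()` excludes implausible latencies outside `[0.7, 10]` s. The
bounds are read as a closed interval — an RT of exactly 0.7 s or 10 s is
retained — and both exclusion fractions are logged on the table.

## The synthetic generator

`build_design()` lays out the factorial design exactly: each session holds
one full Boundary × Play-order × TD crossing (100 trials), exposures are
blocked over sessions, and the defaults give the macaque-style 50 sessions
× 100 trials = 5000 trials per subject (20 sessions × 2 exposures = 2000
for the human-style variant). Clip lengths are drawn uniformly from 4–6 s;
probe frames are placed uniformly subject to the TD separation and the
boundary condition, and infeasible placements raise an error naming the
trial.

`generate_dataset()` adds choices and latencies:

* **Latency.** The mean RT for a chosen frame at video time *t* is
  `t0 + scan_rate * t + replay_offset * [frame in Clip 2]`. The observed
  RT is the reciprocal of a Gaussian *promptness* draw centred on
  `1/mean_rt`, truncated below at 0.05 s⁻¹ (capping RT at 20 s) with
  resampling; the truncation distorts only a tail that the RT filter
  removes anyway. Defaults: `t0 = 0.9` s (a plausible non-replay base
  latency), `scan_rate = 0.0942` s per video-second (the replay speed the
  method itself estimates on real macaque data, compression ≈ 10.6),
  `promptness_sd = 0.15` s⁻¹ (latency CV in the 15–25% range typical of
  trained-animal RT data), `replay_offset = 0` (strict forward replay; a
  negative offset equal to minus the scanned Clip 1 duration reproduces a
  full global-compression reset).
* **Context effect.** Across-context trials perturb the promptness
  distribution either as a *shift* (`+0.1` s⁻¹ on the mean — a
  rate-of-rise gain, the effect the LATER comparison should attribute to
  the shift variant) or as a *swivel* (mean and SD scaled jointly by 1.2,
  preserving their ratio), selectable via `context_mode`.
* **Choice.** `P(correct) = clamp(plogis(c0 + c1 (1 - TS) + c2 across),
  0.5, 1)` with defaults `c0 = 0, c1 = 2.5, c2 = 0.5`, chosen once to land
  in the high-60s-percent overall accuracy regime of trained macaques.
  This is declared synthetic scaffolding — the analysis makes no claim
  about the animals' choice process — but it reproduces the qualitative
  pattern (better accuracy at low TS and on across-context trials, never
  below chance).

What the generator deliberately does *not* emulate: real videos' content
(category is carried as an inert factor), sequential dependencies between
trials, session-level drift, and the idiosyncratic mean boundary position
of any particular stimulus set. Tests passing on synthetic data therefore
demonstrate that the estimators recover what the generative model encodes,
not that any particular animal behaves this way.

## LATER fitting and the shift/swivel comparison

Under LATER, a decision signal rises linearly from start level to a
threshold at distance θ, at a rate drawn per trial from Normal(μ, σ₁);
latency is θ/rate, so promptness 1/RT is Gaussian with mean `m = μ/θ` and
SD `s = σ₁/θ`. The likelihood depends on (m, s) only; reported (μ, θ) use
the convention σ₁ = 1. We fit raw single-trial promptness by maximum
likelihood (not grouped quantiles — the stronger contract), on the
promptness scale throughout; since every variant is compared on the same
scale, no Jacobian to the RT scale is needed.

Four variants constrain the two conditions' (m, s):

| variant | constraint | free parameters |
|---|---|---|
| null | shared (m, s) | 2 |
| shift | shared s, free m | 3 |
| swivel | shared m/s, free s | 3 |
| two fits | all free | 4 |

The shift variant translates the reciprobit line; the swivel variant
pivots it about the infinite-time intercept, which is why its constraint
is formalized as a shared m/s ratio. `null` and `two_fits` have closed-form
MLEs; `shift` and `swivel` are maximized numerically (Nelder–Mead from the
two-fits solution, relative function tolerance 1e-8, at most 10⁴
iterations), and a closed-form pooled-variance solution for the shift case
serves as an independent oracle in the tests. `compare_bic()` applies
`BIC = -2 logL + k log(n)` with n the total observation count, and labels
ΔBIC > 2 as positive, ΔBIC > 6 as strong evidence. Only the main latency
component is modelled — no express/early second component.

In simulation (100 seeded runs per generator, 1000 trials/condition — a
size chosen to match a realistic per-condition trial yield), the shift
generator is preferred over swivel with ΔBIC > 6 in ≥ 90% of runs, the
swivel generator symmetrically, and null data selects the null variant.

## RSA: which replay model does the RT pattern match?

Within-context trials are binned into 8 equal segments by chosen-frame
location (10 and 14 segments as robustness variants) and mean RT is taken
per segment. The pairwise dissimilarity of two segments is the absolute
difference of their scalar mean RTs — "Euclidean distance" of scalars;
off-diagonal entries are rank-transformed (average ranks on ties) over the
upper triangle and linearly scaled to [0, 1]. A completely flat profile
makes every distance tie; that degenerate case maps to all-0.5 with a flag
rather than dividing by zero.

Hypothetical replay models are lines in segment index with a step at the
first Clip-2 segment: `model_rt_pattern(offset)`, with the offset in
slope-units. `offset = 0` is strict forward replay; `offset = -(boundary
segment - 1)` restarts Clip 2 at the origin — full global compression.
`offset_model_family()` builds the 11-model grid from −4 to +4 in 0.8
steps (the grid endpoints are ours; the published figure shows but does
not tabulate its offsets), with the strict-forward model at position 6.

`spearman_model_fit()` correlates data and model RDMs (Spearman, upper
triangle) under a bootstrap: trials resampled with replacement within each
subject, per-subject RDMs rebuilt and averaged, 100 iterations;
`compare_models()` contrasts two models' iteration vectors with a
two-sided Wilcoxon signed-rank test, Benjamini–Hochberg-corrected across
the comparison set (the standard step-up procedure, including its
monotonicity step). Subject-level resampling is available for larger
cohorts.

Two structural facts matter when reading the offset sweep:

* Because both the data RDM and the model RDMs are rank-scaled, the
  comparison is invariant to positive affine rescalings of the segment
  means (units and baselines cancel). It is *not* invariant to arbitrary
  monotone transforms — a convex transform can reorder pairwise
  distances — which is the correct behavior for a distance-rank method.
* Once a positive offset exceeds the within-clip distance range, every
  cross-clip distance outranks every within-clip one and the rank-scaled
  RDM stops changing: the outer positive-offset models (9–11 on the
  default grid) are *identical matrices*. Correlation against the family
  therefore rises to an asymptote around offset 0 and is flat beyond it.
  Offset-recovery statements consequently treat the argmax as a tie set:
  a generating offset counts as recovered when it, or a grid neighbour,
  attains the maximal correlation (exact ties resolved at 1e-12). In 20
  seeded sweeps across all 11 generating offsets (5000 trials each) the
  generating model is recovered in this sense in over 90% of runs.

## Regressions and trend tests

`reciprocal_latency_glm()` fits promptness (1/RT) with a Gaussian-family,
identity-link least-squares model. We read "Gaussian link" as the
canonical identity link of the Gaussian family; a log-RT outcome replicates
the sign pattern and is available by transforming the table. Continuous
regressors are z-scored and two-level factors coded ±0.5, so coefficients
are comparable standardized effect sizes. `slope_test()` produces the
per-subject coefficient table (all trials, correct-only, incorrect-only;
splits under 30 trials are flagged, not fitted), reported without
multiplicity correction as is conventional for per-subject tables.
`polynomial_trend_test()` uses an orthogonal polynomial basis so each
degree's incremental t-test is well-defined given the lower degrees —
with a raw power basis the answer would depend on entry order.

## Derived behavioral statistics

* `compression_factor()`: from an RT span Δ between the first and last
  frame of a video of duration D, replay scans `1000 Δ / D` ms per second
  of video and the compression factor is `D / Δ` (> 1 means replay is
  faster than perception). The nominal duration defaults to the design
  mean of 10 s; the empirical mean is available via the table.
* `clip_rt_contrast()`: per-subject mean RT for Clip-1 vs Clip-2 chosen
  frames, one-tailed paired t (Clip 1 faster), Cohen's d, and the log-RT
  variant.
* `trial_type_anova()`: one-way ANOVA on subject × trial-type mean RTs in
  the between-cells layout (6 subjects give F(2, 15)).
* `inverse_efficiency()`: mean RT in ms divided by percent correct on the
  0–100 scale, per target-location segment (4 segments = 2 per clip; 6
  subjects give F(3, 20)); zero-accuracy segments are flagged undefined.
* `sliding_accuracy()`: windowed accuracy (by target frame) and
  reciprocal RT (by chosen frame); default window 25 frames ≈ 1 s with
  1-frame step (the window is our choice); empty windows stay as gaps.

## Perceptual similarity

For across-context analyses the package scores image-pair similarity
three ways: an RGB-histogram sum of squared differences over 256 intensity
bins per channel (position-invariant; 0 for identical images), a HOG
correlation (magnitude-weighted gradient-orientation histograms over
16-px cells, 8 unsigned orientation bins — both defaults ours), and a
pluggable keypoint-descriptor distance. The keypoint stage is an
interface: any detector returning descriptors can back it. The built-in
backend (`patch_descriptor_backend()`) is a Harris-corner detector with
normalized grayscale patch descriptors — deliberately simple,
photometrically tolerant but not scale- or rotation-invariant, and clearly
not a SURF implementation; matching is nearest-neighbour Euclidean in both
directions so the score is symmetric.

## Numerical choices and degenerate inputs

* Promptness truncation at 0.05 s⁻¹ with resampling keeps the generative
  marginal close to Gaussian while guaranteeing finite positive RTs.
* Optimizer: derivative-free simplex, reltol 1e-8, max 10⁴ iterations;
  non-convergence is an error naming the variant, never a silent result.
* Ties: RDM ranks use average ranks; reciprobit ties collapse to one
  point with pooled mass at Hazen positions `(i - 0.5)/n`.
* Degenerate inputs error loudly: equal probe frames, zero promptness
  variance, empty RSA segments (with the advice to reduce the segment
  count), all-zero Wilcoxon differences (p = 1 by convention).

## Problem sizes used by the checks

The simulation studies shipped with the package use 100 seeded runs at
1000 trials/condition for the LATER recovery study, 20 seeded sweeps of
11 × 5000-trial datasets for offset recovery, and 6-subject × 1000-trial
cohorts for the group-level slope, contrast and bootstrap-RSA checks —
sizes at which each property is comfortably resolvable and a full run
stays in the tens of seconds.

## Limitations

The package analyses latencies; it does not model the choice process
beyond the synthetic scaffolding, does not fit two-boundary
drift-diffusion models, and the RSA cannot distinguish replay models on
the rank-degenerate part of the offset grid (a property of the method,
not of the implementation). Group inferences assume subjects are
exchangeable; mixed-effects extensions are out of scope.
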