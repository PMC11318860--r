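---
title: "Decoding music-evoked chills from pre-listening auditory-reward connectivity: methods and design"
author: "chillconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding music-evoked chills from pre-listening auditory-reward connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chillconn)
```

## The scientific question

Musical "chills" — the shiver-down-the-spine peak-pleasure response — vary
enormously between listeners. chillconn implements an analysis that asks
whether the brain state *immediately before* music starts already predicts
how much of a chills response a listener will go on to report: short
(~40 s) pre-listening resting-state functional connectivity (RSFC) between
the auditory cortical system and the reward system is used to decode the
subsequently reported duration of chills, as well as their physiological
(phasic skin conductance) and neural (region-wise BOLD) intensity.

The pipeline has five stages:

1. **Behavioural targets.** Online button presses (neutral / pleasure /
   chill / tear) are cleaned — presses shorter than 1 s are discarded as
   mis-presses, consecutive same-label presses are concatenated into one
   sustained response — and per-label durations are totalled per trial,
   then averaged over a participant's trials.
2. **Connectivity features.** Each pre-listening rest epoch is detrended,
   band-pass filtered (0.008–0.09 Hz), and summarised as a partial
   correlation matrix over all ROIs (the correlation between two ROIs
   after adjusting for every other ROI), Fisher z-transformed, and
   averaged over trials. Feature sets are edge selections from this
   matrix: the 12 auditory × 8 reward = 96 cross-network edges for the
   headline model, C(10,2) = 45 within-hemisphere edges for the asymmetry
   model, or the full 288-ROI upper triangle (41,328 edges).
3. **Decoding.** A LASSO regression with nested leave-one-out
   cross-validation: an inner leave-one-out loop over the training units
   scores each penalty λ ∈ {0.001, 0.01, 0.1, 1, 10, 100, 1000} by the
   Pearson correlation between inner held-out predictions and actual
   targets; the winning λ is refit on the full training set to predict the
   held-out unit. Accuracy is the correlation between held-out predictions
   and actual targets across units.
4. **Inference.** Exact correlation tests (the t/beta form), permutation
   tests that re-run the *entire* nested cross-validation on permuted
   targets, Benjamini–Hochberg FDR across network pairs, and bootstrap
   comparison of dependent prediction accuracies.
5. **Generalisation.** The λ selected by leave-one-out over the whole
   first cohort is refit on all its units; the frozen weight vector plus
   its training scaler transfers to an independent cohort by a dot
   product with that cohort's features. The exact correlation test's
   inverse gives the minimal cohort size that could replicate an observed
   accuracy (r = 0.53 → n = 11 one-sided at α = .05; the critical r at
   n = 11 is 0.52).

## The partial-correlation estimator

With 40 s of TR = 2 s data a rest epoch has 20 volumes, while the
parcellation has 288 ROIs: the textbook "adjust for all other ROIs"
partial correlation (negated scaled precision) does not exist because the
sample covariance is singular. We therefore invert a shrinkage-regularised
covariance `(1 − ρ) S + ρ m I` (m = mean variance), with ρ estimated by
the Ledoit–Wolf formula. Two details matter:

* **The coefficient is pooled.** ρ is estimated per trial and the cohort
  *median* is applied to every trial (`shrinkage = "pooled"`). A per-trial
  coefficient adapts to each trial's covariance dispersion; because any
  condition-dependent covariance structure changes that dispersion, a
  per-trial ρ rescales *all* edges in a way that carries target
  information into otherwise unrelated edges. We observed exactly this
  failure mode in simulation: with per-trial ρ, network pairs with no
  planted signal decoded the target. A pooled coefficient keeps the
  feature map identical across units. An explicit numeric ρ (including 0
  for large-n oracle checks) remains available everywhere.
* **Edges are selected after inversion.** Partial correlations are always
  computed from the full-parcellation precision matrix and edge sets are
  sliced out afterwards, so an edge's value does not depend on which
  feature set it is reported in. `participantZMatrices()` caches the
  averaged per-participant z-matrix so the 78 network-pair analyses share
  one inversion per trial.

## The synthetic cohort generator

No raw recordings ship with the package; `simulateCohort()` generates
cohorts with the statistical structure the analysis assumes, so every
claim the test suite makes is checked against a known ground truth.

* **Study conditions.** Defaults mirror the emulated design: 38
  participants × 8 trials, TR = 2 s, 40-s pre-listening rest epochs,
  270-s music epochs, 13 networks with 12 auditory (6 per hemisphere) and
  8 reward ROIs, physiological traces at 100 Hz (the original polygraph
  rate of 1,000 Hz adds nothing at desk scale).
* **Planted coupling.** Each participant carries a latent coupling score
  c ~ N(0, 1), jittered per trial (SD 0.3). Rest epochs are multivariate
  normal draws whose auditory↔reward cross-edge correlations are
  0.1 × (1 + c), clipped to the largest uniform cross-block correlation
  the within-network structure (r = 0.3) supports, so the covariance
  stays positive definite at any c. Cross-network correlations are
  otherwise 0: a dense cross-network base would let the planted
  perturbation leak into every network pair's partial correlations
  through the precision matrix, and the localisation the decoding
  analysis is supposed to demonstrate would be destroyed by construction
  rather than tested.
* **Behaviour.** The per-trial chills duration is
  clamp(50 + effectSize × c + ε, 0, music duration) with
  effectSize = 30 s per coupling unit and ε ~ N(0, 30 s) — participant
  means then have a grand mean near 50 s and SD near 32 s, the order of
  the reported behaviour. Chill event counts are Poisson (mean 3) with
  log-normal durations (median 10 s) rescaled to the target total; gaps
  are filled with pleasure/neutral presses ("always press one button"),
  and tears occasionally co-occur inside a chill. Negative targets clamp
  to zero rather than resampling — simpler, and the truncation is part of
  the modelled behaviour.
* **Music epochs and physiology.** Music-epoch BOLD rides on a 100-unit
  baseline; reward ROIs add a double-gamma HRF convolution of the chill
  boxcar (plateau ≈ 1% signal change, scaled by the coupling).
  Electrodermal traces add Bateman-shaped (τ₁ = 0.75 s, τ₂ = 2 s)
  responses 0.5–1.5 s after chill onsets on a slow tonic drift; pulse
  traces are Gaussian bumps at beats with log-normal IBI jitter;
  respiration is a noisy 0.25-Hz oscillation.
* **Reproducibility.** All randomness flows from the config's single
  seed; the caller's RNG state is saved and restored, and an identical
  config yields a byte-identical cohort.

What the generator does *not* emulate: head motion and scrubbing, scanner
drift beyond a linear trend, heavy-tailed BOLD noise, spatial
autocorrelation within networks beyond the single within-network
correlation, or genuine neurovascular coupling. Passing tests therefore
show that the *pipeline* recovers what it assumes, not that real
recordings satisfy those assumptions.

## Numerical choices

* **Filters** are 2nd-order Butterworth applied forward–backward with
  odd-reflection padding and steady-state initial conditions, so constant
  inputs map exactly to their steady response and passband signals suffer
  no phase shift. Music epochs are high-pass filtered only (0.008 Hz);
  `keepMean = TRUE` restores mean signal levels for percent-signal-change
  baselines.
* **Windows** are half-open `[start, end)` in seconds; a volume belongs
  to the window containing its onset time.
* **Coordinate descent** solves `(1/2n)‖y − b − Xs w‖² + λ‖w‖₁` on
  features standardised (population SD) inside each training fold only.
  Outer refits iterate to a tolerance of 1e-6 (scaled by the target's
  SD); the inner λ-selection loop only *ranks* penalties, so
  `fastCvControl()` relaxes its tolerance and sweep caps for
  permutation-scale work — applied identically to observed and permuted
  targets, so the comparison stays exchangeable. λ ties break toward
  stronger shrinkage; an inner fold whose predictions are constant scores
  0 (an intercept-only model claims no relationship), so noise features
  cannot win the selection by returning undefined correlations.
* **Degenerate accuracies** (constant held-out predictions) are reported
  as NA with a flag, never silently as 0.
* **The SCR phasic driver** replaces the original black-box continuous
  decomposition analysis with a documented, deterministic equivalent:
  low-pass (1 Hz) + 10 Hz resampling, running-minimum tonic removal,
  then non-negative Tikhonov-regularised deconvolution against the
  Bateman kernel by projected accelerated gradient descent; driver
  excursions whose reconvolved response peaks below 0.05 μS are zeroed.
  It inverts its own forward model to < 10% L2 error on clean input,
  which is the property the downstream quantification needs.
* **Event-locked quantification** uses a 1-s pre-onset baseline, sums
  baseline-corrected values over the event window, and excludes events
  beyond ±3 SD of the within-measure event distribution (exclusions are
  recorded, not dropped). BOLD responses shift the event window by +4 s
  for haemodynamic delay; the percent-signal-change baseline averages the
  volumes 2 TR before and 2 TR after the (shifted) onset — the
  onset-adjacent ±1 volumes are excluded, with `baselineMode =
  "adjacent"` available as the alternative reading.
* **The paired rest-condition comparison** (`pairedEdgeTest`) is a
  per-edge paired t test on participant-level means with BH-FDR across
  edges — a deliberate simplification of a trial-level mixed model; the
  trial-level feature tables remain exportable for users who want to
  refit one externally.

## Design choices that were genuinely open

* **One-sided trial outlier screen.** Only trials above mean + 3 SD are
  removed, matching the stated rule for excessively long durations.
* **Drop-then-merge order** for press cleaning: a sub-second press
  between two same-label presses bridges them into one event.
* **Transfer weights refit on all units.** The cross-cohort model is the
  full-sample refit at the λ chosen by plain leave-one-out, which is the
  standard convention when a single exportable weight vector is needed.
* **Permutation screening.** Permutation tests re-run the full nested
  cross-validation, which is expensive; like the original analysis,
  the pipeline screens network pairs by the (anticonservative)
  parametric correlation test and applies permutation + FDR inference to
  the screened set. The parametric screen only costs permutation work;
  all published significance comes from the permutation p-values.
* **SCR log transform** is log(1 + x) on the per-participant total, so
  zero totals stay finite.
* **Outlier pooling.** The ±3 SD event screen pools events within
  participant × measure (not across participants); both this and the log
  transform placement are recorded in the output metadata.

## Problem sizes used by the validation suite

The statistical validation runs on desk-scale cohorts chosen so the full
suite completes on a single CPU while keeping the study's design
constants: 38 participants × 8 trials with the complete auditory (12) and
reward (8) systems and 4 ROIs per remaining network (64 ROIs, 78 network
pairs) for planted-effect recovery and transfer; 14 participants × 2
trials × 12 ROIs for the 200-cohort null calibration at 200 permutations;
20 replicate cohort pairs for transfer generalisation; 6 replicate
cohorts for the check that the planted pair outranks all 77 other
network pairs on average; 10-minute
intrinsic rest sampled as 8 × 18-s windows, 20 repetitions (the original
procedure's 10,000 repetitions are available by argument). The whole-brain
288-ROI parcellation is exercised where its combinatorics are the point
(edge counts, pair enumeration) and remains the default for real-format
cohorts.

## Known limitations

* The generator's planted coupling is a covariance-scale mechanism; it
  cannot distinguish hypotheses about *why* pre-task rest differs from
  intrinsic rest, only whether the pipeline separates them.
* Leave-one-out accuracy has a wide null distribution at n = 38; the
  parametric correlation p on cross-validated predictions is
  anticonservative and must not be used as final inference — use the
  permutation machinery (this is why it exists).
* The nested CV treats trials of one participant as exchangeable units in
  the trial-level variant, as in the emulated analysis; participant
  identity is carried in the outputs so a grouped CV could be added.
* `fastCvControl()` truncates coordinate descent at the smallest penalties
  where the solution is non-unique anyway; the default control reproduces
  the tight-tolerance solution when single fits matter.
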