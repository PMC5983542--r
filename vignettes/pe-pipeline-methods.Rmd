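---
title: "Models and methods of the prediction-error learning pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the prediction-error learning pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pelearn` implements an end-to-end analysis of a probabilistic
instrumental learning task with concurrent fMRI: a Q-learning model of
behavior, maximum-likelihood fitting, prediction-error (PE) regressors
for ROI-level GLMs, generalized psychophysiological interaction (gPPI)
connectivity, and the group statistics of a two-group (control vs. MDD)
design. This vignette documents the models, the defaults and why they
were chosen, the synthetic-data generator, and the numerical decisions.

## The task and its coding

Three runs of 120 trials interleave gain, loss and neutral stimulus
pairs (40 trials each per run, pseudo-random order with at most 4
consecutive trials of one condition, correct-stimulus screen position
counterbalanced exactly 20/20 per condition and run). One stimulus of
each pair — the "correct" one — delivers the better outcome of the pair
with probability 0.8, the other with probability 0.2. Monetary outcomes
are normalized to unit scale: +1 (gain), −1 (loss), 0 ($0/nothing). The
normalization keeps the learning rate and inverse temperature
scale-free; `task_config()$dollars_per_unit` records the $10-per-unit
conversion. Under this coding both neutral outcomes are 0, so the
neutral "correct" stimulus is a label only and neutral accuracy hovers
at chance — which is also why the task-compliance exclusion criterion
(accuracy strictly below 50% excluded) pools the gain correct-choice
rate and the loss avoidance rate and ignores neutral trials.

Trial onsets are spaced 6 s apart with ±1 s uniform jitter (the main
task description gives no timing, so a conventional event-related
spacing is used; both values are configurable).

## Q-learning model

Only the chosen stimulus's expected value is updated:
`pe = outcome − Q`, `Q ← Q + α · pe`, with values starting at 0 and
reset at each run boundary because every run introduces new stimulus
pairs. Choices follow a two-option softmax on the value difference with
inverse temperature β. The model carries one learning rate per valence
and a shared β (3 free parameters; the neutral learning rate exists but
is inert under 0-coded outcomes, and neutral choices contribute ln 2
each to the likelihood). With outcomes in [−1, 1] and Q₀ = 0, every Q
stays in [−1, 1]; the tests verify this as an invariant together with
the equilibrium property E[Q] → 0.8 under forced sampling of a
0.8-contingency stimulus.

Subject-level fitting minimizes the negative log-likelihood (computed in
compiled code; an independent pure-R brute-force recursion checks it to
1e−10 in the test suite) with L-BFGS-B under bounds α ∈ [0, 1],
β ∈ [0, 20], from a fixed 9 × 4 grid of starts
(α ∈ {0.1, …, 0.9} shared across valences, β ∈ {0.5, 2, 5, 10});
ties are broken by lower likelihood, then lower β, so refits are
bit-identical. Choice probabilities are clamped to [1e−12, 1 − 1e−12]
against underflow, and the optimizer tolerance on the objective is 1e−8.
Fit quality is referenced to the chance model (β = 0, every choice at
probability ½, nested in the Q-learning model): a likelihood-ratio
statistic on 3 degrees of freedom and the pseudo-R²
1 − nll/nll_chance. When β̂ collapses toward 0, the likelihood is flat
in α; the fit flags this (`alpha_identifiable = FALSE`) when the
numerical α gradient at the optimum is below 1e−3.

For the imaging stage the pipeline follows the fit-then-pool policy:
learning rates are re-fixed at the arithmetic mean of the per-subject
estimates across both groups (one value per valence; the mean rather
than the median is used), and the PE series entering the GLM are
recomputed from zero with those fixed values. A replication mode
(`fixed_alpha_policy = "fixed"`) sets them directly, defaulting to the
conventional 0.3 (reward) / 0.4 (punishment) operating point. Whether
fitted jointly across runs or per run matters little here; the package
fits jointly across the three runs.

Sign conventions for the regressors: on gain trials the modulator is the
raw PE (RPE; positive for unexpected reward), on loss trials it is the
sign-flipped PE (PPE; positive for unexpected punishment), so a positive
fitted coefficient always means greater activation to the unexpected
event of that valence. Neutral trials carry the raw PE, identically zero
under the outcome coding.

## ROI GLM

All regressor construction lives on the scan grid: event onsets are
assigned to the nearest TR bin (TR = 2 s by default) and convolved with
a canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s,
dispersions 1, undershoot ratio 1/6, 32 s support, peak-normalized;
the kernel is 0 at t = 0 and peaks near 5 s). With jittered 6 s
inter-trial intervals the ≤1 s binning error is small against the HRF
width, and the BOLD generator and the design matrix share the same
construction, so planted couplings are exactly representable — which is
what makes estimator bias testable. Each run's design holds, per
condition, an onset regressor and a PE parametric modulator
(mean-centered per condition and run before convolution; no further
orthogonalization against the onset regressor, a choice that leaves
shared onset/modulator variance with the modulator and is documented
rather than hidden). Runs are analyzed separately and betas averaged per
subject. A condition without events yields all-zero, flagged columns
which the OLS drops. Run length defaults to covering all events plus a
24 s tail (~186 scans per run). No motion or nuisance regressors are
modeled. Estimation is ordinary least squares with classical standard
errors; under the null the t statistics match their reference
distribution (Kolmogorov–Smirnov check in the suite).

The BOLD generator (`simulate_roi_bold`) plants condition amplitudes and
PE couplings at the neural level, convolves with the same kernel, and
adds AR(1) Gaussian noise (innovation sd 1, coefficient 0.3 by default —
the OLS point estimates stay unbiased under this mild autocorrelation,
which the recovery tests confirm).

## gPPI

Connectivity uses the VTA as seed. BOLD-level multiplication of seed and
task regressors is biased for event designs, so the interaction is
formed at the neural level: the seed series is deconvolved by ridge
regression against the scan-grid convolution operator C,
`neural = (CᵀC + λI)⁻¹ Cᵀ y`, with λ fixed at 0.1 times the mean
diagonal of CᵀC; the estimated neural signal is gated by each
condition's scan indicator and re-convolved. The design holds the
psychological regressors, the physiological seed series, the three
interaction terms and an intercept; the interaction coefficients are the
per-condition connectivity values. The ridge default inverts convolution
on smooth signals to within 5% relative error; on spiky event-locked
neural signals recovery is attenuated but order-preserving, which is the
property the analyses rely on (group and condition contrasts, not
absolute coupling units). The mean ROI time series (not a first
eigenvariate) serves as the seed signal.

## The synthetic cohort

`cohort_spec()` defines the generative study the pipeline is validated
on: 26 controls and 25 MDD subjects (the post-exclusion sizes of the
motivating study design), each simulated through the full task. Defaults
and their rationale:

* **Learning rates.** Subject α are Beta-distributed with concentration
  20 (sd ≈ 0.1, a realistic between-subject spread). Controls:
  α_gain mean 0.35; MDD: lowered by 0.25 (mean 0.10). The deficit was
  calibrated once so that the simulated groups reproduce the observed
  reward choice-accuracy contrast of roughly 88% vs 80%; the α → accuracy
  mapping is shallow at β ≈ 3, so a small α deficit produces an
  implausibly small behavioral gap. α_loss mean 0.40 in both groups
  (spared punishment learning). β ~ Gamma(9, 3) (mean 3, sd 1) in both
  groups.
* **Neural couplings** (BOLD a.u. per PE unit, subject sd 0.3): RPE
  couplings 1.0 for both striata (MDD right striatum halved — the
  planted blunted-RPE effect), 0.8 VTA, 0.2 habenula, 0.4 insula; PPE
  couplings 0.8 for habenula/VTA/insula and 0.5 for the striata, equal
  across groups (spared punishment signaling).
* **Connectivity.** VTA-seeded neural gating κ per condition: right
  striatum 0.8 (gain; MDD scaled by 0.6 — the planted connectivity
  reduction) and 0.3 (loss), other targets 0.4/0.4, neutral 0.15,
  subject sd 0.1. The gain > loss asymmetry plants the valence main
  effect.
* **Clinical covariates.** BDI and SHAPS drawn at the group moments of
  the study sample (BDI 0.44 ± 0.71 vs 26.26 ± 9.21; SHAPS 18.6 ± 4.49
  vs 33.40 ± 4.22); lifetime major-depressive-episode (MDE) counts as a
  rounded truncated normal at 3.72 ± 3.06, with 7 of 25 MDD subjects
  masked missing (exercising the n = 18 correlation path); current
  episode length lognormal at 11.52 ± 15.41 months, a nuisance
  covariate only.
* **Disease burden.** A latent standard-normal factor loads (0.75) on
  the MDE count, negatively on the MDD right-striatal RPE coupling and
  positively on the MDD habenular PPE coupling, planting dose-effect
  correlations of magnitude ≈ 0.55 between episode count and the
  ground-truth couplings. Estimation noise attenuates the recovered
  correlations on the beta estimates, as it would in real data.

What the generator does **not** emulate: spatial fMRI structure, scanner
drift, motion, physiological noise, reaction times, or any coupling of
BDI/SHAPS to behavior. Passing tests therefore show that the estimators
recover what was planted under idealized noise — not that the scientific
conclusions would survive real-data confounds that are out of scope
here.

## Group statistics

* **Learning curves.** A linear probability model of trial-level choices
  on Trials × Valence × Group with per-subject random intercepts and
  random valence slopes (REML via `lmer`, Satterthwaite p values); the
  per-valence Group × Trials slopes come from separate within-valence
  models with random trial slopes. The random valence slope is not
  cosmetic: each subject carries its own pair of learning rates, so
  subject-specific valence effects exist by construction, and a
  random-intercept-only model tests the Group × Valence term against the
  wrong error stratum (simulations show its type-I rate near 0.13). With
  the slope included the test holds its nominal level, which is the
  contract the estimator must satisfy. The linear (not logistic) link
  matches the per-trial slope scale conventionally reported for this
  task. Loss is the valence reference level, so the Group × Valence
  coefficient is the MDD accuracy deficit specific to the gain
  condition. Type-I calibration is verified by simulation (500 null
  cohorts of 10 + 10 subjects).
* **Mixed ANOVAs.** Balanced split-plot designs via the classical
  sums-of-squares decomposition (`aov` with subject error strata), one
  value per subject and cell, no sphericity correction by default (the
  within factors of interest are two-level or treated unadjusted, in
  line with common reporting). Partial eta squared is computed from F
  and the degrees of freedom.
* **Effect sizes and families.** Cohen's ds = |t|√(1/n₁ + 1/n₂);
  Fisher z for comparing independent correlations; Bonferroni
  thresholds 0.05/5 for the five ROI tests and 0.05/10 for the clinical
  correlation family. Partial correlations residualize both variables on
  the covariates (with intercept) and use a t reference with
  n − k − 2 degrees of freedom. All tests are two-sided; unadjusted p
  values are reported against the family thresholds.

## Problem sizes and determinism

Every stochastic component takes an explicit seed, and each consumes a
documented stream order (per trial: one choice draw, then one outcome
draw on gain/loss trials), so cohorts, pipeline runs and the written
files reproduce byte-identically from (spec, seed). The validation suite
sizes its simulations to be informative yet quick: 100 subjects per
trial-count condition for parameter recovery, 200/100 seeds for
GLM/gPPI recovery, 500 replicates for the type-I calibrations (with
reduced cohorts of 6 + 6 subjects), and 50 full cohorts for the planted
direction test. These sizes were chosen so that Monte-Carlo error is
well below the tolerances being asserted.

## Known limitations

* The gPPI interaction estimate is attenuated for event-locked neural
  signals; only contrasts (orderings, group differences) are
  interpretable, not absolute coupling magnitudes.
* The linear probability model for binary choices is heteroskedastic;
  its calibration is verified empirically rather than guaranteed
  analytically.
* Scan-grid (TR-resolution) regressor construction trades sub-TR onset
  precision for an exactly invertible generator/estimator pair; with
  rapid designs (ITI close to TR) an oversampled microtime grid would be
  preferable.
* The exclusion criterion pools gain accuracy and loss avoidance; a
  study using gain-only or loss-only accuracy would shift which
  borderline subjects are retained.
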