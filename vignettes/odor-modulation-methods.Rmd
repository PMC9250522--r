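---
title: "Methods: odor modulation of barrel-cortex population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odor modulation of barrel-cortex population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`odormod` implements the analysis chain used to ask whether odors modulate
neuronal activity in the whisker region of primary somatosensory cortex
(wS1, "barrel cortex"): from raw two-photon ROI fluorescence to single-cell
modulation statistics, orofacial kinematics, and population decoding. This
vignette documents the models, conventions and numerical choices, and what
the synthetic-data generator does and does not emulate.

## Trial structure and epochs

A session crosses two grating orientations with two odors (4 bimodal
conditions, 10 repetitions each), presents each stimulus alone (4 unimodal
conditions, 20 repetitions each) and includes a blank (30 repetitions):
9 conditions and 150 trials in a seeded pseudo-random order. Trials last
11 s and are imaged at 31.5 Hz; whisker and breathing channels run at
500 Hz and the facial camera at 20 Hz. All of this is configurable in
`make_protocol()`.

Every analysis window is half-open `[start, end)` in seconds relative to
stimulus onset, with 1-based frame indexing internally and frame times
starting at 0 at the trial start. The stimulation epoch defaults to the
2 s of stimulus presentation — the package fixes the single-cell test
epoch to 0–2 s after onset and exposes it as a `window` argument wherever
it matters. The baseline epoch is 1–2 s before onset.

## Preprocessing

`neuropil_correct()` subtracts the scaled neuropil trace,
`F_cor = F − 0.7·F_n`. `compute_dff()` then estimates `F₀` per cell and
trial as the 8th percentile of that trial's **corrected** trace and forms
`ΔF/F₀ = (F_cor − F₀)/F₀`. Two conventions deserve a note:

* **Percentile convention.** Quantiles use linear interpolation between
  order statistics (R type 7, which is also numpy's default). The
  percentile is taken on the corrected trace, since correction precedes
  normalization in the processing order; the alternative (raw `F`) changes
  `F₀` only through the smooth neuropil component and leaves every test
  statistic rank-identical in our generator.
* **Baseline subtraction.** The scalar mean of `ΔF/F₀` over the baseline
  epoch is subtracted from the whole trial, so the baseline-epoch mean of
  every trace is exactly zero — an invariant the test suite asserts.

Cell/trial pairs with `F₀ ≤ 0` cannot be normalized; they are set to `NA`,
recorded in a flag table, and excluded from downstream tests (rows with
missing values yield `NA` p-values). Spike deconvolution is out of scope;
where a deconvolved signal would be used, `ΔF/F₀` is used instead.

## Single-cell statistics and the shuffle null

Responsiveness is a Kruskal–Wallis test across all conditions on
stimulus-epoch means; modulation is a two-sided Mann–Whitney U test
comparing odor-bearing with odor-free trials, pooling different odors
together (odor identity is treated as a decoding question). The modulation
index is `MI = (mean_odor − mean_no_odor)/mean_no_odor`, undefined when the
reference mean is numerically zero.

**Mann–Whitney convention.** The p-value uses the normal approximation
with tie and continuity correction at all sample sizes (the exact U
distribution is available via `method = "exact"` for tie-free samples).
This choice matters for the shuffle null: at α = 0.05 the test's
*achievable* level depends on the discreteness of U and on the p-value
convention. Computing the rejection probability exactly over the null U
distribution gives 4.871% for 40 vs 40 trials under the corrected normal
approximation (4.984% under the exact-p convention) and 4.907% for 40 vs
30 under either. The corrected approximation is the default because it is
the convention whose level matches the shuffle-null calibration this
statistic is interpreted against, and it is what the common scientific
Python stack computes at these sample sizes.

`shuffle_null_proportion()` permutes the trial labels within the session
and re-tests every cell. Since permutation leaves the pooled sample
unchanged, ranks and tie corrections are computed once per cell and each
permutation costs one rank sum, so hundreds of shuffles per session are
cheap. The default is 100 shuffles per session, configurable. No
multiple-testing correction is applied across cells: the flagged
*proportion* is interpreted against the shuffle null, not per-cell
discoveries against an FDR.

Session-level inference (`summarize_sessions()`) uses percentile bootstrap
CIs over sessions (1000 resamples), paired Wilcoxon signed-rank tests
(real vs shuffled proportion; enhanced vs suppressed), and a two-sample
Kolmogorov–Smirnov test on pooled modulation-index distributions.
`compare_proportions()` is a Pearson chi-square on the 2×2 table without
continuity correction, so that homogeneous tables give a statistic of
exactly zero.

## Orofacial kinematics

Whisking and breathing are analyzed through the same front end
(`analytic_decompose()`): a 2nd-order Butterworth band-pass (4–30 Hz for
the whisker angle, 4–20 Hz for the pressure signal) followed by the
analytic signal, whose modulus is the instantaneous envelope and whose
unwrapped argument the phase. Numerical choices:

* **Zero-phase filtering** (forward–backward) so cycle landmarks are not
  delayed; the signal is demeaned and odd-reflected at the edges over
  about three periods of the lower band edge before filtering, which
  suppresses the start-up transients that would otherwise masquerade as
  cycles in near-constant signals.
* **Cycle boundaries** are crossings of multiples of 2π of the unwrapped
  phase; cycles whose mean envelope falls below a small threshold are
  discarded (a constant trace yields an empty cycle table).
* **Quadratic interpolation.** Within each cycle the raw-angle extrema
  (maximum protraction and retraction) are refined by fitting a parabola
  through the three samples around each sampled extremum; amplitude is the
  range (max − min) and setpoint the center. The alternative reading —
  interpolating the phase rather than the angle extrema — changes cycle
  *timing* at sub-sample scale but not the amplitude/setpoint statistics.
* Breathing amplitude is the mean envelope per cycle and frequency the
  inverse cycle duration; inhalations are negative pressure deflections.
* Curvature is rectified **before** baselining: `|κ|` minus the per-trial
  mean of `|κ|` over the baseline epoch. The order is observable (a
  sign-flipping κ of constant magnitude gives exactly zero) and tested.

Whisker-pad averaging across ~12 whiskers is assumed done upstream; the
module consumes one angle and one curvature trace per trial.
`epoch_kinematics()` summarizes cycles whose midpoint falls in the window;
`kinematics_tests()` contrasts odor against no-odor trials within grating
contexts — unpaired Mann–Whitney across trials within a session, paired
Wilcoxon on session means across sessions.

## Population decoding

`build_features()` averages `ΔF/F₀` in 1-s bins tiling the trial, one
feature per cell per bin. Pooled pseudo-populations concatenate cells from
several sessions after matching trials on (condition, repetition index),
undoing each session's presentation order; unequal repetition counts are a
hard error naming the condition. The optional z-scoring is global (each
feature mean 0, SD 1 across all trials), matching how between-session
variants of such analyses are usually described; because a global scaling
uses test trials, decoders themselves never rescale inside
cross-validation folds, and the vignette flags this as the one place where
a leakage-free variant (train-fold statistics) would differ slightly.

The nearest-centroid decoder uses Euclidean distance (first minimum wins
ties) with seeded stratified k-fold cross-validation; k = 10 by default.
(Descriptions of this analysis alternate between 10- and 20-fold
stratification; the package defaults to 10 with `k` exposed everywhere.)
Permutation p-values locate the real accuracy in `n` label-shuffle
accuracies as the one-sided exceedance fraction floored at `1/n` — the
floor is why 1000 shuffles limit p to 3 decimals; a two-sided option
doubles the smaller tail. `transfer_test()` fits on one stimulus context
and reports the stratified-CV in-domain score next to the accuracy on the
disjoint out-of-domain context.

Multi-class SVMs use libsvm (`e1071`) with a linear kernel; libsvm's
one-against-one pairwise coupling stands in for one-vs-rest — at the
separable and chance extremes the criteria exercise, the two schemes
agree. The regularization rule selects, over a cost grid, the value
maximizing stimulation-epoch accuracy subject to baseline-bin accuracy
staying inside the binomial 95% interval of chance (a cheap stand-in for a
per-cost shuffle null); if no cost qualifies the smallest is used with a
warning. Mixture categorization trains a Gaussian radial-basis SVM on pure
odors only and reports per-ratio assignment fractions. Facial decoding
takes the truncated SVD of the motion-energy matrix (time × pixels,
uncentered, as motion-energy pipelines do), bins the first 500 PC time
courses per trial, and decodes odor identity with the linear SVM.

## The synthetic-data generator

`simulate_population()` emulates what the analysis assumes about such
recordings, with every injected effect recorded as ground truth:

* condition-dependent response amplitudes (dF/F units) drive a boxcar over
  the stimulation epoch convolved with a single-exponential calcium kernel
  (τ = 1.5 s, GCaMP6s-like, so transients outlast the 2-s epoch). The
  kernel is normalized so its mean over the stimulation epoch is 1: an
  injected effect of `e` moves the epoch-mean `ΔF/F₀` by exactly `e` in
  the noiseless case — the basis of exact recovery tests.
* tactile cells (30% by default) respond to gratings with an orientation
  preference; a per-trial log-normal gain (SD 0.25) shared across cells
  models whisking/contact variability in tactile drive.
* a fraction of cells (configurable; effects log-normal around a median
  the user sets — the effect-size distribution of real modulated cells is
  unknown, so this default is a documented stand-in) is enhanced or
  suppressed on odor-bearing trials; suppression is floored at −0.5 dF/F
  so fluorescence cannot go negative.
* odor identity lives on a unit-norm population axis at a configurable
  angle to the tactile (orientation) discriminant: 90° makes tactile
  transfer robust and — because the large mean tactile vector still
  projects onto the odor axis through finite-population sampling and the
  trial-to-trial tactile gain — collapses an odor decoder tested under
  touch to chance; small angles make both directions fragile.
* a shared slow neuropil signal is mixed into `F` with the same 0.7
  coefficient used for correction, so correction removes it exactly when
  noise is zero; `F` and `F_n` carry independent Gaussian noise on top.

`simulate_orofacial()` generates `setpoint + A(t)·sin(phase)` whisking at
8 Hz and sinusoidal breathing at 6 Hz with multiplicative odor gains from
stimulus onset; `simulate_facial_motion()` builds a low-rank-plus-noise
motion-energy matrix whose component time courses optionally carry
odor-specific deflections. Everything is bit-reproducible from
(arguments, seed).

What the generator does **not** emulate: correlated noise between nearby
cells beyond the shared neuropil and tactile gain, slow drift and
photobleaching, nonlinear calcium-to-rate transformations, whisker-contact
mechanics, or real video statistics. Passing tests therefore certify the
*statistical machinery* — calibration of levels and p-values, recovery of
injected effects, decoder geometry — not robustness to every artifact of
real recordings.

## Problem sizes and reproducibility

The test suite runs its statistical checks at desk scale, chosen so the
Monte-Carlo error of each check is small relative to its tolerance: null
calibrations use sessions with the standard 150-trial design but coarser
imaging (the statistics consume only epoch means), e.g. 6 sessions × 150
cells × 80 shuffles for the shuffle-null levels, 120 replicates for
p-value uniformity, and 5–6 sessions per condition for recovery and
transfer properties. `scripts/acceptance.R` recomputes the headline
shuffle-null levels at full scale (20 sessions × 200 cells × 100 shuffles
under the 31.5 Hz, 11-s protocol) from a single `--seed`. All randomness —
trial order, simulation, fold assignment, shuffles, bootstraps — flows
through explicit seeds, and `run_pipeline()` derives per-session,
per-stage seeds from one master seed so identical configurations reproduce
identical outputs.

## Known limitations

* The Mann–Whitney asymptotic convention is deliberate (see above); users
  comparing against exact-test pipelines should expect the shuffle-null
  level to sit at ≈4.98% rather than ≈4.87% for 40 vs 40 trials.
* The chi-square proportion comparison omits the continuity correction;
  with the cell counts involved (hundreds) the difference is negligible.
* Facial decoding operates on motion-energy matrices, not raw video, and
  the SVD is recomputed per session; no alignment of components across
  sessions is attempted beyond trial matching.
* The session container is a directory of CSV/JSON files; arrays are
  stored dense, which is simple and portable but large for full-size
  sessions.
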