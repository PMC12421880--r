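---
title: "Models and methods behind cilisten"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cilisten}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cilisten)
```

This vignette is the package's account of its science: the signal models,
the estimators, the numerical conventions, and the choices made where the
methodology left genuine freedom. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The measurement problem

Listeners with a cochlear implant (CI) present two linked analysis
challenges. First, the implant injects a large electrical artifact into the
EEG that is time-locked to sound onset — exactly the property that defines
the auditory evoked activity one wants to measure — so the two can only be
separated by their different latencies and scalp topographies. Second, the
quantities of interest are small: a steady-state oscillation of a microvolt
or less riding on tens of microvolts of background EEG, and an attentional
alpha-power modulation of a few tens of percent. The package therefore
pairs every estimator with a generative model of the data it is meant to
handle, so that each pipeline stage can be validated against known ground
truth.

## Synthetic sessions

`generate_passive_session()` and `generate_attention_session()` emit
continuous 64-channel records (not pre-cut epochs), so that epoching,
trial rejection and filtering are genuinely exercised downstream.

**Signal classes.** Each source is a one-dimensional time course mixed into
channels through a fixed spatial profile (a Gaussian in unit-sphere chord
distance around a named electrode):

* *Auditory*: a tri-phasic onset template with Gaussian lobes at roughly
  50 ms (+), 100 ms (−) and 180 ms (+) — the P1–N1–P2 complex — plus a
  sinusoid at the tone's AM rate for the tone duration (the steady-state
  response), mixed through a fronto-central profile centred on FCz. The
  onset latencies are a modeling choice; any smooth tri-phasic template
  exercises the 0–230 ms analysis window equally well. The steady-state
  phase is fixed across trials by default; a `phase_jitter_sd` parameter
  exposes trial-to-trial phase variability rather than guessing a value,
  and the default of 0 makes ITPC = 1 the noise-free reference.
* *CI artifact*: a sharp biphasic transient at ~8–15 ms after sound onset
  plus a weak rate-locked pedestal (5 % of the peak) for the tone duration,
  mixed through a temporal profile on the implant side (T7/T8). The
  pedestal reflects that the implant follows the stimulus envelope at every
  AM rate equally, which is what distinguishes it from neural phase-locking.
* *Alpha*: one band-limited (7–13 Hz) Gaussian noise source per hemisphere,
  masked to that hemisphere's channels around PO7/PO8. During the
  anticipation period of the spatial task the source *power* is multiplied
  by `1 + d` (cued side ipsilateral) or `1 − d` (contralateral), with
  `d = alpha_lateralization`, scaled by `alpha_asymmetry` on the
  implant-side hemisphere. Front-cue trials receive the same modulation
  with opposite sign keyed to the to-be-ignored lateral speaker, so the
  suppression index has a planted, reversed effect. Modulating band-limited
  noise (rather than a pure sinusoid) yields realistic alpha spectra.
* *Background*: 30 spatially smooth 1/f sources plus a small white sensor
  floor, and blink-like half-sine transients (300 ms, 100 µV) over the
  forehead at a Poisson rate.

**Amplitude defaults** (µV at the topography centre) are stated nowhere in
the methodology the package implements, so they were fixed once at values a
practitioner would call typical: onset response 15, steady-state 0.8–1.5
depending on rate, CI artifact 150 (device artifacts dwarf neural signals,
but a 150 µV peak keeps single-trial ranges under the 300 µV screening
rule, as in real recordings where artifact trials are retained and removed
by ICA, not by the range rule), background sources 5 RMS, alpha source
variance 10 µV², lateralization depth 0.2 with implant-side asymmetry 1.5.
One structural choice deserves note: the auditory source carries ongoing
1/f activity (0.6 × the background RMS) in addition to its evoked
response, as a real cortical source does. Without it the auditory direction
holds negligible variance and the 90 %-variance ICA recipe could never
retain it — an instructive failure mode of purely evoked simulations.

**What the generator does not emulate:** volume-conducted source
correlations beyond topography overlap, non-stationary artifact morphology,
heartbeat and line noise, electrode drift and impedance changes, or
learning effects within a session. Tests passing on this generator
establish that the estimators recover what was planted under realistic
noise; they cannot certify behavior on pathologies the model omits.

**Designs.** The passive design draws the AM-rate sequence by sampling
proportional to remaining counts among rates that would not extend a run
beyond `max_run`, restarting on the rare dead end; infeasible count/run
combinations are rejected analytically. ISIs and anticipation periods live
on a 0.1-s grid. The spatial task alternates the lateral loudspeaker
block-wise, starting opposite the implant, which yields exactly equal
per-condition counts over an even number of blocks.

## Preprocessing

* **Filtering** is zero-phase Butterworth via forward–backward application:
  an order-2 high-pass cascaded with an order-4 low-pass. A single
  band-pass in transfer-function form is numerically marginal when the
  high-pass edge sits at 0.1 Hz against a 1000 Hz rate; the cascade is
  stable there and attenuates a 200 Hz tone by more than 50 dB relative to
  the passband.
* **Trial rejection** uses the maximum per-channel peak-to-peak range in
  the 0–2 s window. The absolute rule masks ranges above 300 µV. The
  percentile rule masks the `ceiling(0.10 · n_good)` largest ranges; ties
  keep the earlier trial. Both preserve trial order and are idempotent.
* **Decomposition** concatenates retained trials, reduces by PCA to the
  smallest rank whose cumulative eigenvalue share reaches 90 %, and rotates
  that subspace with FastICA. Projecting through all components therefore
  reproduces exactly the PCA-retained data, and removing a component
  subtracts its rank-one contribution.
* **Component classification** replaces visual inspection with documented
  score thresholds (`classifier_thresholds()`): a component is
  *sound-evoked* when the post-onset RMS of its trial-averaged time course
  exceeds 3× the pre-stimulus baseline RMS. This baseline-relative ratio is
  stable across trial counts, unlike an evoked-to-total variance ratio,
  which shrinks as 1/n for noise components and therefore admits no single
  threshold. Sound-evoked components split into *CI artifact* (peak latency
  ≤ 35 ms and ≥ 20 % of absolute topography weight over the implant-side
  temporal electrodes) versus *auditory* (later peak, ≥ 22 % weight over
  the nine fronto-central electrodes). Remaining components become
  *brain_other* on a steep negative log–log spectral slope, frontally
  concentrated ones and the rest *artifact_other*. Thresholds were
  calibrated on synthetic sessions and are exposed in the run
  configuration. At full session size (180 trials) both target components
  are recovered with wide margins; at the reduced sizes used in unit tests
  the CI artifact remains reliable while auditory recovery requires the
  moderate-noise settings the tests use.
* **Spherical-spline interpolation** reconstructs unconnected channels with
  an order-4 spline over 20 Legendre terms and a 1e−8 ridge; constants are
  reproduced exactly and smooth dipolar fields to a few percent.
  Interpolation of more than 25 % of channels is refused. Which channels
  need interpolation is a per-recording input, never inferred.
* **Average referencing** subtracts the instantaneous channel mean. When
  the component model is fitted on average-referenced data its maps are
  mean-zero across channels, and referencing then commutes exactly with
  component projection — the property the test suite checks.

## Steady-state quantification

* **GFP** is the per-sample *population* standard deviation across
  electrodes (n denominator — the convention is isolated in one function),
  averaged over the half-open 0–230 ms window. Averaging, not summation,
  makes the value independent of sampling rate.
* **Evoked spectra** cut the ERP to 0.5–2 s (skipping the onset response),
  apply a rectangular window, zero-pad to a 4-s grid (0.25 Hz spacing) and
  average squared-amplitude power over ±1 Hz around each integer frequency
  from 1 to 60 Hz. The AM rates 4, 20 and 40 Hz fall exactly on this grid.
  Peak power scales as amplitude squared; smoothing averages, so sums over
  a band approximately conserve power.
* **ITPC** takes the windowed Fourier phase of each trial (direct transform
  at the requested frequencies, not wavelets), normalizes each trial to a
  unit phasor and reports the modulus of the across-trial mean — by
  construction in [0, 1] and invariant to per-trial positive scaling. For
  uniformly random phases its expectation is √π/2·n^(−1/2), the
  small-sample Rayleigh limit the tests verify at n = 64.

## Anticipation spectra and lateralization indices

Anticipation-period power uses DPSS multitapers on the 0.75–1.5 s
cue-locked window — after cue offset and before the earliest possible sound
at 1.5 s — with a 2 Hz spectral half-bandwidth, which at 0.75 s yields two
tapers. Tapers come from the tridiagonal Slepian eigenproblem. Output is
spectral density on a 1-Hz grid, so band power is the sum over band bins;
this is the normalization the variance-partition test relies on.

Indices are computed per electrode on condition-average power per
frequency, then averaged over the 7–13 Hz band and over each 12-electrode
occipito-parietal set (computing indices before averaging across electrodes
preserves topographic sign structure; the alternative order is a one-line
change but not exposed). The ALI orientation is fixed as ipsilateral minus
contralateral target, so positive values denote the canonical ipsilateral
alpha increase; the two outputs are keyed to the implant side. Condition
means, not per-trial indices, enter the contrast — matching the index
definitions — and trials pool within condition with equal weight regardless
of block.

## Adaptive procedures

The 2-down-1-up staircase lowers the AM-rate difference only after two
consecutive correct responses (the correct counter resets after every
level change — the standard transformed up-down convention) and raises it
after each error, converging on the 70.7 % point. Steps are 0.5 Hz until
the fourth reversal, 0.25 Hz after; a reversal is a change in prescribed
step direction, the run stops at the tenth, and the threshold is the mean
level over the last six reversals, counted inclusive of the terminating
one (the alternative exclusive count lives one line away in an isolated
function). The difference is clamped to [0.25, 2] Hz so the deviant never
equals the standard; a run that cannot terminate within 400 trials — e.g.
against an observer that never errs and therefore never reverses — raises
an error carrying the partial trace.

The SRT session tracks four independent 1-down-1-up staircases from
+10 dB SNR in 2 dB steps, interleaved so that only the two conditions of a
block's speaker setup advance within that block. The estimator averages
the SNR over all trials of a condition except those of the first block in
which that condition occurred (initial convergence from the +10 dB start
completes well within that block), and flags estimates above +40 dB as
invalid; CI benefit is SRT(on) − SRT(off) per condition, with the
participant-level exclusion if any condition is invalid.

The method of limits scores an ascending run at the first detected level
and a descending run at the lowest still-detected level (one step above the
first miss), so a deterministic observer produces identical scores in both
directions; the threshold averages the last two runs per direction.

Observers are logistic:
p(x) = γ + (1 − γ − λ) / (1 + exp(−β(x − θ))), with γ = 1/3 for the
3-AFC task and 1/9 for the nine-number speech task. The acceptance script
fixes θ = 1.0 Hz with β = 8 /Hz (steep relative to the 0.25–0.5 Hz steps)
and θ = −2 dB with β = 0.5 /dB (a typical speech psychometric slope); the
convergence checks evaluate the observer's own psychometric function at the
mean estimated threshold, an oracle independent of the staircase code.

## Statistics

The paired permutation test realizes label exchange by sign flips of the
paired differences. With n pairs and a budget of 10 000 permutations, all
2ⁿ flip patterns are enumerated when 2ⁿ ≤ 10 000 (the identity pattern
included, so an exhaustive p is never 0); otherwise flips are drawn with
replacement. "Exceeds" is resolved as ≥ (conservative), p is the raw
proportion by default, and the (b+1)/(m+1) estimator is available for the
Monte-Carlo branch. Flipped t statistics are computed from flipped means
alone, since Σ(s·d)² is flip-invariant — which also makes degenerate
all-same-sign flips yield ±∞ cleanly.

The repeated-measures ANOVA evaluates each within-subject effect through
its orthonormal contrast matrix on the subject × cell matrix:
F = (n‖z̄‖²/d) / (tr S · d(n−1)/(d(n−1))) in the standard univariate
decomposition, with the univariate Greenhouse–Geisser
ε = (tr S)² / (d · tr S²) from the covariance S of the contrast scores
(ε = 1 exactly for two-level factors; for the three-level factor the
univariate rather than multivariate ε is implemented). Corrected p-values
scale both degrees of freedom by ε. Only complete cases are accepted —
missing cells are an error, matching the complete-dataset analyses the
package supports. Effects whose between-condition sum of squares is below
1e−12 of the total report F = 0 rather than a 0/0 artifact. A 2×2 design's
interaction F equals the squared paired t of the difference-of-differences,
and the implementation is cross-checked against an independent
repeated-measures path (`car::Anova`) in the tests.

Spearman's ρ is the Pearson correlation of midranks, with constant input
flagged as undefined.

## Numerical conventions

Windows are half-open [start, end) in seconds relative to the event; sample
indices are 0-based in event tables and containers. All generator and
procedure randomness is seeded; identical seeds give bit-identical sessions
and traces, and the local RNG scope never disturbs the caller's random
stream. The interchange container stores float64 little-endian payloads
with a JSON header and TSV tables, round-tripping bit-for-bit.

## Problem sizes

The test suite runs synthetic sessions at 250 Hz with 30–72 trials where
the check concerns signal content, and the full 180-tone / 300-trial
designs where it concerns design counts; staircase convergence uses
300–1000 runs and the acceptance script 1000 runs per procedure. These
sizes were chosen so the estimators' sampling error is far below the
tolerances being checked.

## Known limitations

The component classifier is tuned to the generator's artifact morphology;
real recordings with atypical artifact latency or topography may need the
thresholds adjusted through the run configuration. The montage is an
idealized 10-10 sphere, adequate for set definitions and interpolation but
not a substitute for digitized positions. The ANOVA handles fully
within-subject designs only (1–3 factors), and the permutation test is a
paired two-condition test, not a cluster-based procedure. BrainVision
support is read-only and limited to multiplexed float32/int16 layouts.
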