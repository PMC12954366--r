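---
title: "Methods: time-resolved decoding of emotional expressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved decoding of emotional expressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

emodecode implements a complete sensor-space multivariate decoding
pipeline for EEG studies of emotional facial expressions: within- and
cross-experiment classification of the four basic expression labels
(happy, angry, sad, neutral) from multichannel epochs, with
cluster-permutation and Bayes-factor statistics and onset/peak latency
estimation. A synthetic two-experiment generator with a controllable
shared expression code makes every stage testable end to end without
access to raw recordings. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not establish.

## The analysis model

### Epochs and preprocessing

The pipeline's currency is an `eeg_epochs` object: a trials x channels
x samples array of amplitudes (µV) on a uniform timebase, with a trial
table (participant, dataset, expression, stimulus, correctness,
pseudo-trial flag). Epoch windows are half-open, `[tmin, tmax)`: the
standard −200…1200 ms window at 200 Hz has exactly 280 samples, and
every onset index in the package depends on this convention, so it is
worth stating loudly.

Preprocessing runs filter → baseline → resample → bin:

* **Band-pass 0.1–40 Hz.** A zero-phase windowed-sinc (Hamming) FIR,
  applied with reflection padding and group-delay compensation. The
  upper transition band is `max(0.25·f_high, 2)` Hz. A 0.1 Hz high-pass
  edge cannot be realised on a 1.4 s epoch — the epoch is shorter than
  one cycle of the cutoff — so when the lower edge is below
  `2/duration` it is implemented as exact per-trial DC removal, the
  closest epoch-length equivalent; with a resolvable lower edge a true
  band-pass kernel is designed instead. Filtering epochs rather than
  continuous data is a documented limitation: edge effects are absorbed
  by the padding and the ±200 ms margins of the analysis window.
* **Baseline correction** subtracts the per-trial, per-channel mean of
  the 200 ms preceding stimulus onset.
* **Down-sampling to 200 Hz** is Fourier-domain resampling; removal of
  frequencies above the new Nyquist is exact, and the output length is
  `round(n · f_new/f_old)`.
* **Pseudo-trials**: correct trials of the same image — the same
  participant x stimulus x expression cell — are randomly partitioned
  (seeded) into bins of 3 and averaged, trading trial count for
  signal-to-noise. Remainder trials are dropped; at the study counts
  (12 repetitions per image) nothing is dropped and participants retain
  128 (8-identity design) or 96 (6-platform design) pseudo-trials.
  Whether binning should follow acquisition order is unknowable for
  synthetic data; random seeded assignment is used and the seed is
  recorded in bundle headers.

### Classification

The classifier is Gaussian equal-covariance LDA: class means, pooled
within-class covariance, empirical priors, prediction by the largest
linear discriminant. The pooled covariance is inverted by symmetric
eigendecomposition with a relative tolerance of `p · eps`, falling back
to the pseudo-inverse (with a warning) when rank-deficient; ties in the
discriminant break towards the earliest class level. No shrinkage is
applied by default — matching the default behaviour of the widely used
reference implementations — but a convex shrinkage towards the scaled
identity is exposed. The per-timepoint decoding loop is compiled
(RcppArmadillo) and is tested for exact agreement with the plain-R
reference fit.

Features are single-timepoint channel amplitudes. Temporal smoothing is
applied *afterwards* to participant-level accuracies (35 ms boxcar = 7
samples at 200 Hz, shrinking at the edges), never to the features.

### Cross-validation schemes

* **Within-experiment (nested LOSO)**: one fold per participant x
  stimulus level; training aggregates all other participants restricted
  to the training stimuli, so neither the test participant nor the test
  stimulus is ever seen in training. For the 8-identity design the
  training stimuli are six identities balanced three male/three female:
  removing the held-out identity leaves its sex under-represented, so
  one opposite-sex identity is also excluded, iterated round-robin over
  folds (the choice is deterministic; nothing in the data motivates one
  partner over another).
* **Cross-experiment**: train on the aggregate of one experiment (all
  participants, all stimuli), test on each participant of the other
  individually; both directions. Overlapping participant ids across
  datasets are rejected as ambiguous.

Every plan is audited for leakage (participant/stimulus overlap within
folds, dataset overlap across) before any decoding; `audit_fold_plan()`
errors rather than warns.

Fold accuracies are averaged within test participant, so the unit of
all statistics is the participant. Chance is `1/n_classes` (0.25 or
0.5).

### Searchlight and regions of interest

The sensor searchlight decodes, for each channel, on the cluster formed
by the channel and its immediately adjacent neighbours. Adjacency is
the Delaunay triangulation of the montage's azimuthal-equidistant
projection — the standard parameter-free sensor neighbourhood — made
order-invariant by triangulating in a canonical coordinate sort. The
built-in 64-channel montage uses idealised spherical 10-10 positions
(outer ring on the equator, rows on great-circle arcs); these are not
digitised head measurements, but they reproduce the neighbourhood
structure the pipeline relies on (Cz borders C1/C2/FCz/CPz, and so on).
Six lateral ROIs cross hemisphere (odd terminal digit = left, even =
right, `z` = midline, excluded) with coronal band (Fp/AF/F/FT/FC
anterior; C/T/CP/TP central; P/PO/O/I posterior). The ROI rule is a
naming convention, not a published electrode list.

### Statistics

* **Cluster permutation** (temporal and spatio-temporal): one-sample t
  against chance per point; cluster-forming threshold is the two-sided
  parametric t at α = 0.05 (the reference toolkit's default); clusters
  are same-sign runs (or connected components under channel adjacency x
  temporal contiguity); the statistic is the summed t ("mass"); the
  null is the maximum |mass| over random sign flips of unit-level
  deviations; p-values use the add-one estimator, which is valid at any
  permutation count. Points where every unit deviates identically
  (zero variance — possible in tiny saturated problems) receive a large
  finite stand-in for the infinite t in observed and permuted
  statistics alike.
* **Interval-null Bayes factor**: a one-sample JZS-style test whose
  alternative prior is a Cauchy with scale r = 0.707 truncated to
  standardised effects |δ| ≥ 0.5 and renormalised, against the point
  null δ = 0. The marginal likelihood integrates the noncentral-t
  density over the two prior tails by adaptive quadrature; the test
  suite pins the result to an independent high-resolution trapezoid
  integration on a grid of (n, t), at 0.1% relative tolerance.
  Interval-null Bayes factors admit a second reading — truncated
  alternative against the *complementary* interval — but the
  methodology this test follows composes the whole-Cauchy prior with an
  excluded interval against the point null, and that is what is
  implemented. BF10 > 10 is treated as strong evidence throughout.
* **Effect sizes** are one-sample Cohen's d against chance with the
  n−1 standard deviation.

Bayesian statistics always run on the *smoothed* participant-level
accuracies, matching the pipeline ordering stated above.

### Onsets and peaks

Whole-scalp onset estimation averages searchlight accuracies over all
channels, smooths, computes the Bayes-factor timecourse, and reports
the first post-stimulus timepoint with BF10 above threshold (onset) and
the post-stimulus argmax of the BF (peak), with the Bayes factor and
accuracy at the peak. A single supra-threshold timepoint suffices by
default (`min_run = 1`); no crossing at all yields an explicitly
undefined report, never an error. Peaks are defined on the BF rather
than on accuracy because evidence magnitudes are what the thresholding
operates on; with heterogeneous participants the BF argmax can sit on
the rising flank of the accuracy curve, which is why the high-SNR
recovery validation uses a homogeneous cohort (see below).

## The synthetic generator

`generate_experiment_pair()` simulates two experiments that share an
expression code. Each class template is a sum of K = 4 temporal
Gaussian bumps (SD `width_s`, spaced `width_s/4` around `peak_s`,
hard-zeroed before `onset_s`) weighted by orthonormal per-class
vectors — orthogonality guarantees all six pairwise contrasts carry
signal — and projected through concentric spatial Gaussians of graded
width centred on `topography_center`. Zeroing below the onset means no
expression information exists before the nominal onset, which is what
makes onset recovery a meaningful test.

Three code components enter a trial:

* the **shared** component (weight `shared_weight`), identical across
  the two experiments of a pair and anchored at the canonical
  topography site — the transferable code;
* a **format** component (weight `format_weight`), redrawn per
  experiment with its centre displaced (SD twice the topography SD) and
  its spatial maps at half width — format-specific information that
  supports within-experiment decoding but not transfer;
* a **participant code** (`participant_code_sd`, scaled by the overall
  code weight so a signal-free configuration stays exactly at chance),
  redrawn per participant at displaced local sites — the idiosyncratic
  part of an individual's expression code. This is what makes
  leave-one-participant-out decoding harder than within-participant
  decoding in real data, and it is essential for transfer-specificity
  testing: the accuracy of a classifier applied to a *mismatched*
  template is a deterministic function of the template draw, identical
  for every test participant, so without participant-level code
  variability the sign-flip permutation null (which assumes
  exchangeable units) is miscalibrated for the cross-experiment "null"
  and flags spurious transfer. Participant idiosyncrasy both inflates
  the between-unit variance the test sees and is the scientifically
  realistic regime.

Nuisance terms: a multiplicative participant gain (mean 1, SD
`participant_gain_sd`); per-stimulus evoked offsets (smooth, zero
pre-stimulus, constant over a stimulus's trials and shared by its four
expressions, so they break stimulus generalisation without carrying
expression information); and spatio-temporally correlated noise —
`1/f^α` spectrum in time, squared-exponential covariance
`exp(−d²/ℓ²)` across the projected scalp. All trials are marked
correct: the paradigm re-inserts incorrectly answered trials until the
design count of correct trials is reached, and the pipeline still
filters on the flag.

Defaults are chosen once as a realistic operating point: evoked
amplitude 2.5 µV against 8 µV single-trial noise (a component only
resolvable after pseudo-trial averaging and group aggregation), pink
noise (α = 1), spatial correlation length 0.6 rad, participant gain SD
0.2, stimulus offsets 1 µV, participant code weight 0.4, onset 100 ms,
peak 155 ms, temporal SD 25 ms, posterior-lateral topography (PO8, SD
0.5 rad). Every stochastic element draws from a named substream of one
master seed (`substream_seed()`), so templates, stimulus effects,
gains, noise and binning can be perturbed independently.

## Validation design and problem sizes

The test suite validates each stage against independent oracles (a
brute-force eigendecomposition LDA, an empty-circumcircle check of the
Delaunay adjacency, trapezoid quadrature for the Bayes factor, hand
computations for effect sizes) and then closes the loop with
generator-truth experiments, at sizes chosen to keep the full suite in
the tens of minutes on one core:

* **Null calibration**: 500 runs of the temporal and spatio-temporal
  cluster tests at 500 permutations, 20 units, on Gaussian null data —
  the family-wise error rate must sit inside the 95% binomial interval
  around 0.05; label-shuffled decoding of signal-free synthetic
  experiments (10 participants) must sit within ±0.01 of chance for
  the four-class and a pairwise contrast.
* **Parameter recovery**: a 12 + 12-participant pair on a −200…600 ms
  window with a strong (12 µV vs 4 µV noise), homogeneous
  (gain SD 0.05, no participant code) injected signal; within-dataset
  and both cross-dataset sensor-averaged searchlight onsets must land
  within ±20 ms (four samples) of the injected 100 ms, peaks within
  ±20 ms of 155 ms, and the grand-average searchlight map across the
  four analyses must peak in the injected site's neighbourhood. The
  homogeneous cohort isolates the estimator: with idiosyncratic codes
  the group-level BF peak is systematically earlier than the accuracy
  peak, a real property of the estimator rather than a bug.
* **Transfer specificity**: 20 seeded 8 + 8-participant pairs with the
  shared weight at zero and a format-only code (4.5 µV, participant
  code 0.6) — the within-experiment cluster test must find the code in
  at least 95% of runs while cross-experiment decoding must stay
  non-significant in at least 95%; with the shared code restored,
  cross-experiment evidence (BF10 > 10) must appear in the signal
  window in both directions.
* **End-to-end demo**: 8 + 8 participants, the full real/emoji designs
  on a −200…500 ms window, 1000 permutations, three contrasts,
  searchlight for the four-class contrast — must complete and be
  byte-reproducible under a fixed seed.

What passing these tests shows: the estimators are calibrated under
their own assumptions and recover what the generator injects. What it
does not show: the generator emulates the statistical structure the
analysis assumes (evoked class templates, participant/stimulus
nuisance, coloured noise) but not real data's artifacts, non-Gaussian
noise, volume-conduction physics, latency jitter across trials, or
image-driven low-level confounds — so synthetic recovery bounds
implementation correctness, not the method's behaviour on arbitrary
recordings.

## Known limitations

* FIF or other binary EEG container formats are not read or written;
  the portable bundle (gzipped binary array + TSV trial table + JSON
  header) is the interchange format.
* The 0.1 Hz high-pass edge is honoured as DC removal on epoch-length
  data, as discussed above.
* Cross-experiment "null" decoding with a fixed format code is not
  exchangeable at the unit level; the permutation test is calibrated
  for it only in the presence of realistic participant-level code
  variability. This is an inherent property of transfer designs with a
  single stimulus-set draw, not specific to this implementation.
* Onset estimates carry the smoothing half-window (17.5 ms) as an
  intrinsic backward uncertainty, and single-timepoint onsets (the
  default) are sensitive to isolated Bayes-factor crossings; `min_run`
  exists for conservative use.
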