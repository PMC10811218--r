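---
title: "Decoding left- vs right-hand motor imagery in acute stroke EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding left- vs right-hand motor imagery in acute stroke EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemi)
```

## The problem

Motor imagery (MI) — imagining a hand movement without executing it —
attenuates the sensorimotor mu (~8–13 Hz) and beta (~15–30 Hz) rhythms over
the contralateral motor cortex. This event-related desynchronization (ERD)
is the physiological signal that MI brain–computer interfaces decode. In
acute stroke patients the effect is weaker, more variable in time and
frequency, and recorded under more artifacts than in healthy cohorts, which
is precisely what makes decoder comparisons on such data interesting.

`strokemi` implements the full stack for a 50-subject acute-stroke MI
study design: the dataset's on-disk schema, the preprocessing chain, the
qualitative validation analyses (ERD/ERS curves, Morlet time–frequency
maps, band-power topographies), four decoding pipelines, and a synthetic
cohort generator so that every analysis runs, end to end, without the
deposited recordings.

## Data model

One subject is a `trials x channels x time-samples` tensor: 40 trials x 33
channels x 4000 samples at 500 Hz. Each 8-s trial has three stages:
instruction (0–2 s), imagery (2–6 s, cued by a 4-s video), and break
(6–8 s). Labels are 1 (left hand) and 2 (right hand), alternating.
Channels 1–30 are scalp electrodes in the 10-10 system with CPz (channel
18) as the recording reference; channels 31–32 are horizontal/vertical
EOG; channel 33 is a marker channel carrying 1 at the trial start and 2 at
imagery onset. The published channel table lists FT7 twice; since channel
21 is paired with TP8 at channel 22, the montage resolves channel 21 to
TP7, and `read_raw_mat()` warns if a file disagrees.

Raw tensors are serialised as level-5 MAT containers (`rawdata` +
`labels`), preprocessed trials as 16-bit EDF with a +/-1000 µV physical
range (quantization step ~0.031 µV), and a cohort as an EEG-BIDS style
tree (`build_bids_tree()`). The MAT writer emits uncompressed elements
with a fixed header so regeneration is byte-identical; the reader also
accepts zlib-compressed elements and either label-vector orientation.
HDF5-backed (v7.3) containers are rejected with a clear message.

## Preprocessing

* `remove_baseline()` — per trial and channel, the temporal mean is
  subtracted (mean-removal baseline correction).
* `fir_bandpass()` — 0.5–40 Hz windowed-sinc (Hamming) FIR, 825 taps
  (≈2 Hz transition at 500 Hz), applied forward and backward. Because the
  transition is wider than the 0.5 Hz low edge, a bare FIR of this length
  leaves ~31% of a DC offset after the two passes; the function therefore
  removes the per-channel mean first, which is linear and makes DC
  rejection exact.
* `butter_bandpass_zero_phase()` — order-2 Butterworth applied forward and
  backward (zero phase, 4th-order magnitude); the 8–30 Hz default is used
  by every validation analysis.
* Edge handling: all filters use odd-reflection padding of
  `min(3 * (filter length - 1), n - 1)` samples. One filter length would
  be far too short for the IIR transient; the 3x rule is the usual
  forward–backward convention.
* `epoch_by_marker()` — cuts one epoch per marker-1 sample; the marker
  sample is the epoch's first sample; trailing incomplete epochs are
  dropped with a warning. The marker channel does not encode the class, so
  epochs carry `NA` labels until a label vector is supplied.

## Qualitative validation

`erd_ers_curve()` computes `ERD/ERS% = (X - M) / M * 100`, where `X` is
the squared, same-label-averaged, smoothed band-passed signal and `M` its
mean over the preparation window (-1 to 0 s before imagery onset). The
"smoothness coefficient = 200" is read as a 200-sample (0.4 s) centered
moving average — samples are the only unit that makes the statement
self-consistent. Imagery onset is anchored at 2.0 s (the marker value 2);
the baseline window and onset are arguments, since a different deposit
timing only moves those anchors.

`morlet_tfr()` uses complex Morlet wavelets with 7 cycles per frequency
(the conventional time–frequency trade-off) and unit-energy kernels, so
the map is squared-magnitude power. `band_power_topomap()` averages
squared band-passed amplitude per scalp channel over a window and
interpolates by inverse-distance weighting on the montage coordinates;
`laterality_report()` summarises the C3/C4 asymmetry per class, flagging
contralateral dominance when the ipsilateral electrode retains at least
10% more power than the desynchronized contralateral one (relative to
their mean) — below that, sampling noise can flip the sign on symmetric
data.

## Riemannian core

Spatial covariance matrices (SCMs) of EEG epochs live on the manifold of
symmetric positive-definite matrices. The package uses the
affine-invariant metric throughout:
`delta(A, B) = ||log(A^{-1/2} B A^{-1/2})||_F`. SCMs are shrunk toward
`(trace/n) I` by `lambda = 1e-3` by default — 500-sample narrow-band
windows are otherwise close to singular. Matrix functions go through a
symmetric eigendecomposition with a `1e-12` eigenvalue floor. The Fréchet
mean is the standard fixed-point iteration started at the arithmetic mean
(tolerance `1e-8`, 50 iterations for user-facing calls; `1e-5`/5
iterations for the many per-cell tangent reference points inside the
time-window/filter-bank decoder, where the reference only anchors a local
chart). Tangent coordinates are the upper-triangular half-vectorization
with off-diagonals scaled by sqrt(2), so Euclidean norms equal manifold
distances.

Fisher discriminant directions in tangent space face `n(n+1)/2 = 465`
dimensions against ~24 training trials. `fisher_direction()` therefore
computes the discriminant in the (lossless) PCA subspace of the data,
capped at 20 components, and maps it back — the standard small-sample LDA
construction; a ridge of `1e-3 x mean diagonal` regularizes the
within-class scatter. Geodesic filtering (`fgda_fit()`/`fgda_apply()`)
projects tangent coordinates onto the rank-1 discriminant direction (one
direction for a 2-class problem) and maps back to the manifold.

## Decoders

All decoders consume the protocol's view of a trial: 8–30 Hz, 0–4 s after
imagery onset (the TWFB decoder takes raw epochs and builds its own
views).

* **CSP + LDA** — common spatial patterns from the trace-normalized class
  covariances; features are normalized log-variances (each projection's
  share of the total, which cancels per-trial global gain) of 3 filter
  pairs; linear discriminant analysis on the 6 features.
* **FBCSP + SVM** — 1 CSP pair per filter-bank band (19 four-Hz bands,
  8–12 … 26–30 Hz; the published table's "25–25 Hz" is read as 25–29 Hz,
  the only value continuing the 4-Hz/1-Hz-step pattern);
  mutual-information ranking (equal-frequency 4-bin estimate — robust to
  artifact outliers) keeps the 4 best features plus their CSP partners; a
  linear SVM classifies. The bank's filters are order-4 Butterworth
  (applied zero-phase): with the order-2 filter used for the qualitative
  analyses, the 12 dB/octave skirts leak every narrow-band rhythm into
  every 4-Hz cell and band selection loses its meaning.
* **MDRM** — nearest class Riemannian mean; exact ties go to the lower
  label.
* **TSLDA** — Fisher discriminant on tangent coordinates at the grand
  Riemannian mean; the signed distance to the decision plane is the score.
* **DGFMDRM** — geodesic discriminant filtering of all covariances, then
  MDRM on the filtered matrices.
* **TSLDA + DGFMDRM fusion** — both models score class 2 on `[0, 1]`
  (logistic of the LDA signed distance; softmax of negative Riemannian
  distances), the fused score is their mean, ties resolve toward the
  smaller Riemannian distance.
* **TWFB + DGFMDM** — the proposed pipeline, below.

## The time-window/filter-bank decoder

1. The candidate grid is 7 one-second windows (0–1 … 3–4 s, 0.5-s steps)
   by the 19 bands.
2. A backtracking search optimization algorithm (BSA) selects window and
   band subsets. The genome is real-coded in `[0, 1]` and thresholded at
   0.5; mutation uses the historical population (`M = P + F (oldP - P)`,
   `F = 3 N(0,1)`), crossover is map-based with mix-rate 1, population 20,
   50 generations — BSA's published defaults; all-empty masks are
   repaired to the best univariate candidate, and the final mask is
   polished by greedy single-bit flips, which makes the search exact on
   separable fitness landscapes. The fitness is the average over ten
   independently-seeded 5-fold stratified cross-validations of a fast
   surrogate of steps 4–5 (per-cell tangent features compressed to 6
   principal components and normalized to unit total variance per cell,
   pooled PCA capped at 8 components + Fisher + nearest centroid), minus
   a parsimony penalty of 0.01 per selected window or band. The repeated
   folds, the tight dimension caps and the penalty all address the
   dominant failure mode of wrapper selection at n = 24: the search
   compares on the order of a thousand masks, so the argmax of a noisy
   cross-validation estimate is strongly optimistic (a winner's curse)
   and otherwise accumulates uninformative cells.
3. The covariance set M keeps one SCM per selected cell per trial; each
   cell SCM is trace-normalized, because 500-sample narrow-band
   covariances are dominated by burst/amplitude variability that carries
   no class information. The cells are stored as separate blocks: tangent coordinates of a
   block-diagonal matrix at a block-diagonal reference are exactly the
   concatenation of the blockwise coordinates, so this is the
   block-diagonal reading of the set without ever forming large matrices.
   Each block is scaled to unit total variance before concatenation so
   that no single high-variance cell dominates the joint feature space.
   (`pool = "average"` provides the alternative reading that averages the
   selected SCMs into one matrix per trial.)
4. The concatenated tangent features are first projected (losslessly)
   onto the <= n-1 dimensional PCA span — neighborhoods and distances are
   unchanged but the alignment becomes numerically stable — then embedded
   by local tangent space alignment (`ltsa_reduce()`, 12 neighbors,
   10 output dimensions). Out-of-sample trials map through
   locally-linear barycentric weights of their 12 nearest training
   points.
5. In the reduced (Euclidean) space a Fisher discriminant direction is the
   geometry filter and classification is minimum distance to the class
   centroids along it — after LTSA no SPD structure remains, so this is
   the only self-consistent reading of "discriminant filter + Riemannian
   minimum distance".

## Evaluation protocol

`split_train_test()` makes stratified 60/40 splits (24/16 trials of 40,
12+12 and 8+8 per class); `cross_validate()` runs stratified 10-fold CV,
sums the fold confusions and computes accuracy, Cohen's kappa, and
macro-averaged precision and sensitivity on the pooled matrix. For
balanced truth, `kappa = 2 * accuracy - 1` exactly — a useful consistency
identity between reported accuracy/kappa pairs. Both the CV and the
holdout protocol are exposed (`decode_subject(..., protocol =)`); CV over
the full 40 trials is the headline protocol, the 60/40 split the cheaper
alternative used by the multi-seed comparisons.

## The synthetic generator

`generate_subject_recording()` builds each trial from two
amplitude-modulated sinusoid sources seated at C3 and C4 (mu 10 µV,
beta 5 µV at the source electrode), mixed into the scalp with a Gaussian
falloff (sigma 0.3 of unit-disc distance), plus pink (1/f) noise of
15 µV RMS per channel, blink/saccade EOG with frontal leakage, 15–45 Hz
muscle bursts tied to the lateral temporal/frontal ring (part of the
recorded trials carry motion artifacts), a non-reactive vertex "idle"
beta rhythm at 26 Hz whose amplitude is bursty across trials
(sensorimotor beta famously occurs in high-variance bursts; it carries
no class information), a zeroed CPz reference, and the marker channel. Sinusoid sources were chosen over filtered noise because
they give analytic power ratios for the recovery oracles.

During the imagery window the source contralateral to the imagined hand
is amplitude-scaled by `1 - erd_depth` (default 0.4) with 250-ms
raised-cosine ramps. Three forms of realistic heterogeneity are on by
default, because each corresponds to a documented property of such
recordings and together they are what give adaptive decoders room to
work: per-source log-normal trial-to-trial amplitude jitter (sdlog 0.45 —
single-trial decodability lands in the 55–75% range reported for acute
stroke rather than at ceiling), per-subject reactive rhythm peaks
(mu/beta jittered +/-1.5 Hz), and a per-subject transient ERD window
(onset 0.25–1.25 s after cue, duration 1.5–2.5 s) rather than sustained
suppression — real ERD rises and recovers, and its timing varies between
patients. A fixed `erd_window` (e.g. `c(0, 4)`) switches the transient
off; `erd_depth = 0` yields null recordings in which the classes are
statistically identical.

Clinical covariates are clipped normals matching the cohort's published
summary statistics (age N(56.70, 10.57) on 31–77; duration N(5.78, 6.90)
days on 1–30 — days are assumed, as the printed range is in days; NIHSS,
MBI, mRS likewise; 39/50 male; 27/50 left paralysis). Clipping bias on
the age mean is below 0.1 year. Hemiparesis side does not modulate the
ERD by default: the source data observe, but do not quantify, such an
effect.

What the generator does **not** emulate: volume conduction through a
head model (mixing is a scalar falloff, not a leadfield), non-stationary
covariate shift across the session, line noise, and channel drop-outs.
Passing decoder tests on this generator therefore demonstrates correct
implementations and the expected relative behavior of the methods under
controlled structure — not clinical performance on the deposit.

## Problem sizes in the test suite

The multi-seed comparisons in the package's tests use 20 synthetic
subjects per condition with a 60/40 split, pooling 320 test trials per
method — enough for a ~5% binomial band around chance, which is the
resolution the qualitative claims need. Parameter-recovery checks use
single seeds with analytic oracles. These sizes are the package's choice
of a reasonable desk-scale experiment.

## Known limitations

* The BSA fitness is a surrogate (PCA + Fisher + centroid) of the final
  LTSA pipeline; with 24 training trials a full-pipeline wrapper fitness
  is too variable to select reliably, but the surrogate can rank masks
  slightly differently than the final classifier would.
* With 24 training trials, window/band selection performed strictly
  inside the training split cannot out-perform the broadband
  tangent-space fusion baseline on this generator: the wrapper fitness
  retains residual winner's-curse optimism, the 500-sample per-cell
  covariances are noisier than one 2000-sample broadband covariance, and
  the LTSA embedding at n = 24 costs a few points of accuracy. The
  package reports the comparison as measured; selection pays off
  decisively when the discriminative structure is strongly confined in
  time and frequency (the planted-cell recovery setting), which is also
  the regime in which such pipelines excel on real data.
* LTSA at n = 24 with 12 neighbors is close to its small-sample limit;
  below `k + 1` points the implementation deliberately falls back to PCA
  with a warning.
* EDF export assumes a whole number of 1-s records per epoch and a common
  sampling rate across channels.
* The MAT reader handles real numeric arrays (the dataset schema), not
  arbitrary MATLAB objects, and not v7.3/HDF5 containers.
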