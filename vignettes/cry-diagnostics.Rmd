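---
title: "Methods: cepstral fusion and classification of newborn cries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cepstral fusion and classification of newborn cries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A newborn's cry carries information about their health: healthy newborns cry
with a fundamental frequency (F0) of roughly 400–600 Hz (about 450 Hz on
average) in expiratory bursts of 1–1.5 s, while several pathologies are
associated with low-pitched, hoarse, or unstable phonation. `crydx`
implements an automatic cry-screening pipeline that classifies individual
cry episodes — expiratory (EXP) or inspiratory (INSV) — as *healthy* or
*pathologic* from audio alone: cepstral feature extraction (MFCC and GFCC),
feature-level fusion by canonical correlation analysis (CCA), SVM and LSTM
classifiers with hyperparameter optimization, and a full diagnostic
evaluation suite.

Clinical cry corpora are private, so the package ships a seeded synthetic
generator that emulates the statistical structure such a pipeline assumes.
Everything downstream of the generator treats audio identically whether it
is synthetic or read from WAV + label files.

## The synthetic corpus

`generate_cry()` uses source–filter synthesis: a glottal pulse train at an
F0 drawn from the class band, with per-cycle jitter (F0 perturbation) and
shimmer (amplitude perturbation), filtered through three second-order
formant resonators (1.1, 3.3, 5.5 kHz, 200 Hz bandwidth — generic
infant-tract stand-ins, not physiological estimates), amplitude-enveloped,
and mixed with Gaussian noise at a target SNR. Samples are quantized to the
16-bit grid at generation, so WAV round trips are bit-exact.

Class defaults are the study conditions:

* healthy — F0 400–600 Hz, jitter 1%, shimmer 3%, EXP duration 1–1.5 s,
  SNR 20 dB;
* pathologic — F0 band lowered to 250–400 Hz, jitter 3%, shimmer 10%, and a
  0.3 probability of a subharmonic (alternate glottal cycles attenuated by
  0.55), operationalizing "low-pitched" and "hoarse" phonation. No
  quantitative acoustic model of specific pathologies exists; these values
  are fixtures chosen once to give a clearly separated but non-trivial
  two-class problem.
* INSV episodes are shorter (0.2–0.6 s) and breathier (SNR 10 dB).

Seeding is counter-based (`derive_seed()`): episode *i* of a corpus always
receives the same child seed regardless of generation order, so corpora are
pure functions of `(parameters, seed)`.

What the generator does **not** emulate: recording-channel variation,
reverberation and non-stationary hospital noise, inter-subject anatomical
variability beyond the per-class parameter draws, or the acoustics of any
particular pathology. Passing tests on synthetic data therefore demonstrate
that the pipeline's machinery is correct and that it recovers class
structure *when the assumed acoustic differences exist* — not that those
differences take this form in real newborns.

## Front end and cepstral features

Episodes are pre-emphasized (`y[t] = x[t] − 0.97·x[t−1]`; the coefficient is
the standard speech-processing default) and cut into 10 ms frames with 30%
overlap under a symmetric Hamming window. At 44.1 kHz this gives frames of
441 samples with a hop of `round(441 × 0.7) = 309` samples; trailing partial
frames are dropped, which is immaterial because features are averaged over
frames per episode. Pre-emphasis is applied identically before MFCC and
GFCC extraction (switchable with `preemph = FALSE`).

Each frame is zero-padded to a 512-point FFT. Band energies come from one
of two filterbanks:

* **Mel**: 13 triangular filters with centres equally spaced on the mel
  axis `M(f) = 1125·ln(1 + f/700)` between 0 Hz and Nyquist. Thirteen is
  deliberately small — it mirrors the diagnostic system this package
  reproduces — and `n_mel_filters` is configurable for users who prefer the
  conventional 20–40.
* **Gammatone**: 64 fourth-order gammatone magnitude responses,
  `(1 + ((f − fc)/b)²)^(−2)` with `b = 1.019·ERB(fc)` and
  `ERB(f) = 24.7(4.37 f/1000 + 1)`, centres equally spaced on the ERB-rate
  scale between 50 Hz and Nyquist, peak-normalized.

Energies are floored at `log_floor = 1e-10` (so silent frames stay finite),
logged, and decorrelated with an orthonormal DCT-II; coefficients
`m = 1..13` are retained, excluding the 0th (DC) term, which only carries
overall signal level. Two notational quirks are worth recording. First, the
delta ("derivative") filter is the standard local linear regression

\[
\Delta c_m(n) = \frac{\sum_{i=-T}^{T} i\, c_m(n+i)}{2\sum_{i=1}^{T} i^2},
\qquad T = 2,
\]

with edge frames replicated; a literal reading of some published delta
formulas puts \(\sum_i i = 0\) in the denominator, which is a typographical
artifact. Second, with a 13-filter mel bank the 13th retained DCT
coefficient is structurally zero (a 13-point DCT has only 12 non-DC basis
vectors); it is kept so that the stacked vector has the documented width.
Statics, deltas, and delta-deltas are stacked to 39 dimensions per frame;
per-episode vectors are the time average (deltas are computed on the frame
sequence first, then averaged — the only order in which deltas mean
anything).

## CCA feature-level fusion

Let `X` (GFCC) and `Y` (MFCC) be `39 × n` training matrices with columns as
episodes. After column-centring, the covariance blocks `Sxx, Sxy, Syx, Syy`
are formed, the within-view blocks are ridge-inflated
(`diag += 1e-6 · mean(diag)` — 39×39 covariances from a few hundred
episodes are near-singular), and the whitened cross-covariance
`Sxx^{-1/2} Sxy Syy^{-1/2}` is decomposed by SVD. This yields projection
pairs `Wx, Wy` whose successive projections are mutually uncorrelated, have
unit sample variance, and maximize pairwise correlation. Each pair is
oriented so the first nonzero element of the `Wx` column is positive, which
makes results reproducible across linear-algebra backends.

The fused representation stacks both projected views:
`Z = [Wxᵀ(X − mx); Wyᵀ(Y − my)]`. The default retains `d = 30` canonical
pairs, so two 39-dim views fuse to **60** dimensions; `d` is a configuration
knob, and 30 is simply the default that produces the documented fused
width. The transform is fitted on training episodes only and frozen — test
episodes and, in the LSTM path, individual frames are projected with the
fit-time centring offsets. Using one per-episode-fitted transform for both
the averaged (SVM) and frame-sequence (LSTM) paths keeps the two paths
consistent.

## Classifiers

**SVM.** A soft-margin SVM with the Gaussian kernel
`k(x, x′) = exp(−‖x − x′‖²/(2s²))`, where `s` is the kernel scale and the
box constraint is the misclassification penalty — the two tuned
hyperparameters. Features are standardized inside the model with
training-set statistics. The implementation wraps libsvm (via `e1071`);
predictions are deterministic and order-invariant.

**LSTM.** One to three stacked tanh LSTM layers over the per-frame feature
sequence; the hidden state at the final valid timestep feeds a dense layer
with 2-way softmax under cross-entropy. Sequences are the natural input for
a recurrent model (a single averaged vector would make the recurrence
vacuous); variable lengths are handled by padding with carry-through
masking. The trainer is written in RcppArmadillo with batched BPTT and Adam
(batch size 128, β = 0.9/0.999, no weight decay — unspecified upstream,
recorded here as the package's defaults). A stratified 20% of the training
sequences is held out and scored every 10 optimizer iterations ("iterations"
read as optimizer steps, not epochs); the final refit after hyperparameter
search uses the full training set with no holdout. All randomness (weight
init, shuffling, the holdout split) derives from `cfg$seed`, so training is
bit-reproducible. The decision threshold is 0.5 with exact ties resolved
toward *pathologic*: a screening system should not miss a sick newborn.

The admissible hyperparameter ranges are: initial learning rate
`[0.001, 1]` on a log scale, hidden units `[2, 39]`, epochs `[100, 500]`,
depth `[1, 3]`. `lstm_config(strict = FALSE)` relaxes only the range check
(sanity checks remain) so that scaled-down epoch budgets can be used in
simulation studies; `experiment_config()` infers strictness from the
requested epoch range.

In the pipeline, LSTM input sequences are decimated by `lstm_stride`
(default 4): 10 ms frames with 30% overlap are heavily redundant, and the
class signal lives in the slowly varying spectral envelope, so striding
shortens the recurrence roughly fourfold without discarding usable
structure. Set `lstm_stride = 1` to keep every frame.

## Hyperparameter optimization

Three methods share one trial/result interface, all maximizing validation
accuracy:

* `grid_search()` — the full Cartesian grid, log-spaced where a parameter
  is log-scaled, evaluated in a fixed order; exact argmax.
* `random_search()` — i.i.d. draws uniform on each parameter's scale.
* `bayesian_search()` — a Gaussian-process surrogate on the unit-cube
  rescaling of the space (squared-exponential kernel; length-scale from
  {0.1, 0.2, 0.5, 1, 2} and noise from {1e-6, 1e-4, 1e-2} by marginal
  likelihood; objectives standardized), expected-improvement acquisition
  maximized over 512 random candidates plus 32 local perturbations of the
  incumbent, after a 5-point Latin hypercube initialization. Duplicated
  proposals are re-sampled once. Failed trials (non-finite objective) are
  recorded and excluded from the surrogate.

The surrogate and acquisition are the standard instantiation of sequential
model-based optimization; nothing more exotic is warranted at a budget of
30 evaluations. The SVM search ranges are log-uniform `[1e-3, 1e3]` for
both box constraint and kernel scale — conventional wide RBF-SVM ranges.
Integer parameters are relaxed to continuous and rounded at evaluation.

## Evaluation

The corpus is split 70/30 (stratified; the training total is
`round(0.7 n)`, apportioned across classes by largest remainder, so
balanced corpora of 6010 and 7240 episodes split 4207/1803 and 5068/2172).
Sample-level stratified splitting is the default; because real corpora
contain up to a handful of recordings per newborn, a `group_by_subject`
option keeps all episodes of a subject on one side, at the price of less
exact split sizes. Model selection uses stratified 5-fold cross-validation
on the training set for the SVM and the 20% holdout for the LSTM; the test
set is touched exactly once, after the final refit.

With *pathologic* as the positive class, the report derives accuracy,
recall (sensitivity), specificity, precision, NPV, and F-score (harmonic
mean of precision and recall) as percentages, plus the Matthews correlation
coefficient

\[
\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP{+}FN)(TN{+}FP)(TP{+}FP)(TN{+}FN)}} \in [-1, 1],
\]

with an acceptance gate at **MCC ≥ +0.50**. Ratios with zero denominators
are reported as 0 and listed in an `undefined` field rather than raised, so
batch tables stay total.

## Numerical choices and degenerate inputs

* FFT size 512 — next power of two above the 441-sample frame.
* `log_floor = 1e-10` on band energies; all-zero frames produce finite
  cepstra rather than errors.
* CCA ridge `1e-6 × mean(diag)`; `ridge = 0` on rank-deficient covariances
  raises an error that recommends a positive ridge.
* Canonical-pair sign convention as above; correlations clamped to [0, 1].
* Episodes shorter than one frame, or than the `2T + 1` delta context, are
  rejected with explicit errors.
* Hop rounding `round(L(1 − overlap))` keeps the realized overlap closest
  to the nominal 30%.
* Pre-emphasis accepts the closed interval [0, 1]; 1 is the pure
  first-difference boundary case.
* All split/fold/search randomness is seeded; every pipeline stage derives
  a child seed from the experiment seed with `derive_seed()`.

## Problem sizes used in the shipped studies

The package's own test and acceptance studies run at 200 episodes per class
(EXP defaults) for the end-to-end arms, with the Bayesian budget of 30
evaluations and LSTM epochs scaled to the 5–15 range at stride 4; the HPO
method comparison uses 60 episodes per class with overlapping class F0
bands (pathologic 330–500 Hz) over 20 replicate seeds at an equal budget of
16 evaluations per method. These sizes were chosen as the smallest at which
the studied effects are stable.

## Known limitations

* The pathologic acoustic model is a fixture, not an estimate; absolute
  performance numbers on synthetic corpora say nothing about clinical
  performance.
* The mel bank's 13th cepstral coefficient is structurally zero (see
  above); downstream standardization guards against the zero-variance
  column.
* CCA is linear; kernel or deep variants, and decision-level fusion, are
  out of scope.
* The GP surrogate assumes a stationary smooth objective; heavily
  multimodal objectives at larger budgets would justify a more careful
  acquisition optimizer.
* Subject-wise splitting is provided but not the default; with synthetic
  subjects assigned round-robin it makes little difference, but on real
  corpora subject leakage is a genuine risk worth enabling it for.
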