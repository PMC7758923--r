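---
title: "Detecting the end of postictal generalized EEG suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the end of postictal generalized EEG suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(pgesdetect)
```

## The detection problem

After a generalized tonic-clonic seizure (GTCS), scalp EEG often collapses
into *postictal generalized EEG suppression* (PGES): a near-flat,
low-amplitude trace. Prolonged PGES is a reported risk marker for Sudden
Unexpected Death in Epilepsy, so its duration matters clinically, but the
end of suppression — the onset of the first burst of *intermittent
slow-wave* (ISW) activity — is currently annotated by expert visual review,
with imperfect inter-rater agreement.

This package frames automatic detection the way a real-time monitor must:
slide a fixed 10 s window along the post-seizure recording, and at each
step ask a classifier whether the window has *reached* the end of
suppression. Probabilities are emitted every 100 ms using only samples up
to the current time (no retrospective review), and a detection is accepted
as timely if it falls within a 10 s latency period after the true
transition.

## Signal preparation

Recordings carry 13 standard 10-20 electrodes (Fp1, Fp2, O1, O2, F7, F8,
T7, T8, P7, P8, Fz, Cz, Pz). Preparation follows clinical review practice:

* **Bipolar montage.** Ten adjacent-electrode differences (Fp1-F7, F7-T7,
  T7-P7, P7-O1, Fp2-F8, F8-T8, T8-P8, P8-O2, Fz-Cz, Cz-Pz) suppress the
  common reference and emphasize local activity.
* **Rate alignment.** Clinical acquisition rates vary (150-256 Hz); every
  recording is resampled to a single 200 Hz grid with polyphase rational
  resampling (anti-aliased, deterministic). Per-channel mixed rates within
  one file are rejected rather than silently handled — scalp montage
  channels share a rate in practice.
* **Optional Hann denoising.** A unit-sum raised-cosine moving average
  (default 11 samples, 55 ms at 200 Hz) with reflection padding; the tiny
  edge-induced mean shift is subtracted again so smoothing is exactly
  mean-preserving. No band-pass or notch filter is applied by default,
  since the underlying protocol states none.

Amplitudes are microvolts end to end. Time is seconds from recording
start; windows are half-open `[start, start + window)`.

## Crops and labels

A `crop_spec()` fixes the operating point: window 10 s, stride 100 ms,
latency 10 s. Windows start on the grid 0, stride, 2·stride, … and a crop
is labeled **positive iff its end reaches or passes the annotated end of
suppression** (inclusive boundary). Crops whose end lies beyond
`pges_end + latency` are excluded from datasets entirely — training data
contain no content past the accepted latency period, and truncating would
break the fixed input length. Within a recording the label sequence is
therefore 0…0 1…1, and the retained count has the closed form
`count_crops(min(duration, pges_end + latency), spec)`.

Train/test splitting is at the *recording* level so no recording
contributes crops to both sides; the train size is `floor(fraction × n)`,
which reproduces a 134/34 partition of 168 recordings at 80/20.

## Two detector families

`pges_detector()` is the single fitting entry point and returns a classed
object with `print`, `summary`, `coef`, `predict` and `plot` methods.

**Feature classifiers** (`random_forest` via ranger,
`gradient_boosted_trees` via xgboost) use a per-crop feature bank computed
per montage channel: population variance/skewness/kurtosis; periodogram
band powers, power spectral intensity and relative power in the standard
delta/theta/alpha/beta/gamma bands; peak and median frequency; total
energy; Petrosian fractal dimension; SVD entropy of a delay embedding
(dimension 20, delay 1, the convention of the widely used EEG feature
libraries); second-half/first-half temporal ratios of RMS, delta power and
line length; plus Pearson correlations of all 45 montage pairs. Channels
are demeaned first (EEG is AC-coupled), making every feature invariant to
constant offsets. Degenerate (flat) inputs yield flagged sentinels rather
than NaN so tree models train unimpeded. Features are z-scored with
means/sds estimated on training crops only. The bank is configurable by
family via `feature_config()`; its default layout is documented by its
column names, and it does not claim to replicate any particular
competitor's 127-feature list, which was published elsewhere.

**The compact CNN** (`cnn_config()`) works on raw 10 × 2000 crops:

1. temporal convolution, kernel length 18 samples (90 ms at 200 Hz),
   shared across montages — these filters learn band-intensity detectors;
2. spatial convolution whose kernels span all 10 montages (101 filters by
   default), capturing scalp topography;
3. batch-norm, ReLU, average-pool (×8), dropout;
4. depthwise temporal convolution (multiplier 2, kernel 16) and pointwise
   1×1 convolution (16 maps) to aggregate spatio-temporal structure
   cheaply;
5. batch-norm, ReLU, average-pool (×8), dropout;
6. a fully connected sigmoid output: the probability that the crop reaches
   the end of PGES.

Training minimizes binary cross-entropy with Adam (default 1e-3, batch
64), with inverse-frequency class weights countering the negative-heavy
crop imbalance. A recording-level validation split monitors per-epoch AUC
and the best-validation weights are retained. The implementation is
self-contained C++ (RcppArmadillo) so training is CPU-only, fast, and
bit-reproducible from the seed — initialization, shuffling and dropout all
derive from one RNG.

Where the underlying description was ambiguous, the reading is: "filter
size 18" = temporal kernel *length*; "filter size 101" = spatial filter
*count* (a length-101 spatial kernel is impossible over 10 montages). Both
are one configuration change apart. Pooling factors, the depthwise kernel
length, epoch count, learning rate and dropout were unstated upstream;
the defaults above are this package's choices and all are exposed in
`cnn_config()` / `cnn_train_config()`.

## Continuous inference and evaluation

`probability_trace()` evaluates the detector at every stride position over
the *whole* recording (the latency exclusion is a training-set rule only).
Timestamps are window **end** times, which is what makes the trace causal:
the value at time *t* uses samples up to *t* only — verified by a test
that mutates all samples after a cut point and checks earlier trace values
are bit-identical.

The upstream protocol stops at probabilities; calling a single onset time
requires a rule, which is this package's addition: `onset_rule()` detects
at the earliest grid time where the probability reaches a threshold
(default 0.5) and stays there for k consecutive points (default 3, 300 ms
at the paper-default stride). Raising the threshold can only delay
detection (tested property).

`evaluate_cohort()` reports the pooled per-crop AUC over all test crops
(with the per-recording mean as a secondary statistic — pooling matches
the per-crop framing of the task), the detection rate within the latency
period, latency error quantiles, and a false-alarm rate. A detection
*before* the true end counts as a false alarm and the recording as
incorrect: the latency period only bounds lateness, and earliness handling
had to be decided here. An absent detection is likewise incorrect. AUC is
the Mann–Whitney statistic with ties counted one half, computed from
average ranks and tested against literal pair enumeration.

## The synthetic cohort

Real post-GTCS recordings are protected health information, so the package
ships a seeded simulator that emulates what the pipeline needs: 13
electrodes, 5 minutes by default, acquisition rate drawn from {150, 200,
256} Hz; a suppression phase of band-limited noise (RMS 3 µV by default);
and, from a known transition time, bursts of delta-band (0.5–4 Hz)
slow-wave activity (RMS 30 µV during bursts). Intermittency is a two-state
renewal process with exponential dwell times (mean burst 3 s, duty 0.6).
Because the clinical annotation *is* the onset of the first slow-wave
burst, the renewal process always opens with a burst at the transition.
Slow activity is drawn independently per electrode so bipolar differences
retain it. Optional artifacts add coarse scalp realism without claiming
physiology: slow (<1 Hz) Gaussian transients on Fp1/Fp2/F7/F8 (eye
movement), a global 0.3 Hz oscillation (breathing), and broadband >20 Hz
bursts on F7/F8/T7/T8 (muscle).

What the simulator does **not** model: ictal morphology before
suppression, gradual (non-point) transitions, electrode pops,
non-stationary artifact statistics, or inter-patient variability in
spectra. Passing the recovery benchmarks below therefore shows the
pipeline's machinery is correct and sensitive at clinically plausible
contrasts — it does not certify clinical performance, which in the source
work was measured on private data (AUCs there are not reproducible here
and are not targeted).

## Benchmarks, problem sizes and numerical choices

The standard recovery benchmark used in the tests and the acceptance
script: 40 artifact-free recordings of 120 s (transitions sampled in
(20, 90) s), 80/20 recording split, dataset crops at 1 s stride,
continuous inference at 0.5 s stride, random forest with 300 trees, and a
reduced CNN (4 temporal / 8 spatial filters, 5 epochs). These sizes are
the package's desk-scale choices — they keep a full run in minutes on one
CPU while leaving the operating point (10 s window, 10 s latency)
untouched; the simulator's defaults (300 s, 100 ms stride) remain the
study conditions. On this benchmark the forest reaches test AUC ≈ 0.99
and detects every held-out transition within a fraction of a second; the
reduced CNN exceeds 0.95; a permuted-label control collapses to chance;
and shrinking the slow-wave amplitude toward the suppression floor (9 →
4.5 → 3.3 µV over a 3 µV floor) strictly degrades AUC. All of these are
computed by the test suite and `scripts/acceptance.R`, not quoted.

Numerical details worth knowing:

* The boundary crop (end exactly at `pges_end`) is positive — "reaches"
  is inclusive; grid comparisons use a 1e-9 s guard against floating
  stride accumulation.
* The crop start grid is anchored at t = 0 of each recording (unstated
  upstream; any anchor within one stride is equivalent).
* EDF quantization is 16-bit against per-channel observed extremes;
  round-trips are exact to one quantization step. Flat channels get a
  widened physical range to avoid zero-division.
* SVD entropy demeans its input and computes singular values via the
  eigen-decomposition of the 20×20 Gram matrix (numerically equivalent to
  the SVD, much faster on 2000-sample crops; normalized singular values
  below 1e-15 are dropped from the entropy sum).
* Constant/zero series: Petrosian FD is exactly 1, SVD entropy 0,
  spectral features 0 with a degenerate flag.
* Batch norm uses batch statistics during training and running averages
  (momentum 0.1) at inference, so predictions are independent of batch
  composition; the final batch of an epoch is skipped when it holds fewer
  than two crops.

A caution about negative controls: the probability forest is not a valid
model for a permuted-label control on this kind of data. Its leaf
estimates under label noise vary with local sample density, and on
separable, imbalanced crop sets density tracks the true class — so a
forest trained on permuted labels still *ranks* slow-wave crops above
suppression crops (null AUC far from 0.5 with zero label signal; the
effect reproduces on iid Gaussian toy data with outlier-positive
geometry, and class-balanced resampling merely flips its sign). The
package's permuted-label control therefore uses the boosted-trees
classifier, whose logistic-loss fit has a clean permutation null, and
averages over several permutations (three in the test suite, five in the
benchmark script) because pooled AUC over crops from a handful of
recordings has a wide null distribution.

## Known limitations

* The point-transition assumption: real PGES often ends gradually; the
  simulator and the labeling rule both inherit the single-time-point
  annotation convention.
* Only the 10-20 scalp system and single-rate recordings are supported;
  no ICA or artifact-subspace removal — bipolar subtraction is the only
  re-referencing.
* The CNN is intentionally compact; it is not the place to look for
  state-of-the-art raw-EEG accuracy, and no hyperparameter search is
  provided.
* Class rebalancing is limited to loss weighting; there is no synthetic
  minority oversampling.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(duration_s = 120, sampling_rate_hz = c(150, 200, 256))
coh <- simulate_cohort(12, cfg, seed = 7)
mrecs <- lapply(coh$recordings, function(r)
  resample_montage(to_bipolar_montage(r$recording), 200))
names(mrecs) <- coh$manifest$recording_id

sp <- split_recordings(coh$manifest$recording_id, 0.8, seed = 7)
crops <- lapply(mrecs, enumerate_crops, spec = crop_spec(10, 1, 10))
fit <- pges_detector(bind_crops(crops[sp$train]), "random_forest", seed = 7)
summary(fit)

ev <- evaluate_cohort(fit, mrecs[sp$test], crop_spec(10, 0.5, 10))
ev
```
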