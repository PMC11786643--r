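---
title: "Directed connectivity images from joint EEG-ECG recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity images from joint EEG-ECG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Everything in this package derives from one object: a joint multivariate
autoregressive (MVAR) model of an analysis window holding all channels at
once,

$$x(n) \;=\; \sum_{r=1}^{P} A_r\, x(n-r) \;+\; e(n),$$

where $x(n)$ stacks the 32 EEG and 3 ECG channels, the $A_r$ are $m \times m$
lag-coefficient matrices (entry $(i,j)$: influence of channel $j$, $r$ samples
back, on channel $i$), and $e(n)$ is white innovation noise with covariance
$\Sigma$. Three directed-coupling estimators are read off this model:

* **Pairwise Granger causality (GC).** For an ordered pair (target $x$,
  source $y$), compare the residual variance of a univariate AR($P$) model of
  $x$ against the bivariate VAR($P$) of $(x, y)$:
  $GC_{y \to x} = \ln (V_{x|\bar x} / V_{x|\bar x, \bar y})$, clipped below at
  zero. Unbounded above; zero means the source's past adds nothing.
* **Partial directed coherence (PDC).** With
  $\bar A(f) = I - \sum_r A_r e^{-i 2\pi (f/f_s) r}$,
  $\pi_{ij}(f) = |\bar A_{ij}(f)| \big/ \sqrt{\sum_m |\bar A_{mj}(f)|^2}$.
  Column-normalized; isolates *direct* influences; $\sum_i \pi_{ij}^2 = 1$.
* **Directed transfer function (DTF).** With $H(f) = \bar A(f)^{-1}$,
  $DTF_{ij}(f) = |H_{ij}(f)| \big/ \sqrt{\sum_m |H_{im}(f)|^2}$.
  Row-normalized; transmits direct *and cascaded* influence because the
  inverse mixes paths.

Per window, per frequency band (delta 0.5-4, theta 4-8, alpha 8-13, beta
13-30, gamma 30-45 Hz), the band-averaged $35\times 35$ coupling matrix
(rows = target, columns = source, everywhere in this package) is rendered as
a colour raster image, and a 4-class image classifier is evaluated with
stratified 5-fold cross-validation.

## Processing chain and its parameters

Fixed stage order: band-pass filter, decimate, common-average re-reference
(EEG only), segment into 5000 ms windows with 50% overlap, flag each window
with a variance-ratio stationarity test. Defaults and why:

* **Band edges 0.5-45 Hz.** Spans all five analysis bands; 45 Hz keeps the
  gamma band below the decimated Nyquist.
* **Filter: zero-phase, FFT-domain, Butterworth-magnitude, effective order
  24.** No IIR filter-design library is assumed; the filter multiplies the
  spectrum by the forward-backward magnitude response of an analog
  Butterworth band-pass prototype, which is exactly zero phase (no lag
  distortion of directed estimates) and unconditionally stable at any order.
  The steep default is deliberate: with the upper edge at 45 Hz, 50 Hz mains
  sits only 5 Hz into the stop band and an order-4 forward-backward IIR
  response would pass roughly 38% of its amplitude; the order-24 magnitude
  response passes under 5% including edge transients. An optional mains
  notch is available.
* **Decimation to 128 Hz** (integer factor from 256 Hz) after an
  anti-alias low-pass at $0.45 \cdot f_s^{new}$: halves MVAR cost, keeps
  45 Hz below Nyquist.
* **Stationarity test:** each channel's window is split into halves and the
  variance ratio (larger over smaller) is referred to a two-sided F
  distribution at $\alpha = 0.05$; the window is flagged stationary when at
  least 90% of channels pass. Under the null this rule passes
  $P(\mathrm{Bin}(35, 0.05) \le 3) \approx 0.90$ of windows - an expected
  9.5% false-alarm rate, the price of per-channel sensitivity. Flagged
  windows are *kept* by default (`drop_nonstationary = TRUE` to exclude),
  since exclusion rules are an analysis choice, not a property of the data.
* **MVAR order 10** by default for the joint fit (AIC-guided selection is
  available via `select_order_aic()`; 10 is the conventional order for this
  windowing). **Mean removal** per channel precedes fitting.
* **Frequency grid 0.25 Hz.** At least 19 grid points in the narrowest band;
  when only some bands are requested, only in-band grid points are
  evaluated (the band average is identical).

## Identifiability after common-average re-referencing

Common-average re-referencing subtracts the instantaneous EEG mean from
every EEG channel, so the 32-channel EEG block has rank 31 *exactly*: for
each lag one direction of the joint regression is undetermined. `fit_mvar()`
treats exact rank deficiency as an error by default (it names the channels
involved, which catches duplicated electrodes); the pipeline path passes
`singular_ok = TRUE`, which resolves the ambiguity by pinning the aliased
directions to zero via pivoted QR. Fitted values, residuals, the residual
covariance and all diagnostics are unique regardless of this choice; only
the coefficient *representative* is pinned, deterministically. Regularized
estimation would hide rather than resolve the ambiguity and is deliberately
not offered.

## Model validation

* **Stability:** companion-matrix spectral radius < 1. Windows whose joint
  fit is unstable are logged and skipped (no spectral quantity exists for
  them).
* **Residual whiteness:** per-channel Ljung-Box statistic on residual
  autocorrelations up to 20 lags; the minimum p value over channels is
  reported, 0.05 is the advisory threshold. On residuals of a correctly
  specified fit the statistic is conservative (fitting absorbs
  autocorrelation), so failures indicate real misspecification.
* **Consistency:** simulate a trace of the window's length from the fitted
  model and compare stacked auto/cross-correlations up to lag $P$:
  $100\,(1 - \|R_{data} - R_{sim}\|_F / \|R_{data}\|_F)$, clipped below at
  0; 80% is the conventional advisory threshold (logged, not blocking).

## Granger causality per band

GC is a time-domain quantity; per-band GC is obtained by zero-phase
band-pass filtering the window to the band and then computing pairwise GC.
This is the simplest defensible reading of "GC per frequency band", but
filtering can bias GC (it reshapes the innovation spectrum), so per-band GC
values should be compared within a band, not across bands. The bivariate
(pairwise) formulation is used throughout - it detects cascaded influence as
well as direct influence, unlike conditional multivariate GC, which is out
of scope.

## Imaging choices

* **Fixed scaling.** PDC/DTF live in $[0,1]$ and are clamped as-is; GC is
  mapped through the fixed monotone $1 - e^{-v}$. Nothing is min-max
  normalized per image: per-image normalization would erase exactly the
  between-class intensity differences the classifier must see.
* **Fixed colormap.** A 256-entry analytic blue-to-red lookup table ships
  with the package so rendering is bit-reproducible and independent of any
  plotting library.
* **Nearest-neighbour upscaling** preserves matrix cells as uniform blocks;
  a rendered image is exactly invertible back to its matrix through the
  colormap (to 1/255). Because cells are uniform, rendering at the native
  $35 \times 35$ resolution carries the same information as $224 \times
  224$; the default test pipeline uses the native size and the classifier
  block-averages whatever size it receives.
* PNG output is written by a minimal built-in codec (8-bit RGB, row filter
  0, metadata in tEXt chunks) - again to keep the artifact chain free of
  system-dependent libraries and bit-reproducible.

## Classification

The classifier backend is a contract: `fit_backend(backend, images, labels)`
and `predict_proba(handle, images)` returning per-class probabilities. Two
backends ship:

* **`small_cnn`** (default): a from-scratch 3-block convolutional network
  (3x3 same-padding convolutions, ReLU, 2x2 average pooling; softmax head)
  in base R, trained with ADAM on cross-entropy. Inputs are block-averaged
  to 35 pixels and centered. Defaults (lr $10^{-2}$, batch 32, 15 epochs)
  were chosen for desk-scale datasets of a few hundred to a few thousand
  images; training is deterministic given the seed.
* **`transfer_backend`**: the architecture-agnostic hook for a user-supplied
  pretrained network. The supplied object must expose penultimate-layer
  features and a final fully connected layer to replace; the adapter trains
  a fresh 4-unit softmax head with the standard fine-tuning recipe
  (ADAM, initial learning rate $8 \times 10^{-4}$, mini-batch 32, gradient
  decay factor 0.99, at most 30 epochs, cross-entropy). Features are
  standardized so the fixed learning rate is meaningful regardless of the
  network's feature scale. No pretrained weights ship with the package.

Two metric conventions deserve emphasis because they are easy to misread:

* The **average accuracy** is the mean of one-vs-rest accuracies
  $(tp_i + tn_i)/(tp_i+tn_i+fp_i+fn_i)$ over the four classes. Its chance
  level on balanced data is **0.625**, not 0.25: a random predictor gets
  most "rest" decisions right.
* The reported **AUC** is $\tfrac12(\mathrm{sensitivity} +
  \mathrm{specificity})$ of the *hard* classifier per class - algebraically
  the one-vs-rest balanced accuracy, not a ranking ROC area. A conventional
  probability-ranking ROC-AUC is reported alongside, clearly labeled
  `roc_auc_per_class`, for comparability with studies that plot ROC curves.

Folds are stratified by class by default (window mode) with a logged warning
that window-mode splitting lets one subject's windows appear on both sides
of a fold boundary; `mode = "subject"` assigns whole subjects to folds.

## What the synthetic generator emulates - and what it does not

`generate_emotion_dataset()` builds one ground-truth 35-channel MVAR system
per emotional class: 32 EEG-like channels are resonant AR(2) oscillators
(10 Hz, pole radius 0.9 - alpha-band energy, with small deterministic
per-channel jitter), the 3 ECG-like channels share a 1.1 Hz quasi-periodic
AR driver, and class-dependent directed EEG-ECG edges are added at lag 1
with a single coupling-strength knob (default 0.4, the stated world for the
end-to-end benchmark; 0 makes all classes statistically identical). The
profiles mirror the qualitative class contrasts reported for real data:
happiness couples most EEG channels bidirectionally with the third ECG lead,
disgust couples the second lead broadly, fear has weak heart-brain coupling,
and sadness makes the prefrontal channels Fp1/Fp2 hubs. Every emitted system
is rescaled to companion spectral radius at most 0.95 (lag-$r$ matrices
scaled by $c^r$, which scales companion eigenvalues exactly), so stability
is a construction guarantee, not a sampled property.

Deliberately *not* emulated: PQRST waveform morphology, heart-rate
variability, volume conduction, electrode noise spectra, artifacts. The
estimators consume second-order statistics only, so AR-level realism keeps
the ground truth exact and analyzable. Consequently a green end-to-end test
establishes that the estimator-classifier chain recovers *planted
second-order directed structure*; it does not establish performance on real
recordings, whose nuisance structure is far richer.

One estimator-variance caveat found while validating the generator: with
5000 ms windows at 128 Hz, the joint order-10 fit estimates 350 coefficients
per equation from 630 observations, and the narrowband EEG oscillators make
lagged regressors nearly collinear within a channel. Individual off-diagonal
DTF entries are therefore dominated by estimator noise (the planted
EEG-to-ECG edge contrast between happiness and fear, clear in the
ground-truth DTF, is invisible in the single-entry window estimates), while
the *pattern* across the whole matrix - diagonals, ECG self-transfer,
ECG-to-EEG block - separates the classes well, which is what the image
classifier uses. This is documented rather than "fixed": the window length
and order are the stated operating point, and regularization is out of
scope.

## Numerical and degenerate-input conventions

* Spectral matrices are inverted per frequency; a singular $\bar A(f)$
  (unit-root model) is an error naming the frequency.
* PDC with a zero column norm or DTF with a zero row norm (all-zero model
  row/column) is an error rather than 0/0.
* Negative GC estimates (possible in finite samples) are clipped to 0; the
  GC diagonal is 0 by convention.
* Trailing partial windows are dropped, never padded.
* Zero-variance channels fail fitting and the stationarity test explicitly,
  with the channel named.
* All randomness flows from explicit integer seeds; identical seeds and
  configuration give bit-identical connectivity matrices, PNG bytes and
  cross-validation reports.

## Known limitations

* Pairwise GC (not conditional) inflates cascaded paths; this matches the
  bivariate formulation implemented here but limits causal interpretation.
* The paper-scale headline numbers (97%+ accuracy on gated human data with
  ImageNet-pretrained networks) are out of reach by design: no external
  data, no pretrained weights. The end-to-end benchmark is a synthetic
  recoverability test, not a replication.
* The PNG reader supports exactly the subset the writer emits (8-bit RGB,
  filter 0); it is not a general PNG decoder.
* EDF/BDF reading assumes a uniform sampling rate across signals and skips
  annotation channels.
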