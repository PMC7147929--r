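---
title: "Localizing the subthalamic nucleus from microelectrode recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing the subthalamic nucleus from microelectrode recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During deep-brain-stimulation (DBS) surgery for Parkinson's disease, a
permanent electrode must be placed inside the subthalamic nucleus (STN), a
structure only 4--7 mm across. Before implantation, microelectrodes are
advanced along a planned track and extracellular voltage is recorded for
about ten seconds at each depth: from 10 mm above the planned target in 1 mm
steps, then in 0.5 mm steps from 5 mm above the target onward. The STN
announces itself electrophysiologically — multi-unit firing becomes denser
and the background amplitude rises — and the surgical team listens and looks
for that change to call the *dorsal* (entry) and *ventral* (exit) borders.

`merstn` implements an objective version of this judgement: per-epoch
features (three families), binary inside/outside classification (classical
learners, a weighted-majority-vote ensemble, and a deep feed-forward
network), and conversion of the per-depth calls into border depth estimates.
Because no public MER dataset of this kind exists, the package ships a
synthetic-MER simulator that reproduces the statistical structure the
classifiers rely on, with known ground-truth borders so that localization
error is measurable in millimetres.

## The simulator: what it emulates and what it does not

`sim_config()` defines the study conditions. Each trajectory draws a true
dorsal border uniformly from [-2, 0] mm and a ventral border from [+2, +4] mm
(depths are signed mm relative to the surgical target, negative above), giving
nucleus spans of 2--6 mm, consistent with STN anatomy. Every scheduled depth
yields one epoch:

* **outside the STN** — a single-unit Poisson spike train at 15 Hz (absolute
  refractory period 2 ms) on Gaussian background noise of SD 1.0;
* **inside the STN** — three pooled units totalling 60 Hz on background
  noise of SD 2.5.

Spikes are zero-mean biphasic waveforms (difference of offset Gaussians,
about 1 ms wide) with lognormal amplitudes (mean 6, CV 0.25). The trace then
passes through the acquisition chain used clinically: a zero-phase
Butterworth bandpass (500--5000 Hz, order 4) and a 60 Hz notch (Q = 30),
with optional 8-bit quantization. The firing-rate and noise contrasts are
assumptions, not published values — the source studies report no
quantitative inside/outside statistics — chosen so that the synthetic
problem is clearly learnable but not degenerate at short epoch lengths.

The simulator deliberately omits: gradation near borders (labels switch
crisply at the drawn border), other nuclei along the track (substantia
nigra, zona incerta), 1/f field potentials, electrode drift, and
patient-to-patient variability. Passing tests on this data therefore
demonstrates that the pipeline recovers a *planted* inside/outside contrast
end to end; it does not certify clinical performance, where class overlap
and non-stationarity are the real difficulty.

## Feature spaces

Three families are extracted per epoch, each usable on its own:

* **Conventional (10 features)** — spike count, ISI standard deviation,
  pause index (count ratio of ISIs above/below 50 ms), pause ratio
  (duration ratio of the same split), RMS amplitude, spiking rate, Teager
  energy, zero crossings, curve length, and the spike threshold itself.
  Spikes are detected by crossings of three sample standard deviations,
  with each event snapped to the local extremum within ±0.5 ms and a 2 ms
  dead time. These features are conventionally z-scored per trajectory
  (`normalize_by_trajectory()`), which requires the completed track and is
  therefore a post-operative step.
* **FFT (10,000 features)** — the one-sided power spectrum aggregated into
  uniform frequency bins over 0--Nyquist, scaled so that summed bin powers
  equal the signal's summed squares. Band powers at 500--1000 Hz
  (multi-unit) and 1000--3000 Hz (single-unit) are carried alongside for
  plotting.
* **Wavelet (N/2 features)** — an orthonormal Haar discrete wavelet
  transform to 4 levels; by default the finest detail band is the feature
  vector, which is 120,000 coefficients for a 10-s epoch at 24 kHz.

Degenerate inputs never produce `NaN`: with 0 or 1 detected spikes all five
ISI features are 0; with no sub-50 ms ISI the pause index falls back to the
long-ISI count and the pause ratio to long-ISI time over epoch duration;
constant features z-score to 0. Odd lengths inside the wavelet pyramid are
padded by repeating the edge sample, and the pad positions are recorded so
the inverse transform is exact.

With normalization off, an epoch's features depend only on that epoch — the
property that makes the FFT and wavelet families usable while the electrode
is still advancing. A test asserts this by comparing batch extraction
against single-epoch extraction.

## Classifiers

The classical learners are an RBF support vector machine, ridge-penalized
logistic regression (penalty 1e-4, one code path for both the 10-dim and the
10k/120k-dim spaces), k-nearest neighbours (k = 5), and a CART decision tree.
SVM, logistic regression and the network standardize features using training
statistics only; per-trajectory normalization is a separate, feature-space
construction. The ensemble fits all four on an internal 75/25 split of the
training data, weights each by its held-back accuracy, refits on the full
training data, and predicts by weighted majority vote. Vote ties are broken
toward class 0 (outside the STN) — for this application a false "inside" is
the costly error. Class totals within 1e-9 (relative to the summed weights)
are treated as tied, since totals that are equal as real numbers can differ
in the last floating-point bits depending on summation order.

The deep model is a fully connected network, ten hidden ReLU layers of 50
units and a sigmoid output, trained on cross-entropy plus an L2 weight
penalty (lambda = 0.0285) with inverted dropout (rate 0.3) on hidden
activations. No deep-learning framework is involved: forward and backward
passes are plain R matrix algebra with Adam updates (learning rate 1e-3,
minibatch 64), early stopping on a 10% validation split (patience 8), and
all randomness drawn from one seed.

### Why the network trains in two stages

The wavelet feature space is wide: 12,000 inputs at 1-s epochs, 120,000 at
clinical length, against hundreds to thousands of training epochs. The
discriminative signal is in the *scale* of the coefficients (variance), not
their sign, so a linear readout of the raw inputs carries no information —
but a randomly He-initialized ReLU stack already maps class-dependent
variance into class-dependent activation means. Backpropagating immediately
through the enormous input layer lets those millions of parameters memorize
the training set before any generalizable structure forms; empirically this
collapses held-out accuracy toward chance. `fit_mlp()` therefore first fits
the output layer exactly as a ridge-penalized logistic regression (penalty
1e-3) on the frozen stack's activations — a linear probe — and then
fine-tunes all layers by backpropagation at a reduced learning rate (factor
0.1) under the configured L2 and dropout, keeping the weights of the best
validation epoch. For low-dimensional inputs (e.g. the XOR capacity check)
`probe_init = FALSE` restores plain end-to-end training.

## Evaluation protocol

`split_epochs()` supports per-epoch splitting (the protocol behind the
headline clinical numbers) and per-trajectory splitting. The package's own
synthetic study uses a whole-trajectory 80/20 split: held-out tracks remain
intact, so border localization can be evaluated on them, and no epoch of a
test track ever influences training. `cross_validate()` runs stratified
k-fold (default 10) cross-validation and accepts fit/predict stubs so the
protocol itself can be tested against oracles. `score_predictions()` reports
the confusion matrix with inside-STN as the positive class; the
false-positive rate FP/(FP+TN) is the safety-critical figure, since a false
"inside" risks placing the electrode outside the nucleus.

`localize_borders()` median-smooths the 0/1 depth sequence (window 3 epochs;
positions beyond the track ends count as "outside", which is physically
true) and takes the longest run of inside calls; its first and last depths
are the dorsal and ventral estimates, with ties between equal runs going to
the shallowest. This extraction rule is this package's construction — the
clinical workflow stops at per-epoch classification and leaves border
reading to the surgeon.

## Problem sizes and numerical choices

The packaged synthetic study simulates 60 trajectories of 1-s epochs
(26 depths each, 1560 epochs) — large enough for stable accuracy estimates
while keeping a laptop-scale runtime; the same code runs unchanged at 10-s
epochs. Under these conditions (seed 7) the held-out results are
approximately: wavelet+DNN accuracy 92--93%, FFT+ensemble accuracy at or
near 100% with all four members above 85%, and both STN borders of every
held-out trajectory within one fine depth step (0.5 mm) of truth when
localized from the ensemble's predictions — the ensemble is the stronger
border localizer on this synthetic analogue, while the deep network's
residual epoch errors occasionally split an inside run. These are
synthetic-analogue figures, not clinical ones: the planted contrast is
cleaner than surgical reality.

Other fixed choices: Haar normalization is orthonormal so Parseval holds to
1e-6 and reconstruction to 1e-9; FFT bins follow the same convention; the
printed form of the threshold formula (which reduces to the square root of a
sum of deviations from the mean, identically zero) is provided as
`method = "literal"` for comparison, with 3 x sample SD as the working
default; KNN prediction is wrapped in a fixed seed because distance ties are
otherwise broken at random.

## Limitations

* The simulator's class contrast is an assumption; absolute accuracies on
  synthetic data say nothing about clinical accuracy.
* Border localization presumes exactly one inside run per track; tracks
  grazing the nucleus edge, or traversing other active nuclei, would need a
  multi-run rule.
* The per-trajectory normalization of conventional features is
  post-operative by construction; intraoperative use is limited to the FFT
  and wavelet families, as intended.
* The deep model's probe-then-fine-tune schedule is tailored to
  variance-coded, very wide inputs; architectures with batch normalization
  or residual paths would be the modern route but are out of scope here.
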