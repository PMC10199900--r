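---
title: "Models and methods behind porecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind porecall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

porecall studies how far single amino acids can be told apart from the
ionic-current signatures they produce while translocating an atomically
thin MoS2 nanopore. Because no machine-readable raw recordings are
publicly deposited for this system, the package is built around a
generative model of such recordings whose parameters are the published
per-device population statistics, and a complete analysis chain —
event detection, density-based peak calling, hypothesis testing, and
per-event classification — that can be validated end-to-end against the
ground truth the generator injects. This vignette explains each model,
the tunable parameters and their defaults, and the design decisions taken
where the published description left the choice open.

## The generative signal model

Each analyte on each device is described by an `aa_signal_model`:

* **Blockade distribution.** A one- or two-component Gaussian on the
  relative current blockade dI/I0 (dimensionless), or on the absolute
  blockade dI in nA for the homopeptide device where the source values
  are printed in nA. The packaged table
  `inst/extdata/signal_library.tsv` transcribes the published
  mean ± SD for every (analyte, device) pair. Two populations are
  bimodal (H on Device #6; G on Device #12), which the source attributes
  to different pore-entry orientations. The component *weights* of those
  mixtures are not published; we default to 0.5/0.5 as the symmetric
  prior and keep them configurable per table row. The published ± values
  are treated as population SDs of the generative distribution (rather
  than fitted peak widths); the package reports both sample SDs and
  component SDs so the two readings can be compared.
* **Truncation.** Relative blockades are rejection-sampled into (0, 1]:
  a blockade cannot be negative, and the current can be blocked almost
  to zero but not below. For all tabulated parameter sets the truncated
  mass is negligible (< 1e-5), so truncation does not bias the means.
* **Dwell-time model.** The source reports dwell times only as heatmap
  ranges, mostly above 0.1 ms, so the dwell family is a package decision:
  lognormal with median 0.5 ms and sigma(log) = 0.6. This is right-skewed
  and heavy-tailed, as nanopore dwell distributions are, and puts ~2.3%
  of events below the 0.1 ms dwell-filter cutoff, so the standard filter
  retains most events. Both parameters are per-model columns in the
  table.
* **Charge sign.** K and R are positively charged at the working pH 7.8
  and are driven at -200 mV; the other analytes are negative and driven
  at +200 mV. The simulator refuses a voltage whose sign cannot drive
  the configured analytes.

## The trace simulator

`simulate_trace()` builds a recording as: constant open-pore baseline I0
(default 3 nA), rectangular blockade pulses, white Gaussian noise, and a
causal second-order low-pass Butterworth at 10 kHz standing in for the
recording hardware's 10 kHz anti-alias filter (an R filter-design
routine for the Bessel family is not part of the signal toolbox we build
on; at identical order and cutoff the two differ mainly in phase ripple,
which the detection chain's zero-phase filtering makes immaterial here).
Key choices:

* **Event shape** is a rectangle smoothed only by the acquisition
  filter. The analysis extracts only depth and dwell, so intra-event
  structure would be unconstrained invention; the event-set generator
  and classifier operate on the same shapes.
* **Arrivals** are Poisson (default 10/s; the source does not print
  event rates at 2 uM, so this is a package default) thinned so that
  events never overlap; at the default duty cycle the thinning loss is
  well under 1%. A configuration whose rate x mean dwell exceeds 0.5 is
  refused rather than silently saturated. A 2 ms guard of clean baseline
  is kept around each event and at the trace edges.
* **Noise** is white Gaussian *calibrated after the filter*: the input
  SD is the target RMS divided by the square root of the filter's
  variance gain (sum of squared impulse response), so `noise_rms`
  (default 0.01 nA) is the baseline RMS a user would measure on the
  recording. Flicker noise and baseline drift are not simulated by
  default; the moving-average baseline tracker is exercised by a drift
  test instead.
* **Voltage scaling** of the blockade is linear in |V| relative to the
  200 mV tabulation voltage — an ohmic choice; the source asserts only
  that blockades grow from 200 to 300 mV, so all tests rely on the
  monotonicity, not the linearity.

Ground truth (exact event boundaries, injected depth and dwell) is
emitted alongside every trace, and a noiseless/unfiltered mode produces
traces on which detection must recover events exactly — the oracle route
used throughout the test suite.

## The detection chain

`detect_pipeline()` mirrors standard solid-state-nanopore practice
(Transalyzer-style): a zero-phase (forward-backward) second-order
Butterworth at 10 kHz; a centered 300 ms moving-average baseline; event
calling against the local noise SD; and the 0.1 ms dwell filter.
Decisions worth recording:

* **Zero-phase filtering** is used in analysis so dwell boundaries are
  not shifted; the simulator's causal acquisition filter is where the
  real-time hardware behaviour lives.
* **Two-pass baseline.** The first baseline pass runs unmasked; detected
  events (plus one filter rise time of padding) are then masked and the
  baseline re-estimated with masked samples excluded and interpolated,
  so deep events cannot drag the baseline. The noise SD is the MAD of
  the residuals outside the mask.
* **Dual thresholds.** An event opens below baseline - 5 sigma and its
  boundaries are the surrounding crossings of baseline - 2.5 sigma. The
  source does not print its detector's thresholds; 5/2.5 follows common
  nanopore practice and both are config-exposed. At 5 sigma the raw
  false-positive rate on event-free traces stays within the Gaussian
  tail bound (well under one excursion per second), and no noise
  excursion survives the dwell filter.
* **Depth estimate.** dI is the baseline minus the mean of in-event
  samples with half a filter rise time (5 samples at the defaults)
  trimmed from each boundary, so the low-pass ramps do not dilute the
  plateau; events too short to trim fall back to their deepest samples.
  The mean-not-extreme choice matches populations summarized by mean
  peak values.
* **Dwell filter semantics.** "Shorter than 0.1 ms" is excluded, so the
  boundary is inclusive: an event of exactly 0.1 ms is retained.
* Indices are 0-based half-open, times in seconds, currents in nA.
* Fewer than 300 surviving events triggers a warning, mirroring the
  source's minimum collection size for population statistics.

## Peak calling and statistics

Unimodal blockade populations are summarized by the mode of a
Gaussian-kernel KDE with Silverman's bandwidth (the source's normal-kernel
density fit; its tool's bandwidth is unpublished, so the standard rule is
the default and the bandwidth is exposed). The grid argmax is refined by
a parabolic fit through the three neighbouring grid points; shoulder
modes below 10% of the peak density are suppressed. Bimodal populations
are summarized by a two-component Gaussian mixture fitted by EM, best of
10 quantile-initialized random restarts by log-likelihood, because a
broad second component need not produce a distinct KDE mode at equal
weights. The EM implementation is cross-checked against an independent
mixture-model package in the test suite.

Population separation uses the unequal-variance (Welch) two-sample
z-statistic with a two-sided normal p-value; the source does not specify
pooled vs unpooled, and Welch is the safer default when SDs differ (as
the printed ones do). Its type-I error is calibrated by simulation in
the suite (5% ± 1.5% at alpha = 0.05 over 1000 null repeats). No
multiplicity correction is applied: the source reports a single blanket
bound across its pairs, and the package mirrors that surface.

## Per-event classification

Events are encoded as L = 128 points (config-exposed) linearly resampled
over the event plus 20% dwell context per side, normalized by the local
open-pore current (1 = open pore, clipped to [-0.2, 1.2]), with two
scalar features attached: relative blockade and log10 dwell. The source
does not publish its network's input encoding; this one is
baseline-invariant by construction, which the suite asserts.

Two classifiers share this encoding:

* **Gaussian-Bayes baseline** — class-conditional independent densities
  on the two scalar features (a two-component mixture on the blockade
  where BIC prefers it), equal priors, maximum posterior. On synthetic
  data *all* class information lives in these two features, so this
  transparent baseline operates at the Bayes optimum, which
  `bayes_accuracy_two_class()` computes by quadrature as an independent
  check.
* **LSTM sequence classifier** — a single LSTM layer over the encoded
  waveform, mean-over-time pooling, the two scalar features appended to
  the pooled state, four fully connected ReLU layers, and a softmax
  output; trained with Adam and early stopping on validation accuracy.
  It is implemented directly in base-R matrix operations (batched
  backpropagation through time), which keeps the package dependency-free
  on deep-learning frameworks and is fast enough for the problem sizes
  used (hidden width 64 and below; CPU minutes). Defaults (hidden 64,
  FC widths 64/32/16/8, batch 64, lr 1e-3, patience 10) are package
  choices, config-exposed; published hyperparameters are not available.

Because the generator writes class information only into depth and
dwell, the sequence model cannot beat the scalar baseline on synthetic
data — the suite asserts the two agree within 5 points on separable
sets, which is the designed consistency check, not a limitation of the
network. Accuracy-floor experiments therefore use the Bayes baseline;
for the two pairs with published floors the analytic optimum sits well
above them (G/A: ~96% vs 88.41%; S/T: ~89% vs 84.94%).

## Problem sizes and reproducibility

Parameter-recovery experiments simulate 2000 events per analyte (5000
for the bimodal H fit) at 25 events/s — enough that the KDE-mode
standard error (~0.002 for the widest populations, bootstrap-estimated)
sits well inside the ±0.01 recovery tolerance, while one run stays
within tens of CPU seconds. Classification experiments use 2000 events
per class with a stratified 70/15/15 split. Every random stage (samplers,
simulator, splits, EM restarts, network initialisation) is seeded, and
identical seeds reproduce traces and event tables bit for bit;
classifier accuracies reproduce exactly under a fixed config seed.

## What the synthetic data does and does not show

The generator reproduces the *population-level* structure of the
measurements: blockade means/SDs per device, bimodality where reported,
dwell ranges, arrival statistics, noise floor, and filtering. It does
not reproduce waveform microstructure within events (orientation
dynamics, sulfur-pore interactions), device-to-device variability beyond
the tabulated contexts, flicker noise, or clogging artifacts. Passing
recovery tests therefore demonstrates that the analysis chain is
unbiased and correctly calibrated for signals of the published
statistics — not that the classifiers would reach the published
accuracies on real recordings of hard pairs (D/E, K/R, F/Y/W, E/Q),
whose separability depends on waveform structure no published statistic
constrains.

## Known limitations

* Multi-level events (CUSUM-style sub-state segmentation) are out of
  scope; events are single-level by construction.
* Vendor acquisition formats are not read; traces move as TSV or raw
  float32 with a JSON sidecar.
* The linear voltage scaling is a modelling convenience; only its
  monotonicity is treated as established.
* The display downsampling is for plots only and never feeds
  detection.
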