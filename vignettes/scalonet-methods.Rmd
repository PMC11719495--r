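---
title: "Scalogram tiling and depthwise CNNs for EEG seizure classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalogram tiling and depthwise CNNs for EEG seizure classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

scalonet classifies 35-channel, 1-second EEG segments as *epileptic* or
*normal* in three stages:

1. **Time-frequency imaging.** Each channel is transformed with the
   continuous wavelet transform (CWT) using the real Morlet wavelet
   $\psi(t) = e^{-t^2/2}\cos(5t)$:
   $$W(a,b) \;=\; \frac{1}{\sqrt{a}} \sum_{n=0}^{T-1} x[n]\,
   \psi\!\left(\frac{n-b}{a}\right), \qquad b = 0,\dots,T-1,$$
   a Riemann-sum discretization of the CWT integral with unit sample
   spacing and boundaries handled by truncation (only available samples
   enter the sum). The magnitude $|W|$ over the scale grid $a = 1,\dots,100$
   is min-max normalized per image, mapped through a piecewise-linear jet
   colormap, and bilinearly resized to a 100x100 RGB tile.

2. **Tiling.** The 35 channel tiles are concatenated into one composite:
   channel $i$ (0-based position in the stored channel order) lands at
   column $i \bmod 7$ and row $\lfloor i/7 \rfloor$ of a 7-column by 5-row
   grid, yielding a 700-px-wide by 500-px-high image. The grid places the
   x-index fast and the y-index slow, which is the only convention
   consistent with both the position formulas and the composite's pixel
   dimensions; tile content is copied verbatim.

3. **Classification.** A compact depthwise CNN consumes the composite:
   resize to $150 \times 210 \times 3$ (values scaled to $[0,1]$), conv
   $3{\times}3{\times}4$ relu, depthwise $5{\times}5$ relu, conv
   $3{\times}3{\times}8$ relu, maxpool $2{\times}2$, depthwise
   $5{\times}5$ relu, maxpool $2{\times}2$, flatten (12,672), dropout 0.6,
   dense 512 relu, dense 1 sigmoid — 6,489,809 trainable parameters.
   Training uses Adam at learning rate 0.0002, batch size 128, binary
   cross-entropy, and a 75/25 train/eval split; epilepsy is the positive
   class and a segment is called epileptic when the sigmoid output is at
   least 0.5. Evaluation reports accuracy, sensitivity, specificity,
   precision and F1 from the confusion matrix.

## Design choices where the specification was open

**Convolution geometry.** Padding and strides are forced by the published
layer shapes: valid padding with stride 1 for both convolution kinds
(each $k{\times}k$ layer shrinks spatial dims by $k-1$), stride-2 pooling
with floor division. The depthwise layers use channel multiplier 1 and are
*not* followed by pointwise $1{\times}1$ convolutions — the tabulated
architecture lists none, so the depthwise/pointwise factorization remains
descriptive background rather than part of this network.

**The resize layer.** The first layer converts a 500x700x3 composite to
150x210x3 (or 50x70, 100x140, 200x280 via `input_size`), which is a
spatial resize, not a pure value rescaling; it is implemented as bilinear
resize plus scaling of pixel values to $[0,1]$ and named
`rescale_resize`. Resizing uses the half-pixel-centre convention (output
centre $(i+0.5)/H_\text{out}$ maps to input coordinate
$(i+0.5)H_\text{in}/H_\text{out} - 0.5$, clamped), with axes stretched
independently.

**Scale grid and rendering.** The scale range is nowhere stated; the
default $a = 1,\dots,100$ in unit steps matches the 100-px tile height
before resizing and spans roughly 4--400 Hz at 500 Hz sampling (the real
Morlet's centre frequency is $\approx 0.8125$ cycles, so a scale $a$
responds near $0.8125\,f_s/a$). Magnitude $|W|$ is rendered, the
conventional scalogram choice for a colormapped image. Normalization is
per image (min-max), so rendering is invariant to overall signal
amplitude; a constant coefficient field renders as jet(0). The jet
colormap is defined by the closed form
$\mathrm{round}(255\,\mathrm{clamp}(1.5 - |4v-\kappa|, 0, 1))$ with
$\kappa = 3, 2, 1$ for r, g, b — a normative, plotting-library-free
definition that makes image bytes bit-reproducible.

**CWT evaluation.** The Riemann sum is evaluated as an exact zero-padded
FFT linear convolution of the signal with the sampled wavelet kernel,
truncated where $|t| > 8$ ($\psi(8) \approx 10^{-14}$, far below the
round-off of the sum itself). The test suite checks agreement with a
dense, truncation-free Riemann-sum oracle at relative L2 error below
$10^{-6}$ (observed: $\sim 10^{-15}$). A cross-library comparison against
PyWavelets' "morl" transform is also included: PyWavelets discretizes via
finite differences of the integrated wavelet, which departs from the plain
Riemann sum at small scales, so rank agreement above 0.99 per scale is
asserted for scales 30--100 only; below that the two discretizations
genuinely measure slightly different quantities.

**Training engine.** The network runs on a compact compiled engine inside
the package (im2col + GEMM convolutions, depthwise convolutions, max
pooling with argmax caching, inverted dropout, dense layers, Adam and
RMSprop, binary cross-entropy). Weight initialization is Glorot uniform;
initialization, epoch shuffling and dropout masks all derive from one
seed, so fits are exactly reproducible. Analytic gradients are verified
against finite differences in the test suite. Two independent routes to
the architecture's bookkeeping exist and are cross-checked: an analytic
fold over layer rules (`propagate_shapes()`, `count_parameters()`) and the
shapes/weights the engine actually materializes
(`model_layer_shapes()`, `model_parameter_count()`).

**Splitting.** The published protocol assigns 75% of *segments* to
training with the remaining 25% serving as both validation and test; this
is the default (`split_spec(mode = "segment")`). Because clinical segments
are nested within subjects, segment-level splitting risks subject leakage,
so a `mode = "subject"` alternative assigns whole subjects to one side
only; it is provided and tested but not the default, to stay faithful to
the published protocol. A `three_way = TRUE` flag further halves the
held-out records into separate validation and test partitions for users
who prefer not to reuse the 25% for both roles.

**Zero-denominator scores.** A score whose denominator is zero (e.g.
sensitivity with no positive segments) is reported as 0 with a warning
rather than NaN, so parameter sweeps never abort; F1 is 0 when precision
and sensitivity are both 0.

## The synthetic cohort

The public 35-channel clinical dataset behind the published numbers is
external, so the package ships a generator whose output exercises every
pipeline stage with class structure a clinician would recognize:

* **Normal segments**: 35 independent $1/f^{\beta}$ background sources
  ($\beta = 1$) with an alpha-band (8--13 Hz) sinusoid at 1.5x the noise
  RMS, spatially mixed by a per-subject, strictly diagonally dominant
  35x35 matrix (unit diagonal, off-diagonal rows scaled to absolute sum
  0.5). Mixing is fixed per subject so subject-wise splitting is
  meaningful.
* **Epilepsy segments**: the same background plus a 3 Hz spike-and-wave
  discharge — per complex, a Gaussian spike ($\sigma = 10$ ms) followed
  30 ms later by an opposite-polarity half-sine slow wave (180 ms wide,
  0.6x the spike amplitude) — injected on a fixed focal half of the
  channels at 4x each channel's background RMS. Focality makes the 35-tile
  composite informative rather than redundant.
* **Cohort structure**: 40 subjects per class by default, each
  contributing a uniformly drawn 6--10 segments of 1 s at 500 Hz, echoing
  the variable per-subject segment counts of clinical cohorts while
  staying desk-scale (the clinical dataset averages ~86 segments per
  subject over 121 subjects). 500 Hz is a clinically plausible sampling
  rate; none is stated for the original recordings. Amplitude units are
  arbitrary since per-image normalization makes classification
  scale-robust.
* **Seeding**: one seed expands through a counter-based hash into
  per-subject and per-segment streams, so regenerating a subset of the
  cohort reproduces exactly the segments it shares with the full cohort.

What the generator does *not* emulate: ocular/muscle artifacts, electrode
montage geometry, ictal-versus-interictal distinctions, non-stationary
background changes, or realistic inter-subject variability beyond the
mixing matrix. Passing the end-to-end test therefore shows the pipeline
learns the intended class structure from images it built itself — it does
not certify clinical performance.

## Problem sizes and numerical notes

The shipped end-to-end experiment trains for 15 epochs at 100x140 input
on the default cohort (~650 segments, 75/25 split) — the package's chosen
desk-scale stand-in for the published 100-epoch, 10,356-segment runs, and
the scale used by the test suite and `scripts/acceptance.R`. Bandpower
features (1--4 Hz vs 8--13 Hz) separate the synthetic classes almost
linearly (held-out logistic-regression accuracy well above 85%), so the
CNN test is not vacuous. Ties in max pooling resolve to the first element
in column-major window order; relu subgradient at exactly 0 is 0; the
sigmoid/BCE head clamps probabilities to $[10^{-12}, 1-10^{-12}]$ before
taking logs. All disk images are 8-bit RGB PNG with deterministic bytes.

## Known limitations

* The real-data accuracies of the original experiments require the
  external clinical recordings and are out of scope; only the metric
  arithmetic on their published confusion counts is reproduced.
* SGD/Adagrad runs ("no learning observed" in the original report) are
  not modelled; the engine implements Adam and RMSprop.
* EDF input is not implemented (no EDF reader is available to the
  package); the canonical interchange format is CSV plus a JSON sidecar.
* The engine is single-threaded and meant for method-scale experiments,
  not production training workloads.
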