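---
title: "Classifying gait activities from step-segmented inertial data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gait activities from step-segmented inertial data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstep)
```

## The problem

Wearable inertial sensors record triaxial acceleration (in g) and angular
velocity (in deg/s) while people walk. Segmented into individual steps,
these recordings support classifying the *gait activity* being performed:
walking on level ground, going up or down an incline, and going up or down
stairs. Naturalistic datasets of this kind are heavily imbalanced — level
walking dominates, stair activities are rare — and classifiers trained on
such data drift toward the majority class while still reporting high
accuracy.

`gaitstep` implements a complete classification stack for step-segmented
data at 100 Hz from a single waist-mounted sensor (accelerometer range
±4 g, gyroscope ±500 deg/s):

1. **Data treatments** for class imbalance: leave the data unbalanced,
   subsample every class to the minority count, or augment every class up
   to the majority count with synthetic steps.
2. A **shallow pipeline**: statistical features per step, classified by
   naive Bayes, an entropy-split decision tree, an RBF support vector
   machine, or k-nearest neighbours under stratified five-fold
   cross-validation.
3. A **deep pipeline**: each step is encoded as a three-channel Gramian
   Angular Field (GAF) image and classified by a compact convolutional
   network.
4. A shared **evaluation report** (per-class precision/recall/F-measure,
   supports, accuracy, macro and weighted averages, confusion matrix).
5. A **synthetic gait generator** so that the entire stack is testable
   without access to restricted gait datasets.

## Preprocessing

Each of the six axis series is low-pass filtered and smoothed before any
feature is computed.

* **Low-pass filter.** A 4th-order Butterworth filter, default cutoff
  10 Hz at 100 Hz sampling, applied forward and backward so the net phase
  is zero and peak positions inside the step are preserved. Human gait
  energy sits well below 10 Hz; the filter removes motion artifacts and
  sensor noise. Step segments are short (tens of samples), so startup
  transients matter: the implementation reflects the series symmetrically
  at both ends (which preserves the local DC level, unlike odd
  reflection) and offsets each pass by the segment's edge value before
  filtering. Residual edge effects attenuate a 20 Hz tone to below 10% of
  its energy on a 2 s segment while passing 1 Hz essentially unchanged.
* **Pseudo-Gaussian smoothing.** Convolution with a normalized discrete
  Gaussian kernel, width 5 samples by default, σ = width/4, truncated at
  ±width/2, with reflective boundary handling. Width 1 is the identity.

Two derived signals per sensor feed everything downstream:

* **Forward-direction signal (FD).** The axis with the greatest
  mean-removed power within the step, taken as aligned with the sagittal
  plane. Power is computed after mean removal because the gravity-aligned
  accelerometer axis carries a ~1 g DC offset that would otherwise always
  win regardless of movement. Ties break to the lowest axis index. The
  choice is made per step and independently per sensor; the data model
  does not assume a fixed sensor orientation.
* **Magnitude vector (XYZ).** The per-sample Euclidean norm
  √(x² + y² + z²), invariant to device rotation.

## Data treatments and augmentation

Given per-class counts, `treatment_plan()` fixes the target composition:
unchanged (*unbalanced*), every class at the minority count (*sampled*,
drawn without replacement), or every class at the majority count
(*augmented*). The balancer synthesizes the deficit for each class by
cycling round-robin through five operators, each applied to a source step
drawn uniformly with replacement from the class's *original* instances —
synthetic steps never seed further synthesis, which prevents progressive
drift.

All operators perturb their input through a variation factor drawn from
N(μ = 1, σ = 0.2) — narrow enough to respect the constraints of human
movement and of step-level segmentation. Non-positive draws (probability
≈ 3×10⁻⁷) are redrawn. Three operators modify the signal magnitude (DMM)
and two its length/frequency (DMF):

| Operator | Group | Action |
|---|---|---|
| scaling | DMM | multiply the whole signal by one factor (drawn per signal) |
| jittering | DMM | multiply each sample by an independent factor (multiplicative noise) |
| smoothing | DMM | convolve with a normalized Hann window of length (L/10) × factor |
| downsampling | DMF | keep L′ = round(L/f) evenly spaced samples, f > 1, one index set for all six signals |
| cutting | DMF | drop round((L/10) × factor) frames from the edges, ⌈n/2⌉ at the start |

DMM operators never change the series length; DMF operators never
introduce values absent from the source, and apply the same frame
selection to all six signals of a step. "Jittering" is implemented as
multiplicative per-element noise — the literal reading of multiplying a
random value onto each element — and is isolated behind its own function
so an additive variant could be swapped in. Hann windows shorter than
three samples degenerate to the identity (a Hann taper needs three points
of support).

## The shallow pipeline

Five descriptive features summarize each step signal: the **width** of
the segment (duration in samples; at a fixed 100 Hz this is seconds up to
a constant), and per selected signal its **height** (max − min), **mean**,
**standard deviation**, and **power** (mean of squared values). Height is
interpreted as the signal range, the standard descriptor consistent with
width as duration; power deliberately includes the DC component, unlike
FD selection, because here it describes the signal rather than ranking
axes. Width is counted once however many signals are selected, so with
s sensors and g signal types the feature vector has 4sg + 1 entries:
5, 9, or 17.

Four classifiers are supported. The decision tree uses entropy splitting
without cost-complexity pruning (an approximation of the classical
C4.5-style tree; exact C4.5 pruning is out of scope since the tree
variant is not the point of the pipeline). The SVM uses an RBF kernel
with C = 1; k-NN uses k = 5. Features are z-scored with statistics of
each training fold only, so no information crosses fold boundaries
through scaling.

Cross-validation is stratified five-fold: treatments are applied *before*
splitting by default, mirroring the evaluated procedure. With the
augmented treatment this lets synthetic steps share folds with their
source steps, an optimistic bias; `split_before_augment = TRUE` assigns
folds first and augments only each training portion, the leakage-free
order. Both orders are exposed rather than asserted because neither
stratification nor ordering is dictated by the problem.

## The GAF image pipeline

A series X is encoded in three stages:

1. **Rescale** to [−1, 1]:
   x̃ᵢ = ((xᵢ − max X) + (xᵢ − min X)) / (max X − min X). The maximum maps
   to 1 and the minimum to −1; offset and positive scale are removed. A
   constant series (max = min) maps to all zeros by convention — the
   neutral angle π/2. Values are clipped to [−1, 1] against floating-point
   overshoot.
2. **Polar representation**: φᵢ = arccos(x̃ᵢ), rᵢ = tᵢ/N. The radius
   locates samples along a spiral for visualization; only the angles
   enter the matrix.
3. **GAF matrix** (summation form): Gᵢⱼ = cos(φᵢ + φⱼ), symmetric, with
   diagonal 2x̃ᵢ² − 1. The difference form is out of scope.

Three signals become the three channels of one feature image, quantized
linearly from [−1, 1] to 8-bit intensities: red = AccXYZ, green = GyrXYZ,
blue = AccFD. Because the source papers on this encoding do not fix an
image side, each signal is first resampled to a configurable side N
(default 64; steps at 100 Hz run ~40–120 samples, so 64 balances fidelity
against network cost). Shrinking uses piecewise aggregate approximation
with fractional bin boundaries — each sample contributes to a bin in
proportion to its overlap, so the series mean is conserved exactly —
and stretching uses linear interpolation. Rescaling happens per step:
the rescale equation is defined over a single series, and per-step
normalization keeps every image at full contrast.

## The convolutional classifier

The network maps an N×N×3 image to five class scores through five 3×3
convolution layers with ReLU activations, three 2×2 max-pooling layers
(after convolutions 1, 3 and 5 — hence N divisible by 8), and two fully
connected layers. Channel widths (16, 32, 32, 64, 64), hidden width 128,
softmax cross-entropy, Adam at 10⁻³, batch size 32: the smallest
conventional instantiation consistent with the 5-conv/3-pool/2-FC census.
Channel intensities are scaled to [0, 1]. Weights are He-initialized from
the config seed; training is reproducible bit-for-bit under a fixed seed.

No R deep-learning framework is assumed: convolution and pooling forward
and backward passes are implemented as compiled kernels (im2col plus BLAS
matrix products), and the training loop, Adam updates and fully connected
layers run in R. Analytic gradients are verified against numerical
differentiation in the test suite.

A stratified 10% of the training partition is held out per run to track
validation loss next to training loss, epoch by epoch. The default
stratified 80/20 train/test split draws round(0.8 × count) per class; a
non-stratified variant exists behind a flag because published per-class
test supports are not always consistent with per-class rounding.

## The synthetic gait generator

The generator emulates the structure of step-segmented waist-sensor
data — five classes at an imbalance of 13/12/63/6/6 percent by default,
steps of 0.4–0.8 s at 100 Hz, values within the ±4 g / ±500 deg/s sensor
ranges — not its biomechanics. Each step is a class-conditional sum of a
fundamental sinusoid at the step frequency plus one harmonic on the
forward axis, a ~1 g gravity offset on the vertical accelerometer axis, a
pitch pattern on the gyroscope whose sign distinguishes up from down
variants, and white Gaussian noise (0.08 g / 12 deg/s by default). The
forward axis is permuted per synthetic subject so forward-direction
selection is genuinely exercised, and per-subject gain varies by ±10%.

A single `separation` parameter spaces the classes; at 0 all five classes
are statistically identical, and accuracy collapses to chance. Separation
acts on two distinct carriers:

* **amplitude offsets** (accelerometer and gyroscope), in units of the
  noise standard deviation — what the statistical features see; and
* **waveform shape** (relative step-frequency shifts and the harmonic
  weight) — what survives the GAF encoding, which removes offset and
  scale by construction, making pure amplitude separation invisible to
  the image pipeline.

The accelerometer and gyroscope phases are drawn independently. With a
shared phase the class-dependent pitch sign would be identifiable from
cross-sensor feature correlations even at separation 0, where the classes
must be indistinguishable.

Passing tests on generated data therefore demonstrates that the pipelines
recover class structure planted in amplitude, duration and waveform
shape under realistic imbalance — not that they handle inter-subject
variability, sensor misalignment, incomplete step segmentation or other
properties of real recordings.

## Evaluation conventions

Reports carry per-class precision, recall, F-measure (harmonic mean,
0 when P + R = 0) and support, overall accuracy, macro (unweighted) and
support-weighted averages, and the confusion matrix (rows = true class).
The spread statistic printed next to weighted averages is the
*population* standard deviation of the five per-class F-measures — the
form that reproduces published spreads exactly. Precision and recall are
0 by convention when their denominator is 0, and the report flags that
the convention fired. The attraction index reads column sums of the
row-normalized confusion matrix: a class with column sum above 1 attracts
more predictions than its expected share (an *attractor*), below 1 a
*repeller*.

## Study conditions used by the checks

The automated checks (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) run the full stack at desk scale:

* Treatment arithmetic is evaluated on the published class composition
  {2098, 1890, 9865, 882, 956}, reproducing totals 15,691 / 4,410 /
  49,325 and per-class synthetic requirements
  {7767, 7975, 0, 8983, 8909}.
* The shallow treatment pattern runs on 600 synthetic steps at the
  published imbalance with separation 1 — weak enough that the majority
  class dominates the unbalanced run, which is the phenomenon under
  test — comparing per-class F-measures and their spread between the
  unbalanced and augmented treatments with the entropy-split tree.
* The CNN check uses 300 images per class at side 32 for 10 epochs at
  separation 4 (strong structure). These sizes keep a full run in about
  a minute while leaving a stable margin above the 0.90 macro-F
  threshold across seeds.

## Known limitations

* The synthetic generator is a fixture, not a biomechanical model; its
  class structure is planted and tunable.
* The decision tree approximates C4.5 by entropy splitting; pruning
  differs.
* The augment-then-split default reproduces the evaluated procedure but
  permits synthetic/source leakage across folds; use
  `split_before_augment = TRUE` for unbiased estimates.
* GAF encoding discards signal offset and scale per step; activities
  distinguished only by absolute signal level are not separable in the
  image domain. The companion statistical features retain that
  information.
* The CNN implementation is single-threaded CPU code aimed at small
  images and datasets; it is not a general-purpose deep-learning stack.
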