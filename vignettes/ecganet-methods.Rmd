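---
title: "ecganet: methods and design notes"
author: "ecganet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecganet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients who arrive at an emergency department with vital signs sometimes
deteriorate into cardiac arrest during their stay. The triage 12-lead ECG —
in many hospitals available only as a printed or PDF report, not as raw
signals — carries early warnings of that trajectory: ST-segment deviation
(the classic ischemia marker) and tachycardia are the two most cited.
`ecganet` implements an image-based risk model for this setting: the input
is a raster of the printed report page, the output a probability that the
patient goes on to arrest.

The package covers the full experimental loop at desk scale: a synthetic
report generator with exact pixel-level ground truth, the image-cleanup
chain, a residual CNN with spatial-attention gates, a recall-weighted loss
for class imbalance, threshold and ranking metrics, Grad-CAM saliency, and
the ablation design that quantifies what each component contributes.
Everything runs on one CPU in minutes; clinical data never enter the
package.

## Synthetic reports: what the generator emulates

`renderReport()` draws a white page with a fine/coarse background grid
(5:1 spacing, as on ECG paper), twelve lead panels in the conventional
3 x 4 arrangement, a 10-second trace per panel, and a solid glyph block per
printed lead label. The beat template in `synthesizeBeat()` is piecewise:
raised-cosine P and T waves, a triangular QRS, and — deliberately — a
perfectly flat ST plateau whose value equals the configured ST offset
exactly, joined by short linear ramps. Outside all waves the baseline is
exactly 0 mV. This template is not a physiological simulator; it was chosen
so that every landmark has an analytic ground truth. During rasterization
the generator records which pixels belong to the trace, the grid, the label
glyphs, and the ST windows; those masks are the oracles for every
preprocessing and saliency test in the package. Lead labels are solid
blocks rather than real fonts for the same reason: their pixel sets are
exact, so component-removal claims can be audited pixel by pixel.

Class signal. `ecgEffect()` defines the case/control generating
distributions. The defaults use disjoint supports — cases draw ST offsets
from 0.2–0.4 mV and heart rates from 100–140 bpm, controls from
-0.05–0.05 mV and 60–90 bpm — which makes the two classes strongly
separable by construction. That is the regime the package's end-to-end
learning checks assume: they verify that the pipeline can recover a signal
that is present, not that it can find a weak one. Overlapping ranges can be
passed to create harder tasks. Within a synthetic image the same ST offset
is applied to all twelve leads, which is stronger than the lead-specific
deviations of real ischemia.

What the generator does not emulate: scanner skew and shadows, vendor
layout differences, real typography, baseline wander, muscle or mains
artifact, and lead-specific morphology. Tests passing on these fixtures
therefore demonstrate correctness of the mechanics (masks, filters,
gradients, bookkeeping) and trainability on clean separable data — not
clinical performance.

Two page presets exist: the 1024 x 768 default and the 256 x 192 "desk"
preset (`deskLayout()`) used throughout the tests, with a 3-px trace
stroke, 8-px fine grid and 20 px/mV vertical scale.

## The cleanup chain

`preprocessReport()` composes four stages, in order; every stage preserves
the raster dimensions and the internal convention foreground = TRUE =
waveform. The printed black(0)-on-white(255) encoding is an I/O
representation handled at the boundary (`maskToImage()`).

1. `binarizeInverted()` — Gaussian blur (default 3-px kernel, sigma 0.5),
   then threshold: blurred intensity below 128 becomes foreground. The
   faint grid (intensity about 200) lands above the cut and disappears; the
   dark trace and labels land below it. An Otsu automatic mode is
   available.
2. `filterComponents()` — 8-connected components whose area falls below 30
   px, or whose bounding box fits within 10 x 10 px (the text-glyph rule),
   are deleted; all other components are preserved pixel-exactly. The
   defaults are calibrated on the desk-preset fixtures and exposed in full.
   Connectivity is 8 so that diagonal trace segments stay one component.
3. `openMask()` — morphological opening with the fixed 3 x 3 all-ones
   element: erosion then dilation, removing anything thinner than the
   element. Because the generator rasterizes strokes by stamping 3 x 3
   squares along a dense polyline, a clean trace is opening-invariant.
4. `equalizeRebinarize()` — the opened mask is rendered back to grayscale,
   optionally blurred, histogram-equalized, and thresholded again. The
   equalization convention is the cdf mapping normalized at the lowest
   occupied bin (`histEqualize()`), so the darkest occupied level maps to 0
   and a constant plane maps to background. The stage's own blur defaults
   to off (kernel 1): after opening, a noiseless mask is already two-valued,
   and any nonzero blur would dilate the stroke by a one-pixel halo that the
   equalization of a near-binary histogram cannot separate again. On
   already-clean input the stage is then an exact no-op, which is tested
   pixelwise.

Numerical conventions worth stating: thresholds always compare with
strict `<` on the 0–255 scale; the blur is an exactly separable Gaussian
with replicate boundary.

## The classifier

`buildNet()` assembles a ResNet-style backbone: a strided stem
convolution, a 2 x 2 max pool, four residual stages of basic blocks (the
first block of a stage carries the stage stride and a 1 x 1 projection on
the skip path), global average pooling and a single-logit head;
probabilities are `plogis(z)`. Two scales exist: `tiny` (widths
8/16/32/64, one block per stage, 64 x 64 inputs — every test uses this) and
`full` (widths 64/128/256/512, 3/4/6/3 blocks, 224 x 224 inputs).

After each of the four stages — and before the next — sits one
spatial-attention gate (`saEnabled = TRUE`): channel-wise mean and max maps
are stacked, convolved with a 7 x 7 learnable kernel, and squashed by a
logistic into a per-location weight in (0, 1) that multiplies every
channel. The kernel size 7 follows the usual convolutional block attention
design. Because the gate is bounded, attention can only re-weight, never
amplify; forcing the gate logits to +20 (`saturateGates()`) makes the
network equal its attention-free twin to machine precision, which is the
consistency check behind the attention ablation.

The forward and backward passes are written in the package (im2col
convolutions in C++ through RcppArmadillo, the rest in R) and are verified
against central finite differences through the whole network in the test
suite. A single-logit head with a logistic was chosen because the loss
consumes probabilities in [0, 1]; the decision threshold (default 0.5) is a
configuration field because deployment thresholds are a clinical choice.

## Binary recall loss

For a batch of N samples with labels $y_i$ and probabilities $p_i$,
predictions at the decision threshold (a tie counts as positive) give the
batch sensitivity $R_1$ and specificity $R_0$. The loss is

$$L = -\frac{1}{N}\sum_i \big[ w_1\, y_i \log p_i +
      w_0\, (1-y_i) \log(1-p_i) \big],
      \qquad w_c = (1 - R_c) + \varepsilon,$$

with the recalls treated as constants (no derivative flows through them),
so the per-sample logit gradient is

$$\frac{\partial L}{\partial z_i} =
  \frac{1}{N}\big[ w_1\, y_i (p_i - 1) + w_0\,(1-y_i)\, p_i \big].$$

A positive sample's gradient is always non-positive and grows in magnitude
as sensitivity falls; symmetrically for negatives and specificity. The
class that is currently under-recalled therefore pulls harder on the
logits, which is the mechanism that raises sensitivity on imbalanced data
without the fixed class weights that tend to flood precision.

Design choices: recalls are computed per batch — the only scope compatible
with a batch-mean loss whose weights are "recall of class c" — and at the
0.5 threshold; the weight floor $\varepsilon$ (default $10^{-2}$) keeps a
class at perfect batch recall from receiving exactly zero signal; log
arguments are clamped at $10^{-7}$ so the loss is finite for saturated
probabilities; a class absent from a batch counts as vacuously recalled
(weight falls to the floor) rather than undefined. With both recalls equal
to r the loss reduces to $(1-r+\varepsilon)$ times ordinary cross-entropy,
and with $\varepsilon = 0$, $R_1 = R_0 = 0$ it is exactly cross-entropy —
both identities are tested to $10^{-12}$.

## Metrics

`auroc()` uses the Mann–Whitney identity (ties count one half);
`auprc()` integrates the precision–recall step curve over unique score
thresholds with no linear interpolation. Both are invariant under strictly
increasing score transforms and are checked exactly against brute-force
enumeration (all label/score sets of size at most 12, over a seeded
sample). Threshold metrics follow the standard confusion-matrix
definitions; any 0/0 ratio returns 0 with a `degenerate` flag instead of
raising, so ablation sweeps never abort on an unlucky split.

## Training, evaluation, ablation

Training is minibatch AdamW (decoupled weight decay 0.01 on weights, none
on biases). The reference regime is 200 epochs at learning rate
$2\times10^{-5}$ (`trainingConfig()`); the desk preset
(`deskTrainingConfig()`) uses 30 epochs at $10^{-3}$ with batch size 16,
sized so that a tiny network fits 200 separable synthetic images on one
CPU in well under a minute. The learning rate was set where the desk-scale
loss curves are stable to the end of the run. Everything derives from one
seed: initialization, epoch shuffles, splits, resampling.

`splitDataset()` is label-stratified at fraction 0.8 by default.
`resampleToRatio()` reaches a target positive proportion by downsampling
the majority side only, without replacement — the conservative reading of
"random resampling" that never duplicates patients. `ablationRun()`
crosses the four toggles (none / attention only / recall loss only / both;
the arms differ only in `saEnabled` and `lossName`, which the report's
wiring table makes explicit) with the requested positive ratios, repeats
each cell with seeds derived deterministically from the base seed, and
reports per-run rows plus arithmetic cell means. The run seed deliberately
excludes the toggle: repeat k of every arm sees the same resampled data,
the same split and the same initialization stream, so the arms are
identically seeded twins and the toggle is the only treatment — the paired
design that makes small-repeat directional comparisons meaningful. The
reference design uses ratios 0.1 and 0.2 with 30 repeats; the desk-scale
checks use 10.

## Grad-CAM

`gradCam()` forms the gradient-weighted channel combination of a chosen
stage's activations, rectifies, and rescales to [0, 1]; overlays mark
exactly the cells above 0.4. A zero gradient field returns a flagged
all-zero map rather than 0/0. On the tiny preset the four stages have
16 x 16, 8 x 8, 4 x 4 and 2 x 2 cells; saliency audits against the
ST-window masks use stage 1, the only stage whose cells (4 px at 64 x 64)
are not larger than a whole beat, and bilinearly upsample to input size.

The saliency check itself is designed so that the question is well-posed:
the generating distributions give both classes the same heart-rate range
and differ only in the ST offset, so a trained model has nothing but the
ST windows to key on; models are trained at the same strength as the
end-to-end learning check; and the ST regions are the ground-truth ST
stroke pixels dilated by a 5 x 5 box, because a 4-px map cell cannot be
expected to resolve a 1-px stroke. The comparison (mean map value inside
the regions versus outside, averaged over case images) was verified to sit
at chance for untrained networks, so passing it requires learned ST
localization. It remains a stochastic property: individual seeds can fail
when a model keys on the baseline-shift counterpart of the elevation
rather than the window itself, which is why the check is a majority over
ten seeded runs.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on the desk preset:
256 x 192 fixtures, 64 x 64 tiny networks, datasets of up to 200 images,
at most 30 epochs, 5-seed medians for the learning check and 10 repeats
per ablation cell. These sizes are the package's desk-scale study
conditions; the full-page layout, full backbone and 200-epoch regime
remain available as configuration.

## Known limitations

* The backbone's `full` scale is functional but slow in this
  implementation; it exists to preserve the architecture family, not for
  production training.
* The generator's class signal is global (all leads shift together) and
  its separability is configurable; nothing here estimates how the model
  would behave on real, weakly separable clinical images.
* Batch-scope recall weighting makes the loss depend on batch composition;
  very small or single-class batches fall back to floor weights.
* At desk scale the recall benefit of the recall-weighted loss under class
  imbalance reproduces consistently, but the AUROC margin attributable to
  spatial attention is small and its sign can flip between dataset seeds;
  distinguishing the two reliably needs the full-scale regime.
* Connected-component defaults are calibrated for the desk layout; other
  layouts need rescaled `minArea` and glyph-box rules.
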