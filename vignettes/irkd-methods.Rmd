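---
title: "Image-representation knowledge distillation: models, defaults, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-representation knowledge distillation: models, defaults, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(irkd)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic generator does
and does not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## The problem

A wrist-worn tri-axial accelerometer yields multichannel quasi-periodic
time series; activity classifiers for such devices must be tiny. Image
representations of a signal window — Gramian angular fields (GAFs) and
persistence images (PIs) — expose structure (long-range temporal
correlation, loop topology of the underlying limit cycle) that a small
1-D network struggles to extract from the raw series, but computing them
at inference time defeats the purpose of a small model. The package
implements distillation as the bridge: image-based teachers supervise a
raw-signal student during training only.

## Representations

**Gramian angular fields.** A window channel is affinely rescaled to
$[-1, 1]$ (per window and per channel, which makes the field invariant to
per-window offset and gain; a constant channel maps to zero, i.e. polar
angle $\pi/2$), mapped to polar angles $\phi_t = \arccos x_t$, and
rendered as $\mathrm{GASF}_{ij} = \cos(\phi_i + \phi_j)$ (symmetric,
diagonal $2x_i^2 - 1$, so the per-step magnitude survives on the main
diagonal) or $\mathrm{GADF}_{ij} = \sin(\phi_i - \phi_j)$
(anti-symmetric, zero diagonal). GASF is the default variant — the
magnitude-preserving diagonal is the property the distillation setting
values. The identity
$\cos(\phi_i+\phi_j) = x_i x_j - \sqrt{1-x_i^2}\sqrt{1-x_j^2}$ is used as
a cross-check in the test suite, not as the implementation. By default the
series is linearly resampled to the image resolution (64) *before* the
field is formed, which is cheaper than building the full $n \times n$
field and resizing the image; the resize route is available via
`gaf_mode = "resize"` since both are legitimate ways to set the output
resolution.

**Persistence images.** Each channel is delay-embedded
($x_p, x_{p+d}, \dots, x_{p+(m-1)d}$); periodicity becomes a loop in the
embedding, and the Vietoris–Rips filtration of the point cloud measures
it as a dimension-1 persistence pair. The backend is built into the
package (no persistent-homology library ships with this stack): a
union-find sweep yields dimension-0 pairs, and a $\mathbb{Z}/2$ column
reduction of the triangle boundary matrix yields dimension-1 pairs; the
standard pairing theorem makes the dimension-2 reduction alone sufficient
for the (edge, triangle) pivots. The flag complex grows cubically, so
clouds are thinned to `max_points` (default 100) evenly spaced points
before the filtration is built; dimensions above 1 are out of scope.
Diagram points are mapped to (birth, persistence) coordinates, weighted
linearly by persistence (the common choice for a "weighted Gaussian";
constant weights are available), convolved with an isotropic Gaussian of
bandwidth `sigma`, evaluated at the cell centers of a square
`resolution × resolution` grid over `grid_range` on both axes, and
normalized by the image maximum (an all-zero image stays zero, and
essential classes — infinite death — are dropped, having no finite
persistence coordinate). Defaults follow the wearable-sensor setting:
`sigma = 0.25` with `grid_range = c(-10, 10)` for GENEActiv-like data;
`0.015` with `c(-1, 1)` for PAMAP2-like data.

Open parameters the literature leaves unstated are exposed rather than
hidden: embedding dimension/delay default to $m = 3$, $d = 2$ (a small
embedding that unfolds one loop per period at these sampling rates),
persistence images default to homology dimension 1 (loops carry the
periodicity; dimension 0 is selectable), and each channel is embedded
separately (one image channel per sensor channel) rather than jointly —
the per-channel layout is also what reproduces the published 2-D
parameter counts with three input channels.

## Networks

Both teachers and the student are pre-activation WideResNets: stem
convolution, three groups of $(d-4)/6$ blocks at widths $16k/32k/64k$,
stride 2 entering groups 2 and 3, size-1 projection shortcut exactly
where shape changes, final BN+ReLU, global average pooling, one biased
classifier. Convolutions are bias-free, normalization layers affine. The
1-D realization uses kernel 3 wherever the 2-D uses 3×3. None of this is
assumed: the architecture is validated against the published parameter
table (0.06/0.54/0.13/1.12 M in 1-D and 0.18/1.55/0.37 M in 2-D at 3
channels and 14 classes) and all four two-teacher compression ratios, in
`test-acceptance.R` and `scripts/acceptance.R`. Dropout is omitted (never
part of this setup). A multiply–accumulate FLOP report (`count_flops`)
is informational only: FLOP conventions differ between papers, so it is
not a fidelity surface.

The engine is compiled single-precision code (tiled im2col + BLAS sgemm,
single-threaded, deterministic); float32 is the standard numeric width
for SGD-trained convolutional networks and makes desk-scale training of
the 2-D teachers practical. Weight vectors cross the R boundary as
doubles in one flat layout, which is what the interpolation diagnostics
operate on. Initialization is He-normal (fan-out) for convolutions,
$\gamma = 1, \beta = 0$ for normalization, uniform
$\pm 1/\sqrt{\text{fan-in}}$ for the classifier, drawn from R's seeded
RNG.

## Distillation

The losses are exactly the standard forms: hard-label cross entropy; the
temperature-softened divergence
$L_{KD} = \tau^2\,\mathrm{KL}\!\left(\sigma(l_T/\tau)\,\|\,\sigma(l_S/\tau)\right)$
with the teacher as the reference distribution (the classical direction;
the reversed order is never used); and the convex combinations
$(1-\lambda)L_{CE} + \lambda L_{KD}$ (single teacher) and
$(1-\lambda)L_{CE} + \lambda[(1-\alpha)L_{KD}^{T1} + \alpha L_{KD}^{T2}]$
(two teachers). All reductions are batch means, so loss values are
invariant to batch size. $\alpha = 0.5$ is the averaging configuration;
$\alpha$ defaults are dataset-specific in the literature (0.7 vs 0.3 is
reported both ways for the two datasets), so the package treats $\alpha$
as an always-explicit experiment parameter rather than claiming a
canonical default.

Teachers are frozen by construction: their logits over the training set
are computed once in evaluation mode and indexed per batch, so no
gradient can reach them; identical runs may share the precomputed logits.
Optimization is SGD with momentum 0.9, weight decay $10^{-4}$, batch 64;
the learning rate starts at 0.05, multiplies by 0.2 at epoch 10, and by
0.1 at every positive multiple of $\lfloor t/3 \rfloor$ epochs (the
period is exposed as configuration; the "every $t/3$" reading of the
schedule is adopted, and when the early drop coincides with a period
multiple both factors apply). The "best" checkpoint is the highest
evaluation accuracy with ties resolved to the earliest epoch.

**Annealing initialization** trains a model with the student's exact
architecture from scratch on raw series with cross entropy only, under
the same schedule (the pretraining length is not separately specified in
the literature; sharing the schedule keeps the initializer and the
student comparable), and starts distillation from those weights with
fresh optimizer state.

## Evaluation and diagnostics

`evaluate_network` reports accuracy (percent), the confusion matrix, and
macro-averaged F1 — macro rather than weighted because equal class weight
is the informative choice under class imbalance.

**Corruption.** Test-time corruption zeroes one contiguous segment of
`round(p·T)` steps per window (start uniform, shared across channels) and
adds i.i.d. Gaussian noise of SD `s` to every sample, with presets
(0.15, 0.06), (0.22, 0.09), (0.30, 0.12). Zero is the neutral value of
the stored signal and "removal" is a single contiguous segment (the
missing-segment reading); the noise SD is taken in the units of the
stored signal, since the levels are dimensionless. The corruption seed is
fixed per comparison so every model sees the identical corrupted test
set. Training always uses clean data.

**Weight-space interpolation.** `parametric_curve` evaluates
$\psi((1-\eta)x_a + \eta x_b)$ over $\eta \in [-1, 2]$. Interpolated
normalization running statistics are meaningless, so by default the
statistics are re-estimated in one accumulation pass over the training
inputs (equal-weight average of batch statistics, the standard
weight-averaging practice); `reestimate = FALSE` interpolates the stored
statistics instead, which reproduces the endpoint checkpoints exactly and
is the mode the endpoint tests use.

**V-score.** The clustering diagnostic embeds penultimate-layer features
with a small exact t-SNE (quadratic cost, adequate for a few hundred test
windows), clusters the 2-D embedding with seeded k-means at $k$ = number
of classes, and scores homogeneity/completeness against the true labels
with the V-measure. The clustering step is one concrete reading of a
"t-SNE + V-score" analysis and is documented as such; `use_tsne = FALSE`
clusters the raw features directly.

## The synthetic generator

Real wearable data is proprietary, so the package ships a generator whose
defaults are the study conditions of the test suite. Each class is a
harmonic series at a class fundamental (geometric ladder from 1 Hz with
ratio 1.3 — the cadence range of slow walking through jogging, with
neighbouring classes close enough to confuse); harmonic profiles cycle
through three gait-like shapes; each subject carries multiplicative
frequency and amplitude factors ($1 + 0.1\,z$, truncated away from zero),
each channel a random phase, and every sample i.i.d. Gaussian noise
(SD 0.3 against unit amplitude). Class counts are produced exactly as
requested (a vector of per-class counts expresses imbalance), and
subject-disjoint train/test splits are obtained with `subject_offset`.

What the generator does emulate: class-structured quasi-periodicity (so
GAF textures and embedding loops are real), subject-level distribution
shift, imbalance, and sensor noise. What it does not: gravity components,
orientation drift, transient gestures, heteroscedastic artefacts. Passing
tests therefore demonstrate the correctness and the qualitative behaviour
of the machinery — not field accuracy on real recordings.

The scaled-down study the acceptance tests run uses 5 classes, 3
channels, 500-sample windows, 200 training windows per class over 16
subjects, 50 test windows per class over 4 held-out subjects, WRN16-1
teachers and students, 30 epochs, $\lambda = 0.7$, $\tau = 4$,
$\alpha = 0.3$, three seeds; teachers are trained once and the seeds vary
the student runs, matching the usual practice of distilling from fixed
pre-trained teachers. These sizes were chosen once as the smallest
configuration in which the distillation comparisons are meaningful
(scratch accuracy well above chance and below saturation).

## Numerical notes and limitations

- Training is bit-reproducible given seeds: single-threaded float32,
  batch order from R's RNG, no atomics. Forward passes in evaluation
  mode are deterministic.
- Constant series, empty diagrams, all-zero images, and degenerate
  clusterings all have defined, documented outcomes (zeros, zero images,
  scores of 0) rather than errors.
- Batch statistics use biased variance (the convention matching the
  normalization definition); running statistics are updated with
  momentum 0.1.
- Ties in argmax prediction resolve to the lowest class index.
- The persistence backend supports homology dimensions 0 and 1 and is
  cubic in cloud size; `max_points` bounds the cost, trading fine-grained
  births for speed. Zero-persistence dimension-1 pairs are dropped;
  dimension-0 deaths at scale zero (duplicate points) are kept.
- The learning-rate schedule compounds aggressively for short runs
  (with $t = 30$ the period is 10, so epoch 10 applies both the early
  drop and a period factor); this is the schedule's defined behaviour,
  not a special case.
- PAMAP2-style ingestion (`read_pamap2`) is a hook: channel selection is
  an explicit argument because no canonical axis subset exists; it is
  not exercised by the test suite.
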