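---
title: "Bayesian U-Net active learning: model, acquisition functions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian U-Net active learning: model, acquisition functions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pixel-wise segmentation models need pixel-wise labels, and producing a full
segmentation mask for a single microscopy image can take an expert many
minutes. `bunet` implements a label-efficient training procedure: a
Bayesian U-shaped convolutional network whose predictive uncertainty is
used to decide *which* unlabelled images are worth sending to the
annotator (the "oracle"), so that a small fraction of the pool needs to be
labelled at all.

# The model

The segmenter is a standard U-Net: a contracting path of two-convolution
blocks (3×3 kernels, same padding) separated by 2×2 max pooling, with the
channel width doubling at every level, and an expanding path of 2×2
stride-2 transposed convolutions whose outputs are concatenated with the
encoder features of matching resolution (skip connections) before each
decoder block. A 1×1 convolution and a per-pixel softmax over the `c`
classes produce the probability map. Each two-convolution block ends in
batch normalization followed by a rectifier. Same padding is used so the
predicted mask is pixel-aligned with the input; dice scores and
acquisition maps therefore cover the whole image.

The Bayesian treatment is Monte-Carlo dropout. Dropout multiplies weights
by Bernoulli masks, which can be read as sampling from an approximate
posterior over networks; keeping dropout **active at prediction time** and
averaging `T` stochastic forward passes approximates the posterior
predictive distribution. The package wires dropout in four benchmarkable
placements:

| variant            | dropout sites                                  |
|--------------------|------------------------------------------------|
| `plain`            | none                                           |
| `standard_dropout` | after every two-convolution block (`2·depth+1`)|
| `maxpool_dropout`  | immediately after each max pool (`depth`)      |
| `both`             | union of the two                               |

Max-pool dropout is the default: perturbing the pooled feature maps gives
usable epistemic uncertainty without the training instability that
convolution-layer dropout is known to cause.

Two prediction modes matter throughout:

* **standard prediction** — one forward pass with every dropout site
  disabled and batch normalization frozen at its running statistics;
  bit-reproducible.
* **MC prediction** — `T` passes with fresh dropout masks, averaged.
  The per-pass spread carries the model uncertainty.

Batch normalization itself can be made stochastic at inference
(re-estimating statistics per pass); this is exposed as the optional
`mcBatchnorm` flag and is off by default, because dropout is the
better-behaved and conventional stochasticity source and there is no
canonical protocol for batch sampling on single-image inference.

# Acquisition functions

All four scores reduce a per-pixel information quantity (in nats) to an
image score by **summation** over pixels, and images with the largest
scores are sent to the oracle.

* **Maximum entropy** — `sum_i H[p(y|x_i)]` of the MC mean prediction.
* **BALD** — mutual information between prediction and posterior:
  entropy of the per-pixel MC mean minus the mean of per-pass entropies.
  Computed entirely from the MC stack.
* **Committee KL** — `KL(standard ‖ MC mean)` summed over pixels: how much
  information is lost when the deterministic prediction is replaced by the
  posterior average.
* **Committee JSD** — the symmetric, bounded Jensen–Shannon counterpart;
  each pixel term lies in `[0, ln 2]`, which makes image scores well
  calibrated against each other.

Numerical rules, fixed so that rankings are deterministic: probabilities
are clamped to `[1e-12, 1]` and renormalized before any logarithm
(`0·log 0 := 0` for entropies); the BALD image sum is floored at zero,
since Jensen's inequality guarantees non-negativity analytically but
floating-point cancellation can leave a tiny negative residue on
near-deterministic stacks. Natural logarithms are used everywhere; the
choice of base does not affect rankings. Pixel sums (not means) follow the
explicit definition of the entropy-based scores; with equally sized images
the two differ only by a constant factor.

# The active-learning loop

Starting from `initialSize` randomly chosen labelled images, the loop
repeats: score a subset of the pool (`subsampleSize`, default the whole
pool), query the oracle for the top `k`, move them into the labelled set,
and retrain **from the current weights** (warm start) with early stopping
on the deterministic validation dice. A `random` acquisition arm is
included as the control baseline that makes efficacy claims testable.
Top-`k` ties are broken by the smallest image id; `k` larger than the
remaining pool returns the whole pool.

Training uses Adam at learning rate 0.001 and categorical cross-entropy,
the standard recipe for this architecture family. Early stopping keeps the
best-validation-dice snapshot with a default patience of 5 epochs within a
60-epoch budget — generalization on these tasks sets in well below 60
epochs, which is what makes repeated warm-start retraining cheap. The
validation set is fixed and held out; it never enters the pool.

The dice coefficient drives both early stopping and evaluation. For
multi-class masks the package reports the **macro average of one-vs-rest
binary dice over the classes present in the ground truth** (background
included when present). This is stated explicitly because a single "dice"
number for a 5- or 50-class problem is otherwise ambiguous; macro-over-
present-classes neither rewards predicting absent classes nor lets the
background class drown out small structures. Empty-vs-empty binary dice is
defined as 1 (the raw formula is 0/0 there).

# Synthetic data generator

The generator emulates the regime this method targets — multi-class 2-D
segmentation of textured objects on a dark background — while staying
small enough to train on a laptop CPU. Each image scatters 3–6 geometric
objects (discs, rectangles, rings; later objects occlude earlier ones)
whose class fixes an intensity band; the mask records the exact rendered
geometry; Gaussian intensity noise controls difficulty; and an affine
augmentation family (rotation, shift, isotropic scale, shear) applies the
same sampled transform to image (bilinear) and mask (nearest-neighbour,
background fill) via `EBImage::affine`. The default preset is 5 classes at
64×64 with noise sd 0.05, chosen as the smallest configuration that is
multi-class enough for acquisition functions to differ meaningfully while
keeping a full active-learning experiment in CPU minutes.

What the generator does **not** emulate: real microscopy point-spread
blur, inter-image illumination drift, annotation noise, and class
imbalance beyond background dominance. Tests passing on this generator
show the algorithmic machinery is correct and that uncertainty-driven
selection beats random selection *on this family*; they are not evidence
about any particular real imaging modality.

# Numerical and design choices

* **Convolution blocks**: conv–conv–batchnorm–rectifier; the first
  convolution is left linear inside a block (the rectifier follows every
  second convolution), with ReLUs between levels providing the
  nonlinearity stack.
* **Dropout rate** defaults to 0.5 (drop probability), exposed in
  `modelConfig()`; inverted scaling (`1/(1-p)`) at train/MC time keeps the
  deterministic pass rescale-free.
* **Initialization**: He-normal kernels, unit batch-norm scale, zero
  offsets; running statistics start at mean 0 / variance 1.
* **Batch-norm epsilon** 1e-5, running-average momentum 0.1, biased
  variance throughout.
* **T** defaults to 20 passes — enough for stable image rankings at
  desk scale; raise it for publication-grade uncertainty maps.
* **Desk-scale defaults**: depth 3, 16 base filters for general use;
  the bundled experiments use depth 2 with 8 filters, a 40-image pool,
  10 validation images, `T = 10`, and a 12-epoch/patience-3 training
  budget per iteration — the sizes at which the full pipeline (five
  paired seeds per acquisition arm) completes in CPU minutes.
* **Checkpoints** are single-file R serializations of the full parameter
  set and running statistics; a save/load round trip reproduces forward
  passes bit-identically.
* **Determinism**: every stochastic step (initialization, dropout masks,
  shuffling, pool subsampling, tie-free selection) draws from R's RNG
  under the caller's seed, so a whole active-learning run is reproducible
  byte-for-byte from its configuration. The per-iteration history
  deliberately records no wall-clock column; timing goes to the log
  stream, keeping result files comparable across runs.

A deliberate property of the transposed-convolution decoder: its 2×2
stride-2 kernel assigns different taps to the two output parities, so even
a constant input produces a (slight) period-2 pattern rather than an
exactly constant output. The network is equivariant to translations by the
pooling period `2^depth`, not to arbitrary translations; the test suite
asserts exactly that.

# Known limitations

* CPU-bound: the implementation targets method-level experiments at
  desk scale, not full-resolution training runs.
* 2-D only; no volumetric variant, attention blocks or pretrained
  encoders.
* Acquisition is purely uncertainty-based; batch diversity (avoiding `k`
  near-duplicate queries per round) is out of scope.
* The oracle is simulated by held-out masks and always answers; real
  annotation noise and refusal are not modelled.
* With very small validation sets the early-stopping signal is itself
  noisy; the defaults use 10 validation images, below which stopping can
  be erratic.
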