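---
title: "Attention-augmented residual networks for mammogram classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-augmented residual networks for mammogram classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hmcnet` implements a three-class mammogram classifier — normal, benign,
malignant — built from a 50-layer bottleneck residual backbone augmented
with four gamma-gated attention blocks, together with the surrounding
experimental machinery: preprocessing, augmentation, patient-level
cross-validation, CAM-based explainability with IoU localization scoring,
and a Friedman/Nemenyi statistical comparison harness. This vignette
documents the model, the numerical choices, and what the synthetic phantom
experiments do and do not demonstrate.

## The network

The backbone is a standard bottleneck residual network: a 7×7/2 stem with
batch normalization, ReLU and 3×3/2 max pooling, followed by four stages of
bottleneck blocks (3, 4, 6, 3 blocks; widths 256, 512, 1024, 2048 at
spatial sizes 56, 28, 14, 7 for 224-px input). All weights are trained from
scratch — no pre-trained layers — because mammographic texture statistics
differ substantially from natural-image corpora.

Four attention blocks share a single mechanism. For a query map $X$ and a
key/value map $Y$, both $(B, C, H, W)$:

$$Q = W_q * X,\quad K = W_k * Y,\quad V = W_v * Y,$$

with 1×1 convolutions $W_q, W_k \in \mathbb{R}^{C \times C/8}$ and
$W_v \in \mathbb{R}^{C \times C}$. After flattening the spatial grid to
$N = H\cdot W$ positions, the energies $E = Q^\top K$ are scaled by
$1/\sqrt{d_k}$ ($d_k = C/8$) and row-softmaxed into attention weights $A$,
each query position holding a distribution over key positions. The output
is the gated residual

$$\mathrm{Out} = \gamma \, (A V) + X,$$

where $\gamma$ is a learnable scalar initialized to exactly 0. The zero
gate is load-bearing: at initialization every attention block is the
identity, so all variants start from the plain backbone's function and the
attention pathways are grown smoothly during optimization. The test suite
asserts this identity bit-exactly.

The four instances are:

* **HA1, HA2** (hierarchical self-attention): $X = Y$ = the outputs of
  stages 1 and 2, refining within-stage spatial dependencies.
* **CA23, CA34** (multi-scale cross-attention): queries come from the
  deeper stage (3 or 4); keys/values come from the previous stage's
  attention-refined output after a channel-matching 1×1 convolution and
  bilinear resampling to the deeper stage's grid.

On scaling: the source formulation is ambiguous — the general energy
definition omits $1/\sqrt{d_k}$ while the per-block equations include it.
We apply the scaling uniformly in all four blocks; it is the standard
choice and keeps the softmax well-conditioned as $C$ grows. The 1×1
projections carry biases initialized to zero (harmless at $\gamma = 0$).
Attention memory is quadratic in position count, so `attend()` refuses maps
beyond a configurable `max_positions` cap rather than approximating.

The head is adaptive average pooling to 1×1 followed by a fully connected
layer to 3 logits; probabilities are the row softmax. Training minimizes
cross-entropy $L = -\sum_c t_c \log p_c$ with Adam
($\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$); the reference learning rate
is $10^{-4}$ with batch size 32. An optional step decay
(`lr_decay_epochs`) divides the rate at chosen epochs. An epoch budget is
not prescribed; the default is 50 and it is configurable. A fraction
(default 10%) of training *patients* is held out patient-wise for
validation curves.

All tensor primitives — convolution (kernel-offset decomposition into BLAS
matrix products), batch normalization, max pooling, attention, bilinear
resampling — carry hand-derived reverse-mode gradients. Each layer's
backward pass is validated against central finite differences in the unit
tests, and a whole-model check confirms that every trainable parameter,
including all four $\gamma$ gates, receives a finite gradient after one
step.

## Data pipeline

**Preprocessing.** Grayscale images in $[0,1]$ are bilinearly resized to
the network input (224 px reference; 64 px in the tiny preset), replicated
into three identical channels, and normalized with fixed mean and standard
deviation 0.5 into $[-1, 1]$.

**Augmentation** (training folds only): brightness and contrast factors
drawn uniformly in $[0.8, 1.2]$, horizontal flip with probability 0.5, and
rotation uniform in $\pm 15^\circ$ with zero fill. The application order —
jitter, then flip, then rotate — is not dictated by the protocol and is
fixed for reproducibility. Augmentation is on-the-fly per epoch; an
offline expansion to a fixed count is available through the phantom writer
if a fixed-size augmented corpus is wanted.

**MIAS format.** The reader parses the whitespace-delimited annotation
dialect (image id, background tissue, abnormality class, severity B/M, ROI
center x y, radius; `NORM` lines carry neither severity nor ROI) and 8-bit
PGM images in both binary and ASCII dialects. Images listed with several
abnormalities collapse to one record with label precedence malignant >
benign and a mask that is the union of the ROI discs. MIAS states
coordinates from a bottom-left origin, so mask rasterization flips the row
axis; getting this wrong visibly displaces every ROI. MIAS ships no
patient identifiers; consecutive pairing (records $2i-1, 2i$ share patient
$i$) reproduces the published two-films-per-patient count (322 images, 161
patients) and enables patient-level splits. This pairing is a convention,
not ground truth, and is isolated in one place.

**Patient-level k-fold.** Patients — never images — are shuffled and
partitioned into $k$ near-equal groups (sizes differ by at most one);
every image of a patient lands in exactly one test fold. The split
function asserts the absence of train/test patient overlap
programmatically before returning.

## The phantom generator

Real mammograms cannot ship with the package, so all end-to-end behavior
is exercised on a seeded synthetic phantom family:

* **normal** — a smooth low-frequency background (a 6×6 uniform random
  grid bilinearly upsampled, plus fine Gaussian noise, sd 0.02);
* **benign** — background plus one bright, near-circular blob (radius
  6–12% of the image side, mild ellipticity, Gaussian radial falloff,
  additive contrast drawn from $U(0.20, 0.35)$);
* **malignant** — background plus an irregular blob whose outline is
  modulated by angular harmonics of orders 2–5 (amplitudes up to 0.15)
  with 6–10 narrow radiating spicules extending 1.6–2.4 core radii, and
  higher contrast $U(0.40, 0.60)$.

The mask is the exact lesion support, so localization scores have perfect
ground truth. The contrast ordering and spiculation mimic the qualitative
radiological signature (malignant lesions more conspicuous and spiculated);
the class-conditional contrast ranges make the task learnable at desk
scale while the shape cue keeps it non-trivial. These defaults were fixed
once when the generator was designed. Construction properties are tested
statistically: lesions are brighter inside their masks, and malignant
masks have a larger perimeter²/area shape index than benign ones.

What phantom experiments demonstrate: that the full pipeline — generation,
splitting, augmentation, optimization, evaluation, explanation, scoring —
is correct and reproducible, and that the architecture can fit and
generalize on a 3-class imaging task at small scale. What they do not
demonstrate: clinical performance. Phantoms lack pectoral muscle, tissue
heterogeneity, acquisition artifacts, calcification clusters and label
noise; headline accuracies on them say nothing about screening mammograms.

## Explainers

All three explainers target the final attention-refined stage output
(x4′, 2048 channels at 7×7 at full size), so attention's effect is visible
in the maps. Heatmaps are bilinearly resized to the input resolution and
min–max normalized; a constant pre-normalization map (where normalization
is undefined) becomes all zeros.

* **Grad-CAM**: channel weights are spatial means of
  $\partial y_c / \partial A$ (pre-softmax score by default), map
  $= \mathrm{ReLU}(\sum_k \alpha_k A_k)$.
* **Grad-CAM++**: pixel weights use the closed form
  $\alpha_{ij} = G_{ij}^2 / (2 G_{ij}^2 + \sum A \cdot G_{ij}^3)$ in powers
  of first derivatives (higher-order derivatives are never materialized);
  pixels with vanishing denominators get weight 0. The default channel
  weight is $\sum_{ij} \alpha_{ij}\,\mathrm{ReLU}(G_{ij})$; a
  `literal_eq24` flag drops the ReLU factor, since the source text prints
  the aggregation without it and the two cannot be distinguished from the
  text alone.
* **Score-CAM** (gradient-free): each channel is min–max normalized and
  upsampled into a mask, multiplied into the input, and the masked image's
  softmax confidence for the target class becomes the channel weight.
  Channel passes run in configurable chunks; results are chunk-invariant.

Localization is scored as IoU between the heatmap binarized at a threshold
(0.5 by default) and the ground-truth mask resampled to heatmap resolution
by nearest neighbour; an empty union scores 0. Published IoU levels for
trained full-scale models (≈0.6–0.7) are a methodology reference point,
not a reproduction target for untrained desk-scale networks.

## Evaluation and statistics

Confusion matrices accumulate element-wise across folds. Metrics follow
the one-vs-rest definitions; macro averages are unweighted means over the
three classes. This macro convention is deliberate: the published fold-1
F1 (98.52) is not the harmonic mean of the printed precision and recall
(98.56), which is consistent with per-class macro-F1 rather than pooled
micro computation. Fold aggregation reports arithmetic mean ± sample
standard deviation (n−1); with five folds both sd conventions round to the
same printed accuracy spread, and the sample convention is documented.
AUC is macro one-vs-rest via the Mann–Whitney rank statistic on softmax
probabilities (the aggregation method behind the published AUC row is
unstated; this is the common default).

The comparison harness ranks $k$ models within each of $N$ folds (ties
averaged) and computes the Friedman statistic
$\chi^2_F = \frac{12N}{k(k+1)} \sum_j \bar R_j^2 - 3N(k+1)$ with a
$\chi^2_{k-1}$ p-value (a Monte Carlo permutation p-value over
within-fold rank permutations is available for small $N \cdot k$, where
the asymptotic approximation is coarse), Nemenyi pairwise p-values from
the studentized
range distribution at $|z|\sqrt 2$ (infinite df), and the critical
difference $CD = q_\alpha \sqrt{k(k+1)/(6N)}$. The reference comparison
(4 models, 5 folds) uses $q_\alpha = 2.949$, giving $CD = 2.41$; note that
the standard two-tailed $\alpha = 0.05$ table value for $k = 4$ is
≈ 2.569 (shipped as `q_nemenyi_05`), and the package takes $q_\alpha$ as a
caller-supplied argument so either convention is available. In the CD
diagram, pairs closer than CD are connected (non-significant); a gap of
exactly CD counts as significant — a boundary convention the tests pin
down.

## Numerical and design notes

* Bilinear resampling uses half-pixel centers without corner alignment;
  interpolation rows sum to 1, so constants are preserved exactly — this
  matters for the adapter identity tests and the degenerate heatmap rule.
* Batch normalization uses batch statistics in training mode and running
  statistics (momentum 0.1) at evaluation; singleton batches fall back to
  running statistics.
* The cross-entropy is the standard negative form; optimization requires a
  minimized loss.
* No class weighting is applied despite the 207/64/51 imbalance of the
  reference dataset, matching the stated protocol.
* Zero-denominator metric cells (empty classes) return 0 and set a flag
  rather than NaN.
* Checkpoints serialize parameters, batch-norm running statistics, the
  configuration, variant and seed under a schema version.

## Problem sizes used in the shipped experiments

The test suite and acceptance script run entirely on the tiny preset
(64-px input, stage widths divided by 8) and micro presets (custom stage
widths at 32–64 px): attention oracles on grids up to 3×3 with 8–16
channels, explainer oracles on 2×2 target maps, and one training run of
300 phantoms (240 training / 60 held-out patients, batch 32, learning rate
2·10⁻³ decayed ×0.1 at epoch 32 of 40) chosen so a single CPU core
completes the whole battery comfortably. The learning-rate choice for this
small-scale run is hotter than the full-scale reference (10⁻⁴) because the
tiny network trains from scratch on a small corpus; the step decay settles
batch-norm statistics near the end. These sizes are the package's own
desk-scale experimental design.

## Known limitations

* The backbone is implemented in interpreted R over BLAS; it is intended
  for desk-scale experiments and method study, not for full-resolution
  GPU-scale training. Full-size forward passes work (seconds per image);
  full-size training is out of practical reach here.
* Single-head attention only, as specified; no sparse or linear-time
  attention approximations.
* No DICOM/FFDM input, no pectoral-muscle removal or breast-boundary
  segmentation.
* The phantom family is a stand-in: synthetic, simplified, and labelled by
  construction.
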