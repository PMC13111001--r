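# hmcnet

Attention-augmented residual networks for three-class mammogram
classification (normal / benign / malignant), with CAM-based
explainability, localization scoring, and a statistical model-comparison
harness — implemented entirely in base R on BLAS matrix products, so the
whole pipeline runs on a CPU with no deep-learning framework.

## Who this is for

Researchers studying attention mechanisms and saliency methods in
mammography CAD who want a transparent, fully inspectable reference
implementation: every primitive (convolution, batch normalization,
gamma-gated attention, reverse-mode gradients, Adam) is plain R code
validated against finite differences and brute-force oracles, and every
experimental control (patient-level splitting, augmentation, seeding) is
explicit.

## The model

A 50-layer bottleneck residual backbone (stage widths 256, 512, 1024, 2048
at 56², 28², 14², 7² for 224-px input), trained from scratch, augmented
with four attention blocks sharing one mechanism. For query map X and
key/value map Y:

    Q = Wq * X,  K = Wk * Y,  V = Wv * Y          (1x1 convolutions, C -> C/8 for Q, K)
    A = softmax( QᵀK / sqrt(d_k) )                 (row-stochastic over key positions)
    Out = gamma * (A V) + X                        (gamma learnable, initialized to 0)

- **HA1, HA2** — hierarchical self-attention (X = Y) refining stages 1 and 2;
- **CA23, CA34** — multi-scale cross-attention: queries from stage 3 (resp. 4),
  keys/values from the previous refined stage after a 1x1 channel-match and
  bilinear resampling.

Because gamma starts at 0, every variant's logits coincide with the plain
backbone's at initialization — the test suite asserts this bit-exactly.
Training minimizes cross-entropy with Adam; evaluation uses patient-level
k-fold cross-validation (all images of a patient in exactly one test
fold). Explainers (Grad-CAM, Grad-CAM++, Score-CAM) target the final
attention-refined stage; localization is scored as IoU between the
binarized heatmap and the ground-truth ROI mask. Model variants are
compared with a Friedman rank test, Nemenyi post-hoc p-values, and a
critical-difference diagram, CD = q_alpha * sqrt(k(k+1)/(6N)).

Inputs: MIAS-style data (PGM images plus the whitespace-delimited
annotation file with circular ROIs) or the built-in seeded phantom
generator, which emulates the three classes with exact lesion masks so the
whole pipeline runs with no download.

## Worked example

```r
library(hmcnet)

# 1. synthesize a small phantom cohort (two images per pseudo-patient)
phantoms <- generate_phantoms(n = 120, size = 64, seed = 1)
ds <- phantom_dataset(phantoms)

# 2. patient-level 3-fold cross-validated training of the attention model
cfg <- run_config(n_phantoms = 120, image_size = 64, variant = "hmc",
                  folds = 3, epochs = 30, batch_size = 32, lr = 2e-3, seed = 1)
out <- run_experiment(cfg, "runs/demo")      # ~5 min on one CPU core
print(attr(out, "aggregate")[, c("metric", "formatted")])
#>       metric     formatted
#>     accuracy  85.00 ± 9.01
#>  sensitivity  85.16 ± 8.58
#>  specificity  92.42 ± 4.56
#>    precision  89.35 ± 6.42
#>           f1 83.22 ± 10.54
#>          auc   0.96 ± 0.03

# 3. explain one malignant test image and score its localization
model <- load_checkpoint(file.path(out, "fold1.ckpt"))
i <- which(ds$labels == 2)[1]
hm <- grad_cam(model, preprocess_image(ds$images[[i]], 64), class_index = 2)
localization_iou(hm, ds$masks[[i]], threshold = 0.5)
#> [1] 0.142

# 4. compare four model variants across five folds
mk <- function(base) data.frame(fold = 1:5, accuracy = base - (1:5) * 0.01)
res <- run_compare(list(hmc = mk(99.7), hierarchical = mk(99.5),
                        multiscale = mk(99.4), baseline = mk(99.2)),
                   q_alpha = 2.949)
sprintf("Friedman chi2 = %.1f (p = %.4f), CD = %.2f",
        res$friedman$statistic, res$friedman$p_value, res$CD)
#> [1] "Friedman chi2 = 15.0 (p = 0.0018), CD = 2.41"
res$cd$significant_pairs
#>  model_i  model_j diff
#>      hmc baseline    3
```

The aggregate table is mean ± sample sd over fold-level metrics (rates in
percent); with a strict ordering of four models over five folds the
Friedman statistic reaches its analytic maximum of 15, and at the
reference critical value q = 2.949 the critical difference is 2.41, so
only rank gaps above 2.41 are flagged significant. The demo run above is
deliberately small; the 300-phantom configuration used by the test suite
reaches 98% held-out accuracy. A command-line wrapper over the same
functions (subcommands `synth`, `train`, `explain`, `localize`,
`compare`) ships in `inst/cli/hmcnet.R`.

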