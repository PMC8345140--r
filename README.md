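# nucquant

Quantification of nuclear IHC biomarker-positive cells in stained tissue
images, with downstream survival stratification. The motivating use case is
the immune-checkpoint marker ICOS in colorectal-cancer tissue microarrays:
DAB-brown nuclei are segmented in RGB patches, touching nuclei are separated
into instances, per-core cell densities (cells/mm²) are estimated, and a
density cutoff is used to stratify patients into prognostic groups.

The package is aimed at computational-pathology researchers who want the
whole chain — data preparation, model, post-processing, evaluation, and
survival analysis — in one reproducible, dependency-light R workflow, plus a
synthetic-data module so every stage can be developed and tested without
access to clinical images.

## What it implements

**Semantic segmentation.** A from-scratch U-Net: four contraction blocks of
two 3×3 convolutions + ReLU with 2×2 max-pooling, a two-convolution
bottleneck, four expansion blocks of a 2×2 up-convolution with skip
concatenation and two 3×3 convolutions, and a final 1×1 projection — 23
convolutional layers in the reference configuration. Training supports Adam
and SGD with Nesterov momentum (0.9), weight decay 3×10⁻⁵, an initial
learning rate of 0.002 reduced on validation plateau, and a menu of losses:
BCE, soft Dice, soft IoU (`1 − Σpy / (Σp + Σy − Σpy)`), focal (γ=2,
α=0.25) and Lovász hinge, combinable as unweighted sums (e.g. BCE+IoU).
Forward and backward passes are BLAS-backed im2col convolutions in base R;
the backpropagation is validated against finite differences in the test
suite.

**Instance separation.** The probability map is thresholded (default 0.5,
ties to foreground), the Euclidean distance transform is computed, regional
extrema with dynamic below a depth `h` are suppressed (h-minima/extended
minima imposition) and the watershed assigns every foreground pixel to one
nucleus. `h` is in pixel-distance units; for two touching discs of radius
`r` at centre distance `d` the relevant dynamic is
`r·(1 − sqrt(1 − (d/2r)²))`, so `h` must be chosen below that value to
split them (see the methods vignette).

**Evaluation.** Pixel accuracy/sensitivity/specificity, Dice
`2TP/(2TP+FP+FN)`, pooled ROC/PR curves with trapezoidal AUC, object-level
precision/recall from one-to-one IoU matching, a Table-style
threshold-sweep report, and the aggregated Jaccard index

```
AJI = Σᵢ |GTᵢ ∩ PD_j*(i)| / ( Σᵢ |GTᵢ ∪ PD_j*(i)| + Σ_{k unused} |PD_k| )
```

with the established per-GT argmax-Jaccard matching (each prediction
consumed at most once, unmatched predictions penalising the denominator).

**Survival stratification.** Cell density per mm² from instance counts and
the µm/px scale, Pearson concordance against reference densities,
time-dependent ROC (cumulative cases / dynamic controls with reverse-KM
censoring weights) to pick the Youden-optimal density cutoff, Kaplan–Meier
curves per group and a 5-year log-rank test.

**Synthetic data.** `generate_patch()` renders DAB-brown elliptical nuclei
(controllable touching fraction, stain jitter, background texture, noise)
with exact instance ground truth; `generate_cohort()` draws survival data
whose hazard depends on density through a log hazard ratio. Both are
seed-deterministic.

## Worked example

```r
library(nucquant)
cfg <- pipeline_config(out_dir = file.path(tempdir(), "demo-run"), seed = 1)
res <- run_pipeline(cfg)   # synth -> split -> train -> predict -> segment -> eval -> survival
print(res$model)
```

```
U-Net semantic segmentation model
  encoder: paper-unet, depth 3, base channels 8
  convolutional layers: 18
  parameters: 120,825
  trained 20 epochs; best val Dice 0.9729 (epoch 20)
```

The demo trains a small U-Net (depth 3, 8 base channels) on 36 synthetic
64×64 patches for 20 epochs (a few seconds on one CPU core) and evaluates
on the held-out test partition:

```r
res$metrics$dice_mean      # 0.983  pixel Dice on test patches
res$metrics$aji_mean       # 0.870  aggregated Jaccard index after watershed
res$concordance            # 0.9685 Pearson R, detected vs true density
print(res$strat)
```

```
Survival stratification by marker density
  optimal cutoff (Youden): 123.94 cells/mm2 (td-ROC AUC 0.735)
  groups: n1 = 128 (high), n2 = 72 (low)
  log-rank (5-year): chi2 = 30.866, df = 1, p = 2.765e-08
```

Here the synthetic cohort (n = 200) was generated with a strong
density→hazard effect, and the stratification chain recovers it: patients
above the data-driven density cutoff have markedly worse survival. Note the
log-rank p-value is exploratory — the cutoff was optimised on the same
cohort (see the vignette's limitations section).

A thin command-line wrapper over the same functions is installed at
`inst/cli/nucquant.R` (`synth`, `split`, `train`, `predict`, `segment`,
`eval`, `survival`, `run` subcommands).

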