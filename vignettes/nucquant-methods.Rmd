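---
title: "Methods: nuclear IHC cell quantification and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear IHC cell quantification and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucquant)
```

# The problem

Immunohistochemistry (IHC) renders cells expressing a nuclear biomarker —
the motivating case is the immune checkpoint ICOS — as DAB-brown nuclei on
a lightly counterstained background. Quantifying a patient's biomarker
burden requires (i) finding the positive pixels, (ii) resolving them into
individual nuclei even when nuclei touch, (iii) converting counts into a
density per mm² of analysed tissue, and (iv) relating that density to
outcome. This package implements that chain end to end and ships a
synthetic-data module so that every stage is testable without clinical
images.

# Semantic segmentation model

The segmentation network is the classic U-Net encoder–decoder.
`unet_config()` fixes the architecture:

* `depth` contraction blocks (default 4), each two 3×3 same-padding
  convolutions + ReLU; 2×2 max-pooling between blocks. Block *k* (0-based)
  has `base_channels * 2^k` channels (default base 64).
* a bottleneck of two 3×3 convolutions,
* `depth` expansion blocks: a 2×2 stride-2 up-convolution, concatenation
  with the same-resolution encoder output, then two 3×3 convolutions,
* a final 1×1 convolution projecting to a single foreground logit.

With the defaults the layer walk (`count_conv_layers()`) counts
8 + 2 + 4 + 8 + 1 = 23 convolutional layers. The binary problem is emitted
as one sigmoid logit rather than a 2-class softmax map; the two are
mathematically equivalent and the single logit keeps the loss menu simple.
The `encoder` argument names the backbone; only the from-scratch
`"paper-unet"` is shipped — pretrained encoders are external binary
artefacts, and the argument is the seam where alternatives can be plugged
in.

All tensor work is done in base R as im2col + BLAS matrix products; the
backward pass is hand-derived and is checked against central finite
differences (tolerance 10⁻⁵) in the test suite, which is the strongest
practical guard for hand-rolled backpropagation.

## Training

`train_config()` defaults follow the reference recipe: initial learning
rate 0.002 (Adam or SGD with Nesterov momentum 0.9), weight decay 3×10⁻⁵,
mini-batches of 4. "Dynamic learning rate based on validation improvement"
is realised as reduce-on-plateau: if the monitored metric does not improve
by `min_delta` for `lr_patience` epochs (default 5) the rate is multiplied
by `lr_factor` (default 0.1). The monitored metric is mean per-patch soft
Dice on the train-val partition — the natural segmentation metric; the
training loss is used when no validation set is supplied. The parameters of
the best-validation epoch are returned, not the last ones.

Loss components operate on probabilities `p` (soft Dice and soft IoU as
`1 −` the smoothed overlap ratio with +1 smoothing, focal with γ = 2 and
α = 0.25, Lovász hinge on the foreground logit). Combinations are
unweighted sums by default, matching the common "BCE+IoU" notation; weights
are exposed for completeness.

# Instance separation

`segment_nuclei()` composes three steps:

1. **Threshold** the probability map at `prob_threshold` (default 0.5);
   ties go to foreground — the rule is documented and tested because it is
   observable at exactly-0.5 probabilities.
2. **Distance transform + h-minima watershed.** The Euclidean distance to
   the nearest background pixel is computed (EBImage; the image border
   counts as background so distances are always finite), and the watershed
   floods it after suppressing shallow regional extrema: any basin whose
   dynamic (height difference between its peak and the saddle to a
   neighbouring basin) is below `h` is merged. 8-connectivity throughout.
3. **Area filter**: instances below `min_area` pixels are dropped (default
   off; 30 px is a sensible choice at 0.25 µm/px for removing stain
   specks), and labels are renumbered consecutively.

## Choosing h

`h` is in pixel-distance units. For two overlapping discs of radius `r`
with centre distance `d`, the saddle of the distance map has height
`sqrt(r² − (d/2)²)` and the peaks height ≈ `r`, so the pair separates only
when

```
h  <  r · (1 − sqrt(1 − (d/2r)²))
```

For near-tangent nuclei (`d → 2r`) the dynamic approaches `r` and a large
`h` is safe; for heavily overlapping pairs (`d ≈ 1.2–1.5 r`) the dynamic is
only ~0.2–0.4 `r`. The shipped default is `h = 6`, the value tuned for ICOS
nuclei imaged at 40× / 0.25 µm per pixel (nucleus radii around 12–15 px and
mostly modest overlap). For the small synthetic nuclei used in the demo
pipeline (radius 4–9 px) the same formula demands `h ≈ 1–2`, which is what
`pipeline_config()` uses. This scale dependence is a property of
distance-transform watershed, not of the implementation: `h` should scale
with nucleus radius, roughly `h ≈ r/3` to split everything down to
`d ≈ 1.5 r`. Increasing `h` can only merge basins, so the instance count is
non-increasing in `h` (tested as an invariant).

# Evaluation

Pixel metrics follow the confusion matrix: accuracy, sensitivity
`TP/(TP+FN)`, specificity `TN/(TN+FP)` and Dice `2TP/(2TP+FP+FN)`.
Whenever a denominator is empty (e.g. sensitivity on an all-background
patch) the metric is reported as `NA` and excluded from means — never
silently coerced to 0 or 1.

ROC and precision–recall curves are computed on pixels pooled over patches
(per-patch curves are available via `pooled = FALSE`), sweeping every
distinct score and integrating by the trapezoidal rule along the curve.

The aggregated Jaccard index follows the established convention: every
ground-truth instance selects the available prediction maximising their
Jaccard index (ground truths processed in descending best-Jaccard order,
each prediction consumed at most once, ties to the lower prediction label);
matched intersections form the numerator, matched unions plus all pixels of
never-matched predictions the denominator. Two properties are worth
stating. First, the definition is procedural, not an optimisation: the
greedy value can be strictly below the best assignment of the same
objective, which is why the test suite checks *equality* against an
independent first-principles implementation of the definition and
*boundedness* against an exhaustive all-assignments maximiser. Second,
AJI = 1 exactly when the maps are identical up to relabelling.

Object-level precision/recall uses one-to-one greedy IoU matching with an
explicit match criterion (default IoU ≥ 0.5, exposed as an argument since
any object-level "true positive" definition must be stated to be testable).
`threshold_sweep()` re-runs the full post-processing per probability
threshold and pools matched/unmatched counts across patches, giving the
standard threshold-vs-precision/recall table.

# Density and survival

`cell_density()` converts an instance count and the analysed pixel area to
cells/mm² via the µm/px scale (default 0.25, a 40× scan); the analysed
area is the pixel count of an optional tissue mask, not a nominal core
area, so artefact exclusions propagate correctly.

`stratify_survival()` implements the downstream chain. The time-dependent
ROC at horizon `t` (default 5 years) uses cumulative cases (event by `t`)
and dynamic controls (still at risk after `t`); cases are weighted by
inverse probability of censoring from the reverse Kaplan–Meier estimate,
with a naive unweighted variant behind `ipcw = FALSE` for comparison. The
cutoff maximises Youden's J, ties resolved toward the lower cutoff so the
high-density group is as inclusive as possible. "5-year survival" testing
administratively censors all observations at the horizon before the
two-group log-rank test (survival::survdiff).

**Limitation — cutoff-selection bias.** Because the cutoff is optimised on
the same cohort that the log-rank test is then applied to, the p-value does
not hold its nominal level: the acceptance suite simulates the full chain
under a null (density-independent hazard) and observes a rejection rate of
roughly 20–25% at the 5% level, the familiar optimal-cutpoint inflation.
The reported p-value should therefore be read as exploratory; a validated
cutoff requires an independent cohort. The package reports the machinery
faithfully and documents the caveat rather than hiding it.

# Synthetic data: what it does and does not emulate

`generate_patch()` draws `n_nuclei` filled ellipses (major semi-axis
uniform in `radius`, minor 0.6–1× major, random orientation), places a
`touching_fraction` of them as overlapping pairs whose centre distance is
0.55–0.85 of the summed effective radii along the connecting direction (so
contact is guaranteed and neither nucleus is swallowed), renders foreground
in DAB-brown (default RGB 115, 70, 40) with per-nucleus log-normal
intensity jitter (sd 0.08), background in a light tint (228, 220, 228)
with low-frequency plane-wave texture, and adds clipped Gaussian pixel
noise (sd 8 of 255). Within a pair the later label owns contested pixels,
so the ground truth stays two instances while the silhouettes form one
blob. All randomness flows from one integer seed through R's Mersenne–
Twister, with the caller's RNG state restored.

`generate_cohort()` draws density from a log-normal (default
meanlog = log 150, sdlog = 0.6 — a plausible spread of positive-cell
densities across cores), event times from an exponential with hazard
`baseline_hazard · exp(log_hr_per_density · density)` (defaults 0.08/year
and 0.01 per cell/mm², i.e. a strong prognostic effect spanning hazard
ratios of ~e⁰·⁸–e³ across the density range), exponential censoring
(0.05/year) and a 10-year administrative cap. These defaults were chosen
once as a realistic stress condition and are not tuned to any dataset.

What the generator does **not** emulate: chromatin texture inside nuclei,
stain co-localisation and deconvolution ambiguity, out-of-focus blur,
tissue folds and artefacts, non-elliptical nucleus shapes, and clustered
(more-than-pairwise) nuclei. Passing tests on synthetic data therefore
demonstrates the correctness of the pipeline's computations and its
behaviour under controlled difficulty — not clinical-grade accuracy on real
slides, which requires real annotated data.

# Numerical and design choices

* Coordinates are row-major, origin top-left, 0 background everywhere;
  connected components and watershed adjacency use 8-connectivity (own
  vectorised label-propagation labeller; the 4-connected alternative merges
  fewer diagonal contacts and is not used).
* Splitting uses largest-remainder rounding of the 60/10/30 ratios with
  remainder ties broken in partition order; an optional group key assigns
  whole patients/cores to one partition to prevent leakage (the natural
  reading when patch-level and patient-level data mix).
* Geometric augmentations apply the identical transform to image and
  masks; masks are resampled nearest-neighbour. The elastic field is the
  curl of a smoothed random potential, hence divergence-free and locally
  area-preserving — flips conserve foreground exactly, elastic and
  rotation conserve it within a few percent (resampling error only).
  Elastic uses mirrored borders; shift-scale-rotate uses constant fill so
  border content is clipped, not duplicated.
* Mask files are 16-bit single-channel TIFF (8-bit PNG cannot hold label
  ids); images are 8-bit PNG.
* Loss smoothing constants are +1 in soft Dice/IoU; probabilities are
  clipped to [10⁻⁷, 1−10⁻⁷] inside logarithms.
* He-normal initialisation; per-image gradient accumulation within a
  mini-batch; weight decay added to the gradient (classic L2).
* Problem sizes in the shipped tests and acceptance script — 64×64
  patches, 50-patch training sets, 30 epochs, depth-3/8-channel smoke
  models, 200-patient cohorts, 200 touching-pair fixtures, 1000 null
  replicates — are the package's chosen demonstration scale: large enough
  for the statistical checks they support, small enough to run routinely.

# Known limitations

* The default `h = 6` presumes 40×/0.25 µm-per-pixel nuclei; users working
  at other scales must rescale `h` (see the formula above) or sweep it.
* The log-rank p-value after data-driven cutoff selection is exploratory
  (see above).
* Training is single-threaded CPU; the architecture is intentionally small
  and the package is not a general deep-learning framework.
* The Lovász gradient uses the standard constant-weights subgradient, so
  finite-difference checks agree only to ~10⁻³ for that component.
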