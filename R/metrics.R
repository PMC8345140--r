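#' Pixel-level confusion counts
#'
#' @param pred,gt binary matrices of identical shape (anything `> 0` counts
#'   as foreground).
#' @return a list with integer counts `tp`, `fp`, `tn`, `fn` partitioning
#'   all pixels.
#' @export
pixel_confusion <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("pred and gt shapes differ")
  p <- pred > 0; g <- gt > 0
  list(tp = sum(p & g), fp = sum(p & !g), tn = sum(!p & !g), fn = sum(!p & g))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`.
#' Metrics with an empty denominator are reported as `NA` (absent), never
#' coerced to 0 or 1.
#'
#' @param counts a list with `tp`, `fp`, `tn`, `fn` as from
#'   [pixel_confusion()].
#' @return named numeric vector `c(acc, sen, spe)`.
#' @export
pixel_metrics <- function(counts) {
  tot <- counts$tp + counts$fp + counts$tn + counts$fn
  if (tot == 0) stop("empty confusion: no pixels")
  sen <- if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn) else NA_real_
  spe <- if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp) else NA_real_
  c(acc = (counts$tp + counts$tn) / tot, sen = sen, spe = spe)
}

#' Pixel-level Dice coefficient
#'
#' `Dice = 2 TP / (2 TP + FP + FN)`; symmetric in its arguments. When both
#' masks are empty the denominator vanishes and `NA` is returned.
#'
#' @inheritParams pixel_confusion
#' @return Dice coefficient in `[0, 1]`, or `NA`.
#' @export
dice_pixel <- function(pred, gt) {
  cts <- pixel_confusion(pred, gt)
  den <- 2 * cts$tp + cts$fp + cts$fn
  if (den == 0) return(NA_real_)
  2 * cts$tp / den
}

# pairwise intersection table between two label maps ->
# list(int = matrix K_gt x K_pd, gt_area, pd_area)
overlap_table <- function(gt, pred) {
  kg <- max(gt); kp <- max(pred)
  gt_area <- if (kg > 0) tabulate(gt[gt > 0], nbins = kg) else integer(0)
  pd_area <- if (kp > 0) tabulate(pred[pred > 0], nbins = kp) else integer(0)
  int <- matrix(0L, kg, kp)
  both <- gt > 0 & pred > 0
  if (any(both) && kg > 0 && kp > 0) {
    idx <- (pred[both] - 1L) * kg + gt[both]
    tab <- tabulate(idx, nbins = kg * kp)
    int <- matrix(tab, kg, kp)
  }
  list(int = int, gt_area = gt_area, pd_area = pd_area)
}

#' Aggregated Jaccard Index (AJI)
#'
#' Instance-segmentation metric: each ground-truth instance is matched with
#' the predicted connected component maximising their Jaccard index, every
#' prediction may be consumed at most once (matching is greedy over
#' ground-truth instances in descending best-Jaccard order; ties broken by
#' the lower prediction label), and predictions never matched penalise the
#' denominator:
#' `AJI = sum |GT_i & PD_j*(i)| / (sum |GT_i | PD_j*(i)| + sum_{k unused} |PD_k|)`.
#'
#' @param gt,pred integer instance label maps of identical shape.
#' @return AJI in `[0, 1]` (1 iff the maps are identical up to relabelling);
#'   `NA` when both maps are empty.
#' @examples
#' gt <- matrix(0L, 4, 4); gt[1:2, 1:2] <- 1L
#' pd <- matrix(0L, 4, 4); pd[2:3, 1:2] <- 1L
#' aji(gt, pd)  # 2 / 6
#' @export
aji <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) stop("gt and pred shapes differ")
  ov <- overlap_table(gt, pred)
  kg <- length(ov$gt_area); kp <- length(ov$pd_area)
  if (kg == 0 && kp == 0) return(NA_real_)
  if (kg == 0) return(0)
  if (kp == 0) return(0)
  uni <- outer(ov$gt_area, ov$pd_area, "+") - ov$int
  jac <- ifelse(uni > 0, ov$int / uni, 0)
  best <- apply(jac, 1, max)
  ord <- order(best, decreasing = TRUE)
  used <- logical(kp)
  num <- 0; den <- 0
  for (i in ord) {
    cand <- which(!used & ov$int[i, ] > 0)
    if (length(cand) == 0L) {
      den <- den + ov$gt_area[i]
      next
    }
    j <- cand[which.max(jac[i, cand])]  # which.max takes the lowest index on ties
    used[j] <- TRUE
    num <- num + ov$int[i, j]
    den <- den + uni[i, j]
  }
  den <- den + sum(ov$pd_area[!used])
  if (den == 0) return(NA_real_)
  num / den
}

#' One-to-one object matching by IoU
#'
#' Greedy matching over all (ground truth, prediction) pairs in descending
#' IoU order; a pair is accepted when both objects are still unmatched and
#' their IoU reaches `iou_threshold`.
#'
#' @param gt,pred integer instance label maps of identical shape.
#' @param iou_threshold minimum IoU in `(0, 1]` for a match.
#' @return a list with `pairs` (data.frame `gt`, `pred`, `iou`),
#'   `unmatched_gt` and `unmatched_pred` (integer label vectors).
#' @export
match_objects <- function(gt, pred, iou_threshold = 0.5) {
  if (!all(dim(gt) == dim(pred))) stop("gt and pred shapes differ")
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must be in (0, 1]")
  ov <- overlap_table(gt, pred)
  kg <- length(ov$gt_area); kp <- length(ov$pd_area)
  pairs <- data.frame(gt = integer(0), pred = integer(0), iou = numeric(0))
  if (kg > 0 && kp > 0) {
    uni <- outer(ov$gt_area, ov$pd_area, "+") - ov$int
    iou <- ifelse(uni > 0, ov$int / uni, 0)
    cand <- which(iou >= iou_threshold, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(iou[cand], decreasing = TRUE), , drop = FALSE]
      g_used <- logical(kg); p_used <- logical(kp)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (g_used[i] || p_used[j]) next
        g_used[i] <- TRUE; p_used[j] <- TRUE
        pairs <- rbind(pairs, data.frame(gt = i, pred = j, iou = iou[i, j]))
      }
    }
  }
  list(
    pairs = pairs,
    unmatched_gt = setdiff(seq_len(kg), pairs$gt),
    unmatched_pred = setdiff(seq_len(kp), pairs$pred)
  )
}

#' Object-level precision and recall from a matching
#'
#' `precision = matched / (matched + unmatched predictions)`,
#' `recall = matched / (matched + unmatched ground truth)`. An empty
#' denominator yields `NA` (e.g. precision with no predictions).
#'
#' @param m a matching as returned by [match_objects()].
#' @return named numeric vector `c(precision, recall)`.
#' @export
object_pr <- function(m) {
  tp <- nrow(m$pairs)
  np <- tp + length(m$unmatched_pred)
  ng <- tp + length(m$unmatched_gt)
  c(precision = if (np > 0) tp / np else NA_real_,
    recall = if (ng > 0) tp / ng else NA_real_)
}

# internal: threshold-free ROC / PR points from pooled scores
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  P <- sum(l); N <- length(l) - P
  if (P == 0 || N == 0) stop("ROC needs both classes present")
  tp <- cumsum(l); fp <- cumsum(1 - l)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  data.frame(threshold = s[keep], tpr = tp[keep] / P, fpr = fp[keep] / N,
             precision = tp[keep] / (tp[keep] + fp[keep]))
}

# trapezoidal integration along an already-ordered curve (x non-decreasing;
# vertical segments contribute nothing). Points must be passed in curve
# order, not re-sorted, so staircase ROC corners are integrated correctly.
trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Pixel-pooled ROC and precision-recall curves
#'
#' Pools all pixels of the supplied probability maps against their binary
#' ground truths, sweeps every distinct score as a threshold and integrates
#' both curves by the trapezoidal rule. With `pooled = FALSE` a list of
#' per-patch curves is returned instead.
#'
#' @param probs a probability matrix or list of matrices.
#' @param gts a binary matrix or list of matrices, paired with `probs`.
#' @param pooled pool pixels across patches (default) or compute per patch.
#' @return a list with `roc` (data.frame `threshold`, `tpr`, `fpr`),
#'   `auc_roc`, `pr` (data.frame `threshold`, `recall`, `precision`) and
#'   `auc_pr`.
#' @export
roc_pr_curves <- function(probs, gts, pooled = TRUE) {
  if (is.matrix(probs)) probs <- list(probs)
  if (is.matrix(gts)) gts <- list(gts)
  if (length(probs) != length(gts)) stop("probs and gts lengths differ")
  if (!pooled)
    return(mapply(function(p, g) roc_pr_curves(p, g, pooled = TRUE),
                  probs, gts, SIMPLIFY = FALSE))
  s <- unlist(lapply(probs, as.vector))
  l <- unlist(lapply(gts, function(g) as.vector(g > 0) * 1))
  pts <- roc_points(s, l)
  roc <- pts[, c("threshold", "tpr", "fpr")]
  auc_roc <- trapezoid(c(0, roc$fpr, 1), c(0, roc$tpr, 1))
  pr <- data.frame(threshold = pts$threshold, recall = pts$tpr,
                   precision = pts$precision)
  auc_pr <- trapezoid(c(0, pr$recall), c(pr$precision[1], pr$precision))
  list(roc = roc, auc_roc = auc_roc, pr = pr, auc_pr = auc_pr)
}

#' Object-level precision/recall over a probability-threshold sweep
#'
#' For each threshold the full post-processing chain is run
#' ([segment_nuclei()] with that threshold), objects are matched against the
#' ground-truth instances and matched/unmatched counts are pooled across
#' patches before computing precision and recall — one row per threshold.
#'
#' @param probs list of probability matrices.
#' @param gt_instances list of ground-truth instance label maps.
#' @param thresholds ascending numeric vector of probability thresholds.
#' @param h minima-imposition depth passed to [segment_nuclei()].
#' @param iou_threshold object-match IoU criterion.
#' @param min_area minimum instance area in pixels.
#' @return data.frame with columns `threshold`, `precision`, `recall`.
#' @export
threshold_sweep <- function(probs, gt_instances,
                            thresholds = seq(0.30, 0.50, by = 0.05),
                            h = 6, iou_threshold = 0.5, min_area = 0) {
  if (is.unsorted(thresholds, strictly = FALSE))
    stop("thresholds must be sorted ascending")
  if (is.matrix(probs)) probs <- list(probs)
  if (is.matrix(gt_instances)) gt_instances <- list(gt_instances)
  res <- lapply(thresholds, function(th) {
    tp <- fp <- fn <- 0
    params <- postproc_params(prob_threshold = th, h = h, min_area = min_area)
    for (i in seq_along(probs)) {
      lab <- segment_nuclei(probs[[i]], params)
      m <- match_objects(gt_instances[[i]], lab, iou_threshold)
      tp <- tp + nrow(m$pairs)
      fp <- fp + length(m$unmatched_pred)
      fn <- fn + length(m$unmatched_gt)
    }
    data.frame(
      threshold = th,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    )
  })
  do.call(rbind, res)
}
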