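# Pixel metrics, Dice, AJI, object matching and curves

test_that("pixel confusion partitions pixels and matches brute force", {
  g <- matrix(0L, 10, 10); g[1:5, 1:6] <- 1L
  expect_equal(pixel_confusion(g, g), list(tp = 30, fp = 0, tn = 70, fn = 0))
  inv <- 1L - g
  cc <- pixel_confusion(inv, g)
  expect_equal(cc$tp, 0); expect_equal(cc$tn, 0)
  # crafted and random cases against a per-pixel tally
  for (s in 1:10) {
    set.seed(s)
    a <- matrix(rbinom(16, 1, 0.5), 4, 4)
    b <- matrix(rbinom(16, 1, 0.5), 4, 4)
    cts <- pixel_confusion(a, b)
    tally <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (i in 1:4) for (j in 1:4) {
      key <- if (a[i, j] && b[i, j]) "tp" else if (a[i, j]) "fp"
        else if (b[i, j]) "fn" else "tn"
      tally[key] <- tally[key] + 1
    }
    expect_equal(unlist(cts)[names(tally)], tally)
    expect_equal(sum(unlist(cts)), 16)
  }
  expect_error(pixel_confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("pixel metrics follow their formulas and the absent rule", {
  m <- pixel_metrics(list(tp = 50, tn = 40, fp = 5, fn = 5))
  expect_equal(m, c(acc = 0.90, sen = 50 / 55, spe = 40 / 45))
  expect_equal(pixel_metrics(list(tp = 30, tn = 70, fp = 0, fn = 0)),
               c(acc = 1, sen = 1, spe = 1))
  # all-negative ground truth: sensitivity undefined, reported absent
  m2 <- pixel_metrics(list(tp = 0, tn = 90, fp = 10, fn = 0))
  expect_true(is.na(m2["sen"]))
  expect_false(is.na(m2["spe"]))
  expect_error(pixel_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "empty")
})

test_that("pixel Dice matches its formula and is symmetric", {
  a <- matrix(0L, 6, 6); a[1:3, 1:4] <- 1L
  expect_equal(dice_pixel(a, a), 1)
  b <- matrix(0L, 6, 6); b[5:6, 5:6] <- 1L
  expect_equal(dice_pixel(a, b), 0)
  # tp = 2, fp = 2, fn = 2 -> 4/8
  g <- matrix(0L, 4, 4); g[1, 1:4] <- 1L
  p <- matrix(0L, 4, 4); p[1, 3:4] <- 1L; p[2, 1:2] <- 1L
  expect_equal(dice_pixel(p, g), 0.5)
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rbinom(64, 1, 0.4), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(dice_pixel(x, y), dice_pixel(y, x))
  }
  expect_true(is.na(dice_pixel(matrix(0, 3, 3), matrix(0, 3, 3))))
})

test_that("AJI reproduces the hand-computed worked cases", {
  # identical maps
  gt <- matrix(0L, 8, 8); gt[2:3, 2:3] <- 1L
  expect_equal(aji(gt, gt), 1)
  # empty prediction
  expect_equal(aji(gt, matrix(0L, 8, 8)), 0)
  # 4-px square vs 4-px square overlapping 2 px: 2/6
  pd <- matrix(0L, 8, 8); pd[3:4, 2:3] <- 1L
  expect_equal(aji(gt, pd), 2 / 6)
  # perfect match plus a spurious disjoint 3-px prediction: 4/7
  pd2 <- gt; pd2[6, 5:7] <- 2L
  expect_equal(aji(gt, pd2), 4 / 7)
  expect_error(aji(gt, matrix(0L, 4, 4)), "shapes")
})

test_that("AJI equals the first-principles oracle and its bounds hold", {
  for (s in 1:60) {
    gt <- make_instance_map(s)
    pd <- perturb_instance_map(gt, s + 5000)
    a <- aji(gt, pd)
    expect_equal(a, oracle_aji(gt, pd), tolerance = 1e-12)
    if (!is.na(a)) {
      expect_gte(a, 0); expect_lte(a, 1)
      # greedy matching never exceeds the best assignment of the objective
      expect_lte(a, aji_assignment_max(gt, pd) + 1e-12)
    }
    # invariance under relabelling
    perm <- sample(max(1, max(gt)))
    gt2 <- gt; gt2[gt > 0] <- perm[gt[gt > 0]]
    expect_equal(aji(gt2, pd), a)
  }
})

test_that("object matching and precision/recall follow the worked cases", {
  gt <- matrix(0L, 12, 20)
  gt[2:5, 2:5] <- 1L; gt[8:11, 8:11] <- 2L
  pd <- matrix(0L, 12, 20)
  pd[2:5, 2:5] <- 1L          # exact match of gt 1
  pd[8:11, 9:12] <- 2L        # strong overlap with gt 2 (iou 3/5)
  pd[2:4, 15:18] <- 3L        # spurious
  m <- match_objects(gt, pd, iou_threshold = 0.5)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$unmatched_pred, 3)
  expect_length(m$unmatched_gt, 0)
  expect_equal(object_pr(m), c(precision = 2 / 3, recall = 1))
  # identical maps match at IoU 1
  mi <- match_objects(gt, gt, iou_threshold = 1)
  expect_equal(mi$pairs$iou, c(1, 1))
  # overlap below the threshold yields no pairs
  m0 <- match_objects(gt, pd, iou_threshold = 0.99)
  expect_equal(nrow(m0$pairs), 1)
  # no predictions: precision absent, recall 0
  m_empty <- match_objects(gt, matrix(0L, 12, 20))
  pr <- object_pr(m_empty)
  expect_true(is.na(pr["precision"]))
  expect_equal(unname(pr["recall"]), 0)
  # exhaustive pairwise-IoU oracle agreement on random fixtures
  for (s in 1:20) {
    g2 <- make_instance_map(s + 300)
    p2 <- perturb_instance_map(g2, s + 7000)
    mm <- match_objects(g2, p2, iou_threshold = 0.3)
    # one-to-one
    expect_false(anyDuplicated(mm$pairs$gt) > 0)
    expect_false(anyDuplicated(mm$pairs$pred) > 0)
    for (r in seq_len(nrow(mm$pairs))) {
      A <- which(g2 == mm$pairs$gt[r]); B <- which(p2 == mm$pairs$pred[r])
      expect_equal(mm$pairs$iou[r],
                   length(intersect(A, B)) / length(union(A, B)))
      expect_gte(mm$pairs$iou[r], 0.3)
    }
  }
})

test_that("object recall is non-increasing in the IoU threshold", {
  g <- make_instance_map(77); p <- perturb_instance_map(g, 88)
  recalls <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    object_pr(match_objects(g, p, th))["recall"], 0)
  expect_true(all(diff(recalls) <= 1e-12))
})

test_that("ROC/PR curves hit their closed-form limits", {
  set.seed(3)
  g <- matrix(rbinom(400, 1, 0.3), 20, 20)
  perfect <- roc_pr_curves(g * 1, g)
  expect_equal(perfect$auc_roc, 1)
  inverted <- roc_pr_curves(1 - g, g)
  expect_equal(inverted$auc_roc, 0)
  # random scores: AUC ~ 0.5
  set.seed(4)
  lab <- matrix(rbinom(1e4, 1, 0.5), 100, 100)
  sc <- matrix(runif(1e4), 100, 100)
  expect_lt(abs(roc_pr_curves(sc, lab)$auc_roc - 0.5), 0.02)
})

test_that("pooled ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  g <- matrix(rbinom(900, 1, 0.25), 30, 30)
  s <- matrix(runif(900), 30, 30) + g * 0.8
  ours <- roc_pr_curves(s, g)$auc_roc
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(g), as.vector(s),
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("threshold sweep equals independent single-threshold runs", {
  ps <- lapply(1:4, function(s)
    generate_patch(synth_patch_config(patch_size = 64, n_nuclei = c(3L, 6L),
                                      radius = c(4, 8), seed = 30 + s)))
  # degraded predictions: blurred + noisy ground truth silhouettes
  probs <- lapply(seq_along(ps), function(i) {
    set.seed(i)
    pr <- ifelse(ps[[i]]$labels > 0, 0.8, 0.15) +
      matrix(rnorm(64 * 64, 0, 0.1), 64, 64)
    pmin(pmax(pr, 0), 1)
  })
  gts <- lapply(ps, `[[`, "labels")
  th <- seq(0.30, 0.50, by = 0.05)
  sweep <- threshold_sweep(probs, gts, thresholds = th, h = 2,
                           iou_threshold = 0.5)
  expect_equal(nrow(sweep), 5)
  expect_equal(sweep$threshold, th)
  for (k in seq_along(th)) {
    single <- threshold_sweep(probs, gts, thresholds = th[k], h = 2,
                              iou_threshold = 0.5)
    expect_equal(sweep[k, ], single, ignore_attr = TRUE)
  }
  # perfect probability maps on disjoint nuclei: precision = recall = 1 at
  # every threshold
  ps0 <- lapply(1:3, function(s)
    generate_patch(synth_patch_config(patch_size = 64, n_nuclei = c(3L, 6L),
                                      radius = c(4, 8), touching_fraction = 0,
                                      seed = 60 + s)))
  gts <- lapply(ps0, `[[`, "labels")
  perfect <- lapply(gts, function(g) (g > 0) * 1)
  sw2 <- threshold_sweep(perfect, gts, thresholds = c(0.25, 0.5, 0.75), h = 2)
  expect_true(all(sw2$precision == 1))
  expect_true(all(sw2$recall == 1))
  expect_error(threshold_sweep(probs, gts, thresholds = c(0.5, 0.3)),
               "ascending")
})
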