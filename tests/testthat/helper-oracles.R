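# Independent brute-force oracles used to validate the implementation paths.
# These deliberately share no code with the package internals.

# 8-connected component labelling by breadth-first flood fill
oracle_label <- function(mask) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      rc <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- rc[1] + dr; c <- rc[2] + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# exhaustive nearest-background search (outside the image = background)
oracle_distance <- function(b) {
  b <- b > 0
  H <- nrow(b); W <- ncol(b)
  bg <- which(!b, arr.ind = TRUE)
  # add a ring of virtual background just outside the image
  ring <- rbind(cbind(0, 0:(W + 1)), cbind(H + 1, 0:(W + 1)),
                cbind(1:H, 0), cbind(1:H, W + 1))
  bg <- rbind(bg, ring)
  d <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (b[r, c])
      d[r, c] <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
  }
  d
}

# AJI computed from first principles on pixel-index sets, following the
# established convention: per-GT argmax Jaccard over not-yet-used
# predictions (ties -> lower prediction label), GT processed in descending
# best-Jaccard order, never-used predictions added to the denominator.
oracle_aji <- function(gt, pred) {
  gt_ids <- sort(unique(gt[gt > 0]))
  pd_ids <- sort(unique(pred[pred > 0]))
  if (length(gt_ids) == 0 && length(pd_ids) == 0) return(NA_real_)
  if (length(gt_ids) == 0 || length(pd_ids) == 0) return(0)
  gset <- lapply(gt_ids, function(i) which(gt == i))
  pset <- lapply(pd_ids, function(j) which(pred == j))
  jac <- function(A, B) {
    i <- length(intersect(A, B))
    if (i == 0) return(0)
    i / length(union(A, B))
  }
  best <- vapply(gset, function(A)
    max(vapply(pset, jac, 0, A = A)), 0)
  ord <- order(best, decreasing = TRUE)
  used <- logical(length(pd_ids))
  num <- 0; den <- 0
  for (i in ord) {
    js <- vapply(seq_along(pset), function(j)
      if (used[j]) -1 else jac(gset[[i]], pset[[j]]), 0)
    pos <- which(js > 0)
    if (!length(pos)) { den <- den + length(gset[[i]]); next }
    j <- pos[which.max(js[pos])]
    used[j] <- TRUE
    num <- num + length(intersect(gset[[i]], pset[[j]]))
    den <- den + length(union(gset[[i]], pset[[j]]))
  }
  den <- den + sum(lengths(pset)[!used])
  if (den == 0) return(NA_real_)
  num / den
}

# maximum of the AJI objective over ALL injective partial assignments
# (an upper bound on the greedy definition; enumeration feasible for <= 4
# instances per map)
aji_assignment_max <- function(gt, pred) {
  kg <- max(gt); kp <- max(pred)
  if (kg == 0 || kp == 0) return(if (kg == 0 && kp == 0) NA_real_ else 0)
  ga <- tabulate(gt[gt > 0], kg); pa <- tabulate(pred[pred > 0], kp)
  int <- matrix(0, kg, kp)
  both <- gt > 0 & pred > 0
  if (any(both))
    int <- matrix(tabulate((pred[both] - 1) * kg + gt[both], kg * kp), kg, kp)
  best <- -Inf
  rec <- function(i, a) {
    if (i > kg) {
      num <- 0; den <- 0; used <- logical(kp)
      for (g in seq_len(kg)) {
        j <- a[g]
        if (j == 0) den <- den + ga[g]
        else { used[j] <- TRUE; num <- num + int[g, j]
               den <- den + ga[g] + pa[j] - int[g, j] }
      }
      den <- den + sum(pa[!used])
      if (den > 0 && num / den > best) best <<- num / den
      return(invisible())
    }
    rec(i + 1, c(a, 0))
    for (j in seq_len(kp)) if (!(j %in% a) && int[i, j] > 0) rec(i + 1, c(a, j))
  }
  rec(1, integer(0))
  best
}

# hand product-limit estimator (no censoring adjustment needed when all
# observations are events or the censoring pattern is explicit)
oracle_km <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  n <- length(time)
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (k in seq_along(times)) {
    at_risk <- sum(time >= times[k])
    d <- sum(time == times[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = times, surv = surv)
}

# hand observed-minus-expected log-rank statistic (1 df, two groups)
oracle_logrank_chisq <- function(time, event, grp) {
  times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (tk in times) {
    n1 <- sum(time >= tk & grp == 1); n2 <- sum(time >= tk & grp == 2)
    n <- n1 + n2
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & grp == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# linear pixel indices of a disc, for building fixtures by hand
ellipse_px <- function(cr, cc, r, H, W) {
  gr <- matrix(rep(seq_len(H), W), H, W)
  gc <- matrix(rep(seq_len(W), each = H), H, W)
  which((gr - cr)^2 + (gc - cc)^2 <= r^2)
}

# small synthetic training sets shared by the heavier tests
make_train_patches <- function(n, seed0, patch_size = 64L) {
  small <- patch_size < 48L
  lapply(seq_len(n), function(i)
    generate_patch(synth_patch_config(patch_size = patch_size,
                                      n_nuclei = if (small) c(2L, 4L) else c(2L, 6L),
                                      radius = if (small) c(3, 5) else c(4, 8),
                                      seed = seed0 + i)))
}

patch_images <- function(ps) lapply(ps, `[[`, "image")
patch_masks <- function(ps) lapply(ps, function(p) (p$labels > 0) * 1L)

# disjoint-disc instance map + realistic perturbation, for metric fixtures
make_instance_map <- function(seed, H = 28, W = 28, kmax = 4) {
  set.seed(seed)
  k <- sample(seq_len(kmax), 1)
  lab <- matrix(0L, H, W)
  centres <- list()
  gr <- matrix(rep(seq_len(H), W), H, W)
  gc <- matrix(rep(seq_len(W), each = H), H, W)
  for (i in seq_len(k)) {
    for (try in 1:50) {
      r <- sample(2:4, 1)
      cr <- sample((r + 1):(H - r), 1); cc <- sample((r + 1):(W - r), 1)
      ok <- all(vapply(centres, function(z)
        (z[1] - cr)^2 + (z[2] - cc)^2 > (z[3] + r + 1)^2, TRUE))
      if (ok) {
        centres[[length(centres) + 1]] <- c(cr, cc, r)
        lab[(gr - cr)^2 + (gc - cc)^2 <= r^2] <- i
        break
      }
    }
  }
  lab
}

perturb_instance_map <- function(gt, seed) {
  set.seed(seed)
  H <- nrow(gt); W <- ncol(gt)
  dr <- sample(-2:2, 1); dc <- sample(-2:2, 1)
  pd <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr); cs <- max(1, 1 + dc):min(W, W + dc)
  pd[rs, cs] <- gt[rs - dr, cs - dc]
  if (max(pd) >= 2 && stats::runif(1) < 0.3) pd[pd == max(pd)] <- max(pd) - 1L
  if (stats::runif(1) < 0.4) {
    r <- sample(2:3, 1)
    cr <- sample((r + 1):(H - r), 1); cc <- sample((r + 1):(W - r), 1)
    gr <- matrix(rep(seq_len(H), W), H, W)
    gc <- matrix(rep(seq_len(W), each = H), H, W)
    sel <- (gr - cr)^2 + (gc - cc)^2 <= r^2 & pd == 0
    pd[sel] <- max(pd) + 1L
  }
  ids <- sort(unique(pd[pd > 0]))
  out <- matrix(0L, H, W)
  out[pd > 0] <- match(pd[pd > 0], ids)
  out
}
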