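#' Load an image/mask patch folder
#'
#' Reads the folder layout produced by annotation export (and by
#' [write_synth_patches()]): `path/images/<id>.<ext>` paired with
#' `path/masks/<id>.<ext>` by shared basename. Masks may be binary (0/1) or
#' instance label maps; the binary ground truth is always derived as
#' `labels > 0`.
#'
#' @param path folder containing `images/` and `masks/` subfolders.
#' @return a list of patches; each is a list with `image` (H x W x 3, 0-255),
#'   `gt_binary` (integer 0/1 matrix), `gt_instances` (integer label map or
#'   `NULL` when the mask was binary) and `source_id`.
#' @export
load_patch_folder <- function(path) {
  img_dir <- file.path(path, "images")
  msk_dir <- file.path(path, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("expected `images/` and `masks/` subfolders under ", path)
  imgs <- list.files(img_dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  msks <- list.files(msk_dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  img_ids <- tools::file_path_sans_ext(imgs)
  msk_ids <- tools::file_path_sans_ext(msks)
  missing_mask <- setdiff(img_ids, msk_ids)
  if (length(missing_mask))
    stop("missing mask for image(s): ", paste(missing_mask, collapse = ", "))
  orphan <- setdiff(msk_ids, img_ids)
  if (length(orphan))
    warning("mask(s) without image ignored: ", paste(orphan, collapse = ", "))
  out <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    id <- img_ids[i]
    image <- read_image(file.path(img_dir, imgs[i]))
    labels <- read_mask(file.path(msk_dir, msks[match(id, msk_ids)]))
    if (!all(dim(labels) == dim(image)[1:2]))
      stop(sprintf("dimension mismatch for `%s`: image %dx%d vs mask %dx%d",
                   id, dim(image)[1], dim(image)[2],
                   nrow(labels), ncol(labels)))
    is_instance <- length(unique(labels[labels > 0])) > 1L
    out[[i]] <- list(
      image = image,
      gt_binary = instances_to_binary(labels),
      gt_instances = if (is_instance) labels else NULL,
      source_id = id
    )
  }
  out
}

#' Convert an instance label map to a binary mask
#'
#' @param m integer matrix of non-negative instance labels.
#' @return integer 0/1 matrix, 1 exactly where `m > 0`.
#' @examples
#' instances_to_binary(matrix(c(0, 1, 2, 0), 2, 2))
#' @export
instances_to_binary <- function(m) {
  if (any(m < 0)) stop("instance labels must be >= 0")
  as_binary((m > 0) * 1L)
}

#' Split patch ids into train / train-val / test partitions
#'
#' Partition sizes follow largest-remainder rounding of `ratios * N`
#' (remainder ties broken by partition order); membership is randomised by
#' `seed`. When `group` is supplied, whole groups (e.g. patients or TMA
#' cores) are assigned to a single partition to prevent leakage.
#'
#' @param ids character/integer vector of patch identifiers.
#' @param ratios numeric triple `(train, train_val, test)` summing to 1.
#' @param seed integer seed.
#' @param group optional vector, same length as `ids`, of grouping keys.
#' @return a data.frame with columns `id` and `partition`
#'   (`"train"`, `"train_val"`, `"test"`).
#' @examples
#' split_dataset(1:10, c(0.6, 0.1, 0.3), seed = 1)
#' @export
split_dataset <- function(ids, ratios = c(0.6, 0.1, 0.3), seed = 1L,
                          group = NULL) {
  if (length(ratios) != 3L || any(ratios < 0))
    stop("ratios must be three non-negative fractions")
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  if (anyDuplicated(ids)) stop("ids must be unique")
  parts <- c("train", "train_val", "test")
  units <- if (is.null(group)) ids else unique(group)
  n <- length(units)
  base <- floor(ratios * n)
  rem <- ratios * n - base
  left <- n - sum(base)
  if (left > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  assign_units <- rep(parts, times = base)[order(perm)]
  if (is.null(group)) {
    data.frame(id = ids, partition = assign_units, stringsAsFactors = FALSE)
  } else {
    data.frame(id = ids,
               partition = assign_units[match(group, units)],
               stringsAsFactors = FALSE)
  }
}

# --- geometric augmentation -------------------------------------------------

# reflect-101 border handling: coordinates beyond the image are mirrored
# about the edge pixels (keeps warps approximately area-preserving, no
# constant-fill clipping at the patch border)
reflect_coord <- function(v, n) {
  if (n == 1L) return(rep(1, length(v)))
  period <- 2 * (n - 1)
  v <- abs(v - 1) %% period
  ifelse(v > (n - 1), period - v, v) + 1
}

# sample an image plane at (real-valued) source coordinates; out-of-image
# coordinates are mirrored ("reflect") or replaced by `fill`
bilinear_sample <- function(plane, sr, sc, border, fill) {
  H <- nrow(plane); W <- ncol(plane)
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gv <- function(r, c) {
    if (border == "reflect") {
      plane[cbind(round(reflect_coord(r, H)), round(reflect_coord(c, W)))]
    } else {
      ok <- r >= 1 & r <= H & c >= 1 & c <= W
      v <- rep(fill, length(r))
      v[ok] <- plane[cbind(r[ok], c[ok])]
      v
    }
  }
  v00 <- gv(r0, c0); v10 <- gv(r0 + 1, c0)
  v01 <- gv(r0, c0 + 1); v11 <- gv(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

nearest_sample <- function(plane, sr, sc, border, fill = 0) {
  H <- nrow(plane); W <- ncol(plane)
  r <- round(sr); c <- round(sc)
  if (border == "reflect") {
    r <- round(reflect_coord(r, H)); c <- round(reflect_coord(c, W))
    return(matrix(plane[cbind(r, c)], H, W))
  }
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  v <- rep(fill, length(r))
  v[ok] <- plane[cbind(r[ok], c[ok])]
  matrix(v, H, W)
}

# apply a source-coordinate field to image + masks (NN for masks, bilinear
# for the image so label integrity is preserved)
warp_patch <- function(patch, sr, sc, border = "reflect") {
  H <- dim(patch$image)[1]; W <- dim(patch$image)[2]
  img <- patch$image
  for (ch in 1:3)
    img[, , ch] <- matrix(bilinear_sample(patch$image[, , ch], sr, sc, border,
                                          fill = stats::median(patch$image[, , ch])),
                          H, W)
  patch$image <- img
  patch$gt_binary <- as_binary(nearest_sample(patch$gt_binary, sr, sc, border))
  if (!is.null(patch$gt_instances))
    patch$gt_instances <- nearest_sample(patch$gt_instances, sr, sc, border)
  patch
}

# separable smoothing of a matrix with a Gaussian kernel (reflecting edges)
smooth_gauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_filter <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[n + 1 - seq_len(half)]))
    stats::filter(vp, k, sides = 2)[(half + 1):(half + n)]
  }
  m2 <- apply(m, 2, pad_filter)
  t(apply(t(m2), 2, pad_filter))
}

#' Geometric augmentation of a patch
#'
#' Applies the listed operations in order, with the identical geometric
#' transform for the image and its masks. Supported ops: `"hflip"`,
#' `"vflip"`, `"elastic"` (smooth random displacement field) and
#' `"shift_scale_rotate"`. Mask resampling is nearest-neighbour.
#'
#' @param patch a patch as returned by [load_patch_folder()] or a list with
#'   `image`, `gt_binary` and optionally `gt_instances`.
#' @param ops character vector of operation names; unknown names error.
#' @param seed integer seed for the random transform parameters.
#' @param elastic_alpha displacement amplitude in pixels (0 = identity).
#' @param elastic_sigma smoothing bandwidth of the displacement field (px).
#' @param shift_limit,scale_limit,rotate_limit maximum |shift| fraction,
#'   |log-scale| fraction and |rotation| in degrees for
#'   `"shift_scale_rotate"`.
#' @return the augmented patch (same structure as the input).
#' @export
augment_patch <- function(patch, ops, seed = 1L,
                          elastic_alpha = 2, elastic_sigma = 20,
                          shift_limit = 0.1, scale_limit = 0.1,
                          rotate_limit = 30) {
  known <- c("hflip", "vflip", "elastic", "shift_scale_rotate")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
  H <- dim(patch$image)[1]; W <- dim(patch$image)[2]
  with_seed(seed, {
    for (op in ops) {
      if (op == "hflip") {
        patch$image <- patch$image[, W:1, , drop = FALSE]
        patch$gt_binary <- patch$gt_binary[, W:1, drop = FALSE]
        if (!is.null(patch$gt_instances))
          patch$gt_instances <- patch$gt_instances[, W:1, drop = FALSE]
      } else if (op == "vflip") {
        patch$image <- patch$image[H:1, , , drop = FALSE]
        patch$gt_binary <- patch$gt_binary[H:1, , drop = FALSE]
        if (!is.null(patch$gt_instances))
          patch$gt_instances <- patch$gt_instances[H:1, , drop = FALSE]
      } else if (op == "elastic") {
        gr <- matrix(rep(seq_len(H), W), H, W)
        gc <- matrix(rep(seq_len(W), each = H), H, W)
        if (elastic_alpha > 0) {
          # incompressible deformation: displacement = curl of a smooth
          # random potential, so the field is divergence-free and the warp
          # is locally area-preserving (foreground counts conserved up to
          # resampling error)
          psi <- smooth_gauss(matrix(stats::rnorm(H * W), H, W),
                              elastic_sigma)
          dr <- (psi[, c(2:W, W)] - psi[, c(1, 1:(W - 1))]) / 2
          dc <- -(psi[c(2:H, H), ] - psi[c(1, 1:(H - 1)), ]) / 2
          amp <- max(sqrt(dr^2 + dc^2), 1e-12)
          dr <- dr / amp * elastic_alpha
          dc <- dc / amp * elastic_alpha
          patch <- warp_patch(patch, as.vector(gr + dr), as.vector(gc + dc),
                              border = "reflect")
        }
      } else if (op == "shift_scale_rotate") {
        sh_r <- stats::runif(1, -shift_limit, shift_limit) * H
        sh_c <- stats::runif(1, -shift_limit, shift_limit) * W
        sc <- exp(stats::runif(1, -scale_limit, scale_limit))
        th <- stats::runif(1, -rotate_limit, rotate_limit) * pi / 180
        cr <- (H + 1) / 2; ccn <- (W + 1) / 2
        gr <- matrix(rep(seq_len(H), W), H, W) - cr - sh_r
        gc <- matrix(rep(seq_len(W), each = H), H, W) - ccn - sh_c
        # inverse mapping: rotate by -th, scale by 1/sc
        sr <- (cos(th) * gr + sin(th) * gc) / sc + cr
        scc <- (-sin(th) * gr + cos(th) * gc) / sc + ccn
        patch <- warp_patch(patch, as.vector(sr), as.vector(scc), border = "fill")
      }
    }
    patch
  })
}
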