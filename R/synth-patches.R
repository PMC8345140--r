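#' Configuration for synthetic IHC patch generation
#'
#' Describes the simulated imaging conditions: DAB-brown elliptical nuclei on
#' a light hematoxylin/eosin-like background, with a controllable fraction of
#' touching (overlapping) nucleus pairs, multiplicative per-nucleus stain
#' intensity jitter, low-frequency background texture and additive Gaussian
#' pixel noise.
#'
#' @param patch_size side length of the square patch in pixels.
#' @param n_nuclei integer count or range `c(min, max)` of nuclei per patch.
#' @param radius range `c(min, max)` of the major ellipse semi-axis in pixels
#'   (minor semi-axis is 0.6-1 times the major, never below 2 px).
#' @param touching_fraction proportion in `[0, 1]` of nuclei placed as
#'   overlapping pairs.
#' @param stain_foreground RGB triple (0-255) of the DAB-brown nucleus stain.
#' @param stain_background RGB triple (0-255) of the background tissue tint.
#' @param stain_jitter standard deviation of the per-nucleus log-normal
#'   intensity factor (0 disables jitter).
#' @param noise_sd standard deviation of the additive Gaussian pixel noise
#'   (0-255 scale; 0 disables noise).
#' @param seed integer seed; all randomness of [generate_patch()] flows from
#'   it and global RNG state is left untouched.
#' @return an object of class `"synth_patch_config"`.
#' @seealso [generate_patch()], [generate_touching_pair()]
#' @export
synth_patch_config <- function(patch_size = 256L,
                               n_nuclei = c(4L, 12L),
                               radius = c(6, 14),
                               touching_fraction = 0.3,
                               stain_foreground = c(115, 70, 40),
                               stain_background = c(228, 220, 228),
                               stain_jitter = 0.08,
                               noise_sd = 8,
                               seed = 1L) {
  if (patch_size <= 0) stop("patch_size must be > 0")
  stop_if_not_scalar_prob(touching_fraction, "touching_fraction")
  if (length(radius) == 1L) radius <- c(radius, radius)
  if (any(radius < 2)) stop("radii must be >= 2 px")
  if (radius[1] > radius[2]) stop("radius range must be increasing")
  if (length(n_nuclei) == 1L) n_nuclei <- c(n_nuclei, n_nuclei)
  if (any(n_nuclei < 0)) stop("n_nuclei must be >= 0")
  if (length(stain_foreground) != 3L || length(stain_background) != 3L)
    stop("stain colours must be RGB triples")
  if (noise_sd < 0 || stain_jitter < 0) stop("noise/jitter scales must be >= 0")
  structure(list(
    patch_size = as.integer(patch_size), n_nuclei = as.integer(n_nuclei),
    radius = radius, touching_fraction = touching_fraction,
    stain_foreground = stain_foreground, stain_background = stain_background,
    stain_jitter = stain_jitter, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synth_patch_config")
}

# rasterize a filled ellipse; returns linear pixel indices within H x W
ellipse_pixels <- function(H, W, cr, cc, a, b, theta) {
  rmax <- ceiling(max(a, b))
  r0 <- max(1L, floor(cr - rmax)); r1 <- min(H, ceiling(cr + rmax))
  c0 <- max(1L, floor(cc - rmax)); c1 <- min(W, ceiling(cc + rmax))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc2 <- c0:c1
  dr <- matrix(rr - cr, length(rr), length(cc2))
  dc <- matrix(rep(cc2 - cc, each = length(rr)), length(rr), length(cc2))
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  inside <- (u * u + v * v) <= 1
  ri <- row(inside)[inside] + r0 - 1L
  ci <- col(inside)[inside] + c0 - 1L
  (ci - 1L) * H + ri
}

# render clean image + noise given a label map and per-nucleus jitter factors
render_patch_image <- function(labels, config, jitter) {
  H <- nrow(labels); W <- ncol(labels)
  img <- array(0, c(H, W, 3))
  # low-frequency background texture: sum of 3 random plane waves
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  tex <- matrix(0, H, W)
  for (j in 1:3) {
    fr <- stats::runif(1, 0.002, 0.02); fc <- stats::runif(1, 0.002, 0.02)
    ph <- stats::runif(1, 0, 2 * pi); amp <- stats::runif(1, 2, 6)
    tex <- tex + amp * cos(2 * pi * (fr * rr + fc * cc) + ph)
  }
  for (ch in 1:3) img[, , ch] <- config$stain_background[ch] + tex
  fg <- labels > 0
  if (any(fg)) {
    fac <- jitter[labels[fg]]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[fg] <- config$stain_foreground[ch] * fac
      img[, , ch] <- plane
    }
  }
  if (config$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, config$noise_sd), dim(img))
  round(clip(img, 0, 255))
}

#' Generate a synthetic IHC-like patch with instance ground truth
#'
#' Nuclei are filled ellipses with random orientation and eccentricity. A
#' fraction of them (per `touching_fraction`) is placed as overlapping pairs;
#' within a pair the later label wins pixel ownership, so the rendered
#' silhouettes touch while the ground truth remains two instances. Before
#' noise, every labelled pixel carries the foreground stain colour (scaled by
#' the per-nucleus jitter factor).
#'
#' @param config a [synth_patch_config()].
#' @return a list with elements `image` (H x W x 3 array, 0-255) and
#'   `labels` (integer instance label map of the same spatial size, one
#'   positive label per generated nucleus).
#' @examples
#' p <- generate_patch(synth_patch_config(patch_size = 96, seed = 7))
#' max(p$labels)            # number of nuclei
#' dim(p$image)
#' @export
generate_patch <- function(config = synth_patch_config()) {
  stopifnot(inherits(config, "synth_patch_config"))
  with_seed(config$seed, {
    H <- W <- config$patch_size
    n <- if (config$n_nuclei[1] == config$n_nuclei[2]) config$n_nuclei[1] else
      sample(config$n_nuclei[1]:config$n_nuclei[2], 1L)
    labels <- matrix(0L, H, W)
    if (n == 0L) {
      img <- render_patch_image(labels, config, numeric(0))
      return(list(image = img, labels = labels))
    }
    n_pairs <- floor(config$touching_fraction * n / 2)
    placed <- list()  # each: c(cr, cc, rmax)
    margin <- config$radius[2] + 1
    draw_axes <- function() {
      a <- stats::runif(1, config$radius[1], config$radius[2])
      b <- max(2, a * stats::runif(1, 0.6, 1))
      c(a, b)
    }
    clear_of <- function(cr, cc, rmax, skip = integer(0)) {
      for (i in seq_along(placed)) {
        if (i %in% skip) next
        p <- placed[[i]]
        if ((cr - p[1])^2 + (cc - p[2])^2 < (rmax + p[3] + 1)^2) return(FALSE)
      }
      TRUE
    }
    nuclei <- list()  # each: list(cr, cc, a, b, theta)
    add_nucleus <- function(cr, cc, ax, theta = stats::runif(1, 0, pi)) {
      nuclei[[length(nuclei) + 1L]] <<- list(cr = cr, cc = cc, a = ax[1],
                                             b = ax[2], theta = theta)
      placed[[length(placed) + 1L]] <<- c(cr, cc, max(ax))
    }
    place_single <- function() {
      for (try in 1:500) {
        ax <- draw_axes()
        cr <- stats::runif(1, margin, H - margin)
        cc <- stats::runif(1, margin, W - margin)
        if (clear_of(cr, cc, max(ax))) { add_nucleus(cr, cc, ax); return(TRUE) }
      }
      FALSE
    }
    # radius of an (a, b) ellipse along direction `phi` relative to its own
    # orientation; used to guarantee pair members really overlap
    eff_radius <- function(ax, phi) {
      ax[1] * ax[2] / sqrt((ax[2] * cos(phi))^2 + (ax[1] * sin(phi))^2)
    }
    place_pair <- function() {
      for (try in 1:500) {
        ax1 <- draw_axes(); ax2 <- draw_axes()
        th1 <- stats::runif(1, 0, pi); th2 <- stats::runif(1, 0, pi)
        cr <- stats::runif(1, margin + max(ax2), H - margin - max(ax2))
        cc <- stats::runif(1, margin + max(ax2), W - margin - max(ax2))
        if (!clear_of(cr, cc, max(ax1) + 2 * max(ax2))) next
        ang <- stats::runif(1, 0, 2 * pi)
        re1 <- eff_radius(ax1, ang - th1)
        re2 <- eff_radius(ax2, ang - th2)
        # centre distance: overlapping (< re1 + re2) but neither nucleus
        # swallowed by the other (a couple of pixels always stick out)
        d_lo <- max(0.55 * (re1 + re2), abs(re2 - re1) + 2)
        d_hi <- 0.85 * (re1 + re2)
        if (d_lo >= d_hi) next
        d <- stats::runif(1, d_lo, d_hi)
        cr2 <- cr + d * cos(ang); cc2 <- cc + d * sin(ang)
        add_nucleus(cr, cc, ax1, th1); add_nucleus(cr2, cc2, ax2, th2)
        return(TRUE)
      }
      FALSE
    }
    for (k in seq_len(n_pairs))
      if (!place_pair()) stop("could not place nuclei: patch too crowded")
    for (k in seq_len(n - 2L * n_pairs))
      if (!place_single()) stop("could not place nuclei: patch too crowded")
    for (k in seq_along(nuclei)) {
      nu <- nuclei[[k]]
      px <- ellipse_pixels(H, W, nu$cr, nu$cc, nu$a, nu$b, nu$theta)
      labels[px] <- k  # later label wins overlap
    }
    jitter <- if (config$stain_jitter > 0)
      exp(stats::rnorm(n, 0, config$stain_jitter)) else rep(1, n)
    img <- render_patch_image(labels, config, jitter)
    list(image = img, labels = labels)
  })
}

#' Generate a touching pair of disc-shaped nuclei
#'
#' A stress fixture for watershed-based instance separation: two discs of
#' equal radius whose centres are closer than one diameter, so the union
#' silhouette is a single connected blob while the ground truth holds two
#' instances (the second label wins the overlap).
#'
#' @param radius disc radius in pixels (>= 2).
#' @param centre_distance distance between disc centres in pixels; must lie
#'   strictly between 0 and `2 * radius`, otherwise an error is raised.
#' @param seed integer seed (controls rendering noise/jitter only).
#' @param noise_sd additive pixel-noise standard deviation for the rendered
#'   image.
#' @return a list with `image` and `labels` as in [generate_patch()], with
#'   exactly two instances.
#' @examples
#' tp <- generate_touching_pair(10, 14)
#' max(tp$labels)  # 2
#' @export
generate_touching_pair <- function(radius, centre_distance, seed = 1L,
                                   noise_sd = 0) {
  if (radius < 2) stop("radius must be >= 2 px")
  if (centre_distance <= 0) stop("centre_distance must be > 0")
  if (centre_distance >= 2 * radius)
    stop("centre_distance >= 2*radius: discs do not touch")
  pad <- 6
  H <- as.integer(ceiling(2 * radius + 2 * pad))
  W <- as.integer(ceiling(2 * radius + centre_distance + 2 * pad))
  cr <- pad + radius
  cc1 <- pad + radius
  cc2 <- cc1 + centre_distance
  labels <- matrix(0L, H, W)
  labels[ellipse_pixels(H, W, cr, cc1, radius, radius, 0)] <- 1L
  labels[ellipse_pixels(H, W, cr, cc2, radius, radius, 0)] <- 2L
  cfg <- synth_patch_config(patch_size = max(H, W), noise_sd = noise_sd,
                            stain_jitter = 0, seed = seed)
  img <- with_seed(seed, render_patch_image(labels, cfg, rep(1, 2)))
  list(image = img, labels = labels)
}

#' Write a set of synthetic patches to an image/mask folder
#'
#' Produces the on-disk layout consumed by [load_patch_folder()]:
#' `dir/images/<id>.png` and `dir/masks/<id>.png` (16-bit label maps).
#'
#' @param n number of patches.
#' @param dir output directory (created if needed).
#' @param config base [synth_patch_config()]; patch `i` uses `seed + i`.
#' @param seed integer base seed.
#' @return character vector of patch ids, invisibly.
#' @export
write_synth_patches <- function(n, dir, config = synth_patch_config(),
                                seed = 1L) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("patch%04d", seq_len(n))
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    p <- generate_patch(cfg)
    write_image(p$image, file.path(dir, "images", paste0(ids[i], ".png")))
    write_mask(p$labels, file.path(dir, "masks", paste0(ids[i], ".tif")))
  }
  invisible(ids)
}
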