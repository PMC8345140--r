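#' U-Net architecture configuration
#'
#' The default configuration reproduces the classic encoder-decoder U-Net:
#' `depth` contraction blocks of two 3x3 convolutions + ReLU each, 2x2
#' max-pooling between blocks, a two-convolution bottleneck, `depth`
#' expansion blocks of a 2x2 up-convolution, skip concatenation and two 3x3
#' convolutions, and a final 1x1 projection to the foreground logit.
#' Contraction block `k` (0-based) carries `base_channels * 2^k` channels.
#' With the defaults (`depth = 4`, `base_channels = 64`) the layer walk
#' counts 23 convolutional layers (8 + 2 bottleneck + 4 up-convolutions +
#' 8 + 1 final).
#'
#' @param input_size integer triple `(H, W, 3)`; spatial dims must be
#'   divisible by `2^depth`.
#' @param depth number of contraction blocks (>= 1).
#' @param base_channels channels of the first block.
#' @param encoder backbone name; `"paper-unet"` (the from-scratch encoder
#'   above) is the only backbone shipped, the argument is the plug-in point
#'   for alternative encoders.
#' @param n_classes number of segmentation classes; the binary problem
#'   (background vs positive cell) is emitted as a single sigmoid logit.
#' @return an object of class `"unet_config"`.
#' @export
unet_config <- function(input_size = c(256L, 256L, 3L), depth = 4L,
                        base_channels = 64L, encoder = "paper-unet",
                        n_classes = 2L) {
  if (depth < 1) stop("depth must be >= 1")
  if (length(input_size) != 3L || input_size[3] != 3L)
    stop("input_size must be (H, W, 3)")
  if (any(input_size[1:2] %% 2L^depth != 0L))
    stop("input spatial dims must be divisible by 2^depth")
  if (!identical(encoder, "paper-unet"))
    stop("unknown encoder backbone: ", encoder)
  if (n_classes != 2L) stop("only the binary (2-class) problem is supported")
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels), encoder = encoder,
                 n_classes = 2L), class = "unet_config")
}

he_init <- function(nin, nout, fan) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fan)), nin, nout)

init_unet_params <- function(config, seed = 1L) {
  D <- config$depth; B <- config$base_channels
  with_seed(seed, {
    chan <- B * 2L^(0:(D - 1L))           # channels per contraction block
    enc <- vector("list", D)
    cin <- 3L
    for (k in seq_len(D)) {
      C <- chan[k]
      enc[[k]] <- list(
        c1 = list(W = he_init(9L * cin, C, 9L * cin), b = numeric(C)),
        c2 = list(W = he_init(9L * C, C, 9L * C), b = numeric(C))
      )
      cin <- C
    }
    CB <- B * 2L^D
    bott <- list(
      c1 = list(W = he_init(9L * cin, CB, 9L * cin), b = numeric(CB)),
      c2 = list(W = he_init(9L * CB, CB, 9L * CB), b = numeric(CB))
    )
    up <- vector("list", D)
    dec <- vector("list", D)
    for (k in D:1) {
      C <- chan[k]
      cup <- if (k == D) CB else chan[k + 1L]
      up[[k]] <- list(W = lapply(1:4, function(m) he_init(cup, C, cup)),
                      b = numeric(C))
      dec[[k]] <- list(
        c1 = list(W = he_init(9L * 2L * C, C, 9L * 2L * C), b = numeric(C)),
        c2 = list(W = he_init(9L * C, C, 9L * C), b = numeric(C))
      )
    }
    final <- list(W = he_init(B, 1L, B), b = 0)
    list(enc = enc, bott = bott, up = up, dec = dec, final = final)
  })
}

#' Build an (untrained) U-Net model
#'
#' @param config a [unet_config()].
#' @param seed seed for the He-normal weight initialisation.
#' @return an object of class `"unet"` (parameters, config, empty history).
#' @seealso [unet_train()], [predict.unet()], [count_conv_layers()]
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  structure(list(params = init_unet_params(config, seed), config = config,
                 loss = loss_spec("bce"), history = NULL),
            class = "unet")
}

#' Count convolutional layers by a layer walk
#'
#' Walks the parameter tree and counts every convolutional layer: 3x3
#' convolutions in contraction/bottleneck/expansion blocks, 2x2
#' up-convolutions and the final 1x1 projection. The default configuration
#' yields 23.
#'
#' @param model a `"unet"` object or a [unet_config()].
#' @return integer layer count.
#' @examples
#' count_conv_layers(unet_config())  # 23
#' @export
count_conv_layers <- function(model) {
  if (inherits(model, "unet_config")) model <- build_unet(model, seed = 0L)
  stopifnot(inherits(model, "unet"))
  p <- model$params
  n <- 0L
  walk <- function(x, nm) {
    if (is.list(x)) {
      if (!is.null(x$W)) n <<- n + 1L else for (el in x) walk(el, nm)
    }
  }
  walk(p$enc, "enc"); walk(p$bott, "bott"); walk(p$up, "up")
  walk(p$dec, "dec"); walk(p$final, "final")
  n
}

# channels emitted by each contraction block (for introspection/tests)
encoder_channels <- function(model) {
  p <- if (inherits(model, "unet")) model$params else model
  vapply(p$enc, function(bl) ncol(bl$c2$W), integer(1))
}

# forward pass; x is an H x W x 3 array scaled to [0, 1].
# With cache = TRUE all intermediates needed by unet_backward are kept.
unet_forward <- function(params, x, cache = FALSE) {
  D <- length(params$enc)
  H <- dim(x)[1]; W <- dim(x)[2]
  X <- matrix(x, H * W, 3L)
  hs <- H; ws <- W
  skips <- vector("list", D)
  cc <- if (cache) list(enc = vector("list", D), dec = vector("list", D)) else NULL
  for (k in seq_len(D)) {
    idx <- conv_idx(hs, ws)
    A0 <- X
    Z1 <- conv_fwd(A0, params$enc[[k]]$c1$W, params$enc[[k]]$c1$b, idx)
    A1 <- relu(Z1)
    Z2 <- conv_fwd(A1, params$enc[[k]]$c2$W, params$enc[[k]]$c2$b, idx)
    A2 <- relu(Z2)
    skips[[k]] <- A2
    pidx <- pool_idx(hs, ws)
    P <- pool_fwd(A2, pidx)
    if (cache) cc$enc[[k]] <- list(A0 = A0, A1 = A1, A2 = A2, P = P,
                                   hs = hs, ws = ws)
    X <- P; hs <- hs %/% 2L; ws <- ws %/% 2L
  }
  idx <- conv_idx(hs, ws)
  B0 <- X
  B1 <- relu(conv_fwd(B0, params$bott$c1$W, params$bott$c1$b, idx))
  B2 <- relu(conv_fwd(B1, params$bott$c2$W, params$bott$c2$b, idx))
  if (cache) cc$bott <- list(B0 = B0, B1 = B1, B2 = B2, hs = hs, ws = ws)
  X <- B2
  for (k in D:1) {
    oidx <- pool_idx(2L * hs, 2L * ws)
    U <- upconv_fwd(X, params$up[[k]]$W, params$up[[k]]$b, oidx)
    hs <- 2L * hs; ws <- 2L * ws
    idx <- conv_idx(hs, ws)
    Cc <- cbind(skips[[k]], U)
    Z1 <- conv_fwd(Cc, params$dec[[k]]$c1$W, params$dec[[k]]$c1$b, idx)
    A1 <- relu(Z1)
    Z2 <- conv_fwd(A1, params$dec[[k]]$c2$W, params$dec[[k]]$c2$b, idx)
    A2 <- relu(Z2)
    if (cache) cc$dec[[k]] <- list(Xin = X, U = U, Cc = Cc, A1 = A1, A2 = A2,
                                   hs = hs, ws = ws)
    X <- A2
  }
  logits <- as.vector(X %*% params$final$W) + params$final$b
  if (cache) {
    cc$top <- X
    list(logits = logits, cache = cc)
  } else {
    logits
  }
}

# backward pass: gradient of the scalar loss wrt every parameter, given
# dlogits (vector over pixels at full resolution)
unet_backward <- function(params, cache, dlogits) {
  D <- length(params$enc)
  g <- list(enc = vector("list", D), bott = NULL, up = vector("list", D),
            dec = vector("list", D), final = NULL)
  top <- cache$top
  dL <- matrix(dlogits, ncol = 1L)
  g$final <- list(W = crossprod(top, dL), b = sum(dlogits))
  dX <- dL %*% t(params$final$W)
  for (k in 1:D) {
    cd <- cache$dec[[k]]
    idx <- conv_idx(cd$hs, cd$ws)
    dZ2 <- dX * (cd$A2 > 0)
    b2 <- conv_bwd(dZ2, cd$A1, params$dec[[k]]$c2$W, idx)
    dZ1 <- b2$dX * (cd$A1 > 0)
    b1 <- conv_bwd(dZ1, cd$Cc, params$dec[[k]]$c1$W, idx)
    g$dec[[k]] <- list(c1 = list(W = b1$dW, b = b1$db),
                       c2 = list(W = b2$dW, b = b2$db))
    Cskip <- ncol(cache$enc[[k]]$A2)
    dSkip <- b1$dX[, seq_len(Cskip), drop = FALSE]
    dU <- b1$dX[, -seq_len(Cskip), drop = FALSE]
    oidx <- pool_idx(cd$hs, cd$ws)
    bu <- upconv_bwd(dU, cd$Xin, params$up[[k]]$W, oidx)
    g$up[[k]] <- list(W = bu$dW, b = bu$db)
    # store for the encoder sweep
    cache$dec[[k]]$dSkip <- dSkip
    cache$dec[[k]]$dOut <- bu$dX
    dX <- bu$dX  # flows to the layer below (k-1 handled in this loop order)
  }
  # dX now is the gradient wrt the bottleneck output B2
  cb <- cache$bott
  idx <- conv_idx(cb$hs, cb$ws)
  dZ2 <- dX * (cb$B2 > 0)
  b2 <- conv_bwd(dZ2, cb$B1, params$bott$c2$W, idx)
  dZ1 <- b2$dX * (cb$B1 > 0)
  b1 <- conv_bwd(dZ1, cb$B0, params$bott$c1$W, idx)
  g$bott <- list(c1 = list(W = b1$dW, b = b1$db),
                 c2 = list(W = b2$dW, b = b2$db))
  dP <- b1$dX
  for (k in D:1) {
    ce <- cache$enc[[k]]
    pidx <- pool_idx(ce$hs, ce$ws)
    dA2 <- pool_bwd(dP, ce$A2, ce$P, pidx) + cache$dec[[k]]$dSkip
    idx <- conv_idx(ce$hs, ce$ws)
    dZ2 <- dA2 * (ce$A2 > 0)
    b2 <- conv_bwd(dZ2, ce$A1, params$enc[[k]]$c2$W, idx)
    dZ1 <- b2$dX * (ce$A1 > 0)
    b1 <- conv_bwd(dZ1, ce$A0, params$enc[[k]]$c1$W, idx)
    g$enc[[k]] <- list(c1 = list(W = b1$dW, b = b1$db),
                       c2 = list(W = b2$dW, b = b2$db))
    dP <- b1$dX
  }
  g
}

#' Predict a foreground probability map
#'
#' Runs the network in inference mode on one RGB patch. Input values may be
#' 0-255 (rescaled internally) or already in `[0, 1]`.
#'
#' @param object a `"unet"` model.
#' @param image numeric array `H x W x 3` with `H`, `W` divisible by
#'   `2^depth`.
#' @param ... unused.
#' @return numeric matrix `H x W` of probabilities in `[0, 1]`.
#' @export
predict.unet <- function(object, image, ...) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be an H x W x 3 array")
  D <- object$config$depth
  if (any(d[1:2] %% 2L^D != 0L))
    stop("image dims must be divisible by 2^depth = ", 2L^D)
  if (max(image) > 1.5) image <- image / 255
  z <- unet_forward(object$params, image)
  matrix(stats::plogis(z), d[1], d[2])
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat("U-Net semantic segmentation model\n")
  cat(sprintf("  encoder: %s, depth %d, base channels %d\n",
              cfg$encoder, cfg$depth, cfg$base_channels))
  cat(sprintf("  convolutional layers: %d\n", count_conv_layers(x)))
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("  parameters: %s\n", format(np, big.mark = ",")))
  if (!is.null(x$history)) {
    best <- which.max(x$history$val_dice)
    cat(sprintf("  trained %d epochs; best val Dice %.4f (epoch %d)\n",
                nrow(x$history), x$history$val_dice[best], best))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
summary.unet <- function(object, ...) {
  print(object)
  cat(sprintf("  encoder block channels: %s\n",
              paste(encoder_channels(object), collapse = ", ")))
  if (!is.null(object$history)) {
    cat("  training history (last rows):\n")
    print(utils::tail(object$history, 5))
  }
  invisible(object)
}

#' Plot the training history of a U-Net
#'
#' @param x a trained `"unet"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.unet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", col = "firebrick",
                 xlab = "epoch", ylab = "training loss", ...)
  if (any(is.finite(h$val_dice))) {
    graphics::par(new = TRUE)
    graphics::plot(h$epoch, h$val_dice, type = "l", col = "steelblue",
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4)
    graphics::mtext("validation Dice", side = 4, line = 2, col = "steelblue")
  }
  invisible(x)
}
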