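# Internal CNN primitives.
#
# Feature maps live as N x C matrices with N = H*W pixels in R's
# column-major order; convolutions are realised as im2col + BLAS matrix
# products. Index tables for the 3x3 neighbourhood, 2x2 pooling and 2x2
# up-convolution are cached per spatial resolution.

.nn_cache <- new.env(parent = emptyenv())

# 3x3 neighbourhood index table (zero padding -> NA)
conv_idx <- function(H, W) {
  key <- paste0("c", H, "x", W)
  got <- .nn_cache[[key]]
  if (!is.null(got)) return(got)
  n <- H * W
  rr <- rep.int(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  idx <- matrix(NA_integer_, n, 9)
  for (k in 1:9) {
    r2 <- rr + offs$dr[k]; c2 <- cc + offs$dc[k]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    v <- rep(NA_integer_, n)
    v[ok] <- (c2[ok] - 1L) * H + r2[ok]
    idx[, k] <- v
  }
  .nn_cache[[key]] <- idx
  idx
}

# child indices of the 2x2 blocks of an H x W grid (H, W even)
pool_idx <- function(H, W) {
  key <- paste0("p", H, "x", W)
  got <- .nn_cache[[key]]
  if (!is.null(got)) return(got)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  ro <- rep.int(seq_len(H2), W2)
  co <- rep(seq_len(W2), each = H2)
  lin <- function(r, c) (c - 1L) * H + r
  out <- list(lin(2L * ro - 1L, 2L * co - 1L),
              lin(2L * ro,      2L * co - 1L),
              lin(2L * ro - 1L, 2L * co),
              lin(2L * ro,      2L * co))
  .nn_cache[[key]] <- out
  out
}

im2col <- function(X, idx) {
  n <- nrow(idx); C <- ncol(X)
  cols <- matrix(0, n, 9L * C)
  for (k in 1:9) {
    ok <- which(!is.na(idx[, k]))
    cols[ok, ((k - 1L) * C + 1L):(k * C)] <- X[idx[ok, k], , drop = FALSE]
  }
  cols
}

# 3x3 same-padding convolution; weight W is (9*Cin) x Cout, bias length Cout
conv_fwd <- function(X, Wt, b, idx) {
  Y <- im2col(X, idx) %*% Wt
  Y + rep(b, each = nrow(Y))
}

conv_bwd <- function(dY, X, Wt, idx) {
  cols <- im2col(X, idx)
  Cin <- ncol(X)
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(Wt)
  dX <- matrix(0, nrow(X), Cin)
  for (k in 1:9) {
    ok <- which(!is.na(idx[, k]))
    tgt <- idx[ok, k]
    dX[tgt, ] <- dX[tgt, , drop = FALSE] +
      dcols[ok, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

relu <- function(X) X * (X > 0)

# 2x2 max pooling; returns pooled map, keeps inputs for the backward pass
pool_fwd <- function(X, pidx) {
  Y <- pmax(X[pidx[[1]], , drop = FALSE], X[pidx[[2]], , drop = FALSE],
            X[pidx[[3]], , drop = FALSE], X[pidx[[4]], , drop = FALSE])
  Y
}

pool_bwd <- function(dY, X, Y, pidx) {
  dX <- matrix(0, nrow(X), ncol(X))
  assigned <- matrix(FALSE, nrow(Y), ncol(Y))
  for (m in 1:4) {
    child <- X[pidx[[m]], , drop = FALSE]
    sel <- (child == Y) & !assigned   # first of equal maxima wins
    assigned <- assigned | sel
    dX[pidx[[m]], ] <- dX[pidx[[m]], , drop = FALSE] + dY * sel
  }
  dX
}

# 2x2 stride-2 up-convolution: input N x Cin at H x W -> output 4N x Cout at
# 2H x 2W. Weights: list of 4 Cin x Cout matrices (one per sub-position).
upconv_fwd <- function(X, Wl, b, oidx) {
  Cout <- ncol(Wl[[1]])
  Y <- matrix(0, 4L * nrow(X), Cout)
  for (m in 1:4) Y[oidx[[m]], ] <- X %*% Wl[[m]]
  Y + rep(b, each = nrow(Y))
}

upconv_bwd <- function(dY, X, Wl, oidx) {
  dX <- matrix(0, nrow(X), ncol(X))
  dW <- vector("list", 4L)
  for (m in 1:4) {
    dYm <- dY[oidx[[m]], , drop = FALSE]
    dW[[m]] <- crossprod(X, dYm)
    dX <- dX + dYm %*% t(Wl[[m]])
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

# ---- optimizers over nested parameter lists --------------------------------

# recursively apply a leaf update; state mirrors the parameter structure
opt_walk <- function(p, g, s, leaf) {
  if (is.list(p)) {
    if (is.null(s)) s <- vector("list", length(p))
    for (i in seq_along(p)) {
      res <- opt_walk(p[[i]], g[[i]], s[[i]], leaf)
      p[[i]] <- res$p; s[[i]] <- res$s
    }
    return(list(p = p, s = s))
  }
  leaf(p, g, s)
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  leaf <- function(p, g, s) {
    g <- g + weight_decay * p
    if (is.null(s)) s <- list(m = p * 0, v = p * 0)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  opt_walk(params, grads, state, leaf)
}

sgd_nesterov_step <- function(params, grads, state, lr, momentum = 0.9,
                              weight_decay = 0) {
  leaf <- function(p, g, s) {
    g <- g + weight_decay * p
    if (is.null(s)) s <- list(v = p * 0)
    s$v <- momentum * s$v - lr * g
    list(p = p + momentum * s$v - lr * g, s = s)  # Nesterov look-ahead form
  }
  opt_walk(params, grads, state, leaf)
}

# elementwise a + b over nested lists (gradient accumulation)
nest_add <- function(a, b) {
  if (is.list(a)) return(mapply(nest_add, a, b, SIMPLIFY = FALSE))
  a + b
}

nest_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, nest_scale, s = s))
  a * s
}
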