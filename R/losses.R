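#' Segmentation loss specification
#'
#' Names the loss components and their weights. Combination losses (e.g.
#' BCE + IoU) are unweighted sums by default. Components:
#' \describe{
#'   \item{`bce`}{binary cross-entropy, averaged over pixels.}
#'   \item{`dice`}{soft Dice loss, `1 - 2 sum(p y)/(sum(p) + sum(y))`.}
#'   \item{`iou`}{soft IoU (Jaccard) loss, `1 - sum(p y)/(sum(p) + sum(y) - sum(p y))`.}
#'   \item{`focal`}{focal loss with `gamma = 2`, `alpha = 0.25`.}
#'   \item{`lovasz`}{Lovasz hinge on the foreground logit.}
#' }
#'
#' @param components character vector, subset of
#'   `c("bce", "dice", "iou", "focal", "lovasz")`.
#' @param weights positive weights, recycled to the number of components
#'   (default all 1).
#' @return an object of class `"loss_spec"`.
#' @export
loss_spec <- function(components = "bce", weights = 1) {
  components <- tolower(components)
  known <- c("bce", "dice", "iou", "focal", "lovasz")
  bad <- setdiff(components, known)
  if (length(bad)) stop("unknown loss component(s): ", paste(bad, collapse = ", "))
  if (length(components) == 0L) stop("loss_spec needs at least one component")
  weights <- rep_len(weights, length(components))
  if (any(weights <= 0)) stop("loss weights must be > 0")
  structure(list(components = components, weights = weights),
            class = "loss_spec")
}

# Jaccard-extension gradient of the Lovasz hinge for sorted errors
lovasz_grad <- function(y_sorted) {
  n <- length(y_sorted)
  gts <- sum(y_sorted)
  inter <- gts - cumsum(y_sorted)
  union <- gts + cumsum(1 - y_sorted)
  jac <- 1 - inter / union
  if (n > 1) jac[2:n] <- jac[2:n] - jac[1:(n - 1)]
  jac
}

# loss value + gradient wrt logits; z, y are vectors over pixels
loss_and_grad <- function(z, y, spec) {
  n <- length(z)
  p <- stats::plogis(z)
  pc <- clip(p, 1e-7, 1 - 1e-7)
  total <- 0
  dz <- numeric(n)
  comps <- numeric(length(spec$components))
  names(comps) <- spec$components
  for (i in seq_along(spec$components)) {
    w <- spec$weights[i]
    cmp <- spec$components[i]
    if (cmp == "bce") {
      L <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
      g <- (p - y) / n
    } else if (cmp == "dice") {
      e <- 1
      A <- sum(p * y); B <- sum(p) + sum(y)
      L <- 1 - (2 * A + e) / (B + e)
      dp <- -(2 * y * (B + e) - (2 * A + e)) / (B + e)^2
      g <- dp * p * (1 - p)
    } else if (cmp == "iou") {
      e <- 1
      I <- sum(p * y); U <- sum(p) + sum(y) - I
      L <- 1 - (I + e) / (U + e)
      dp <- -(y * (U + e) - (I + e) * (1 - y)) / (U + e)^2
      g <- dp * p * (1 - p)
    } else if (cmp == "focal") {
      al <- 0.25; ga <- 2
      L <- mean(-al * y * (1 - pc)^ga * log(pc) -
                  (1 - al) * (1 - y) * pc^ga * log(1 - pc))
      dp <- al * y * (ga * (1 - pc)^(ga - 1) * log(pc) - (1 - pc)^ga / pc) +
        (1 - al) * (1 - y) * (-ga * pc^(ga - 1) * log(1 - pc) + pc^ga / (1 - pc))
      g <- dp * p * (1 - p) / n
    } else { # lovasz hinge
      s <- 2 * y - 1
      err <- 1 - z * s
      o <- order(err, decreasing = TRUE)
      jac <- lovasz_grad(y[o])
      L <- sum(pmax(err[o], 0) * jac)
      de <- jac * (err[o] > 0)
      g <- numeric(n)
      g[o] <- de
      g <- g * (-s)
    }
    comps[i] <- L
    total <- total + w * L
    dz <- dz + w * g
  }
  list(loss = total, dz = dz, components = comps)
}

#' Compute a (possibly combined) segmentation loss
#'
#' Evaluates the weighted sum of the components named in `spec` on a
#' predicted probability map against a binary target. Each component is
#' non-negative and the multi-component value equals the sum of the
#' single-component values.
#'
#' @param pred numeric matrix/array of predicted foreground probabilities in
#'   `(0, 1)`.
#' @param target binary matrix/array of the same shape.
#' @param spec a [loss_spec()].
#' @return the scalar loss, with the per-component values in attribute
#'   `"components"`.
#' @examples
#' p <- matrix(0.5, 4, 4); y <- matrix(1, 4, 4)
#' seg_loss(p, y, loss_spec("bce"))  # log(2)
#' @export
seg_loss <- function(pred, target, spec = loss_spec("bce")) {
  stopifnot(inherits(spec, "loss_spec"))
  if (!all(dim(pred) == dim(target))) stop("pred and target shapes differ")
  p <- as.vector(pred); y <- as.vector(target) * 1
  if (anyNA(p) || anyNA(y)) stop("NaN/NA in loss inputs")
  if (any(p <= 0) || any(p >= 1)) p <- clip(p, 1e-7, 1 - 1e-7)
  res <- loss_and_grad(stats::qlogis(p), y, spec)
  structure(res$loss, components = res$components)
}
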