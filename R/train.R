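#' Training configuration
#'
#' Defaults follow the reference training recipe: initial learning rate
#' 0.002, Nesterov momentum 0.9 (SGD only), weight decay 3e-5, and a
#' dynamic learning rate that is reduced on a validation-metric plateau
#' (factor 0.1 after `lr_patience` stagnant epochs).
#'
#' @param optimizer `"adam"` or `"sgd"` (SGD with Nesterov momentum).
#' @param lr initial learning rate (> 0).
#' @param momentum Nesterov momentum (SGD only).
#' @param weight_decay L2 weight decay coefficient.
#' @param batch_size mini-batch size (>= 1), e.g. 2, 4 or 8.
#' @param epochs number of training epochs.
#' @param lr_factor multiplicative learning-rate reduction on plateau.
#' @param lr_patience epochs without validation improvement before reducing.
#' @param min_delta minimum improvement of the validation metric to reset
#'   the plateau counter.
#' @param seed integer seed controlling shuffling (and any other training
#'   randomness).
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), lr = 0.002,
                         momentum = 0.9, weight_decay = 3e-5,
                         batch_size = 4L, epochs = 10L, lr_factor = 0.1,
                         lr_patience = 5L, min_delta = 1e-4, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (lr <= 0) stop("lr must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must be in (0, 1)")
  structure(list(optimizer = optimizer, lr = lr, momentum = momentum,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), min_delta = min_delta,
                 seed = as.integer(seed)), class = "train_config")
}

# soft Dice of a probability map against a binary target (validation metric)
soft_dice <- function(p, y) {
  p <- as.vector(p); y <- as.vector(y) * 1
  (2 * sum(p * y) + 1) / (sum(p) + sum(y) + 1)
}

norm_img <- function(x) if (max(x) > 1.5) x / 255 else x

#' Train a U-Net on image/mask pairs
#'
#' Fits the model by mini-batch gradient descent on the requested loss,
#' monitoring mean per-patch soft Dice on the validation set. The learning
#' rate is reduced on plateau and the parameters of the best-validation
#' epoch are returned (last epoch when no validation set is given, in which
#' case the training loss is monitored instead).
#'
#' @param x list of RGB patch arrays (H x W x 3, values 0-255 or `[0,1]`).
#' @param y list of binary masks (H x W), paired with `x`.
#' @param x_val,y_val optional validation patches/masks.
#' @param config a [unet_config()]; spatial dims must match the patches.
#' @param train a [train_config()].
#' @param loss a [loss_spec()].
#' @param model optionally, an existing `"unet"` to continue training.
#' @param verbose print one line per epoch.
#' @return a trained `"unet"` object; `$history` is a data.frame with
#'   columns `epoch`, `train_loss`, `val_dice`, `lr`.
#' @export
unet_train <- function(x, y, x_val = NULL, y_val = NULL,
                       config = unet_config(), train = train_config(),
                       loss = loss_spec("bce"), model = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(config, "unet_config"), inherits(train, "train_config"),
            inherits(loss, "loss_spec"))
  if (length(x) == 0L || length(x) != length(y))
    stop("empty training set or x/y length mismatch")
  has_val <- !is.null(x_val) && length(x_val) > 0
  if (has_val && length(x_val) != length(y_val))
    stop("x_val/y_val length mismatch")
  x <- lapply(x, norm_img)
  if (has_val) x_val <- lapply(x_val, norm_img)
  if (is.null(model)) model <- build_unet(config, seed = train$seed)
  params <- model$params
  opt_state <- NULL
  lr <- train$lr
  n <- length(x)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_dice = numeric(0), lr = numeric(0))
  best_metric <- -Inf
  best_params <- params
  stall <- 0L
  step <- 0L
  with_seed(train$seed, {
    for (ep in seq_len(train$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1L, n, by = train$batch_size)) {
        idx <- ord[b0:min(b0 + train$batch_size - 1L, n)]
        grads <- NULL
        bloss <- 0
        for (i in idx) {
          fw <- unet_forward(params, x[[i]], cache = TRUE)
          lg <- loss_and_grad(fw$logits, as.vector(y[[i]]) * 1, loss)
          g <- unet_backward(params, fw$cache, lg$dz)
          grads <- if (is.null(grads)) g else nest_add(grads, g)
          bloss <- bloss + lg$loss
        }
        grads <- nest_scale(grads, 1 / length(idx))
        step <- step + 1L
        res <- if (train$optimizer == "adam") {
          adam_step(params, grads, opt_state, lr = lr, t = step,
                    weight_decay = train$weight_decay)
        } else {
          sgd_nesterov_step(params, grads, opt_state, lr = lr,
                            momentum = train$momentum,
                            weight_decay = train$weight_decay)
        }
        params <- res$p
        opt_state <- res$s
        ep_loss <- ep_loss + bloss
      }
      ep_loss <- ep_loss / n
      val_metric <- if (has_val) {
        mean(vapply(seq_along(x_val), function(i) {
          z <- unet_forward(params, x_val[[i]])
          soft_dice(stats::plogis(z), y_val[[i]])
        }, numeric(1)))
      } else {
        -ep_loss  # monitor training loss when no validation set
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, train_loss = ep_loss,
        val_dice = if (has_val) val_metric else NA_real_, lr = lr))
      if (val_metric > best_metric + train$min_delta) {
        best_metric <- val_metric
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train$lr_patience) {
          lr <- lr * train$lr_factor
          stall <- 0L
        }
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  val %.4f  lr %.2e",
                        ep, ep_loss, val_metric, lr))
    }
  })
  structure(list(params = best_params, config = config, train = train,
                 loss = loss, history = hist,
                 best_metric = if (has_val) best_metric else NA_real_),
            class = "unet")
}
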