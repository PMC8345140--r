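# U-Net architecture, forward contracts, losses and gradients

test_that("default architecture counts 23 convolutional layers", {
  expect_equal(count_conv_layers(unet_config()), 23)
  # census: 2*depth contraction + 2 bottleneck + depth up-conv +
  # 2*depth expansion + 1 final = 5*depth + 3
  for (d in 1:3) {
    cfg <- unet_config(input_size = c(64L, 64L, 3L), depth = d,
                       base_channels = 4L)
    expect_equal(count_conv_layers(cfg), 5 * d + 3)
  }
})

test_that("contraction blocks double their channel width", {
  cfg <- unet_config(input_size = c(32L, 32L, 3L), depth = 3L,
                     base_channels = 4L)
  net <- build_unet(cfg, seed = 1)
  expect_equal(nucquant:::encoder_channels(net), c(4L, 8L, 16L))
})

test_that("prediction preserves spatial shape and is deterministic", {
  cfg <- unet_config(input_size = c(64L, 64L, 3L), depth = 1L,
                     base_channels = 4L)
  net <- build_unet(cfg, seed = 2)
  for (hw in list(c(64, 64), c(32, 48), c(16, 16))) {
    x <- array(runif(prod(hw) * 3) * 255, c(hw, 3))
    p <- predict(net, x)
    expect_equal(dim(p), hw)
    expect_true(all(p >= 0 & p <= 1))
  }
  x <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  expect_identical(predict(net, x), predict(net, x))
  # extreme inputs stay in range
  expect_true(all(predict(net, array(0, c(64, 64, 3))) >= 0))
  expect_true(all(predict(net, array(255, c(64, 64, 3))) <= 1))
  # contract violations
  expect_error(predict(net, array(0, c(63, 64, 3))), "divisible")
  expect_error(predict(net, matrix(0, 64, 64)), "H x W x 3")
  expect_error(unet_config(input_size = c(60L, 60L, 3L), depth = 3L),
               "divisible")
})

test_that("loss components match closed forms and are additive", {
  y1 <- matrix(1, 8, 8)
  p_half <- matrix(0.5, 8, 8)
  expect_equal(as.numeric(seg_loss(p_half, y1, loss_spec("bce"))), log(2),
               tolerance = 1e-12)

  # perfect-prediction limit
  set.seed(1)
  y <- (matrix(runif(64), 8, 8) > 0.5) * 1
  p_perf <- ifelse(y == 1, 1 - 1e-6, 1e-6)
  for (cmp in c("bce", "dice", "iou", "focal", "lovasz"))
    expect_lt(as.numeric(seg_loss(p_perf, y, loss_spec(cmp))), 1e-4)

  # additivity of combinations
  p <- matrix(runif(64), 8, 8)
  combined <- as.numeric(seg_loss(p, y, loss_spec(c("bce", "iou"))))
  separate <- as.numeric(seg_loss(p, y, loss_spec("bce"))) +
    as.numeric(seg_loss(p, y, loss_spec("iou")))
  expect_equal(combined, separate, tolerance = 1e-6)
  # weights scale components
  expect_equal(as.numeric(seg_loss(p, y, loss_spec("bce", 2))),
               2 * as.numeric(seg_loss(p, y, loss_spec("bce"))))
  expect_error(seg_loss(matrix(NaN, 8, 8), y), "NaN")
  expect_error(loss_spec("hinge"), "unknown loss")
})

test_that("backpropagation matches finite-difference gradients", {
  cfg <- unet_config(input_size = c(8L, 8L, 3L), depth = 2L,
                     base_channels = 2L)
  net <- build_unet(cfg, seed = 3)
  set.seed(5)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- (matrix(runif(64), 8, 8) > 0.5) * 1
  spec <- loss_spec(c("bce", "dice", "iou", "focal"))
  fw <- nucquant:::unet_forward(net$params, x, cache = TRUE)
  lg <- nucquant:::loss_and_grad(fw$logits, as.vector(y), spec)
  g <- nucquant:::unet_backward(net$params, fw$cache, lg$dz)

  paths <- list(
    list(function(p) p$enc[[1]]$c1$W, function(p, W) { p$enc[[1]]$c1$W <- W; p }),
    list(function(p) p$enc[[2]]$c2$b, function(p, W) { p$enc[[2]]$c2$b <- W; p }),
    list(function(p) p$bott$c2$W, function(p, W) { p$bott$c2$W <- W; p }),
    list(function(p) p$up[[2]]$W[[3]], function(p, W) { p$up[[2]]$W[[3]] <- W; p }),
    list(function(p) p$up[[1]]$b, function(p, W) { p$up[[1]]$b <- W; p }),
    list(function(p) p$dec[[1]]$c1$W, function(p, W) { p$dec[[1]]$c1$W <- W; p }),
    list(function(p) p$final$W, function(p, W) { p$final$W <- W; p }),
    list(function(p) p$final$b, function(p, W) { p$final$b <- W; p })
  )
  loss_at <- function(params)
    nucquant:::loss_and_grad(nucquant:::unet_forward(params, x),
                             as.vector(y), spec)$loss
  eps <- 1e-5
  for (pth in paths) {
    W <- pth[[1]](net$params)
    for (i in sample(length(W), min(3, length(W)))) {
      Wp <- W; Wp[i] <- Wp[i] + eps
      Wm <- W; Wm[i] <- Wm[i] - eps
      num <- (loss_at(pth[[2]](net$params, Wp)) -
                loss_at(pth[[2]](net$params, Wm))) / (2 * eps)
      expect_equal(pth[[1]](g)[i], num, tolerance = 1e-5)
    }
  }
})

test_that("invalid configurations and datasets are rejected", {
  expect_error(unet_config(depth = 0), "depth")
  expect_error(unet_config(encoder = "resnet50"), "unknown encoder")
  expect_error(unet_train(list(), list()), "empty training set")
  expect_error(train_config(lr = -1), "lr")
  expect_error(train_config(batch_size = 0), "batch_size")
})
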