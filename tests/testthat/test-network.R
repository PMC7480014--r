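# Small configurations keep these tests fast; the full-width architecture is
# exercised in test-acceptance.R.

small_cfg <- function(width = 1 / 16, seg = 256, ch = 4)
  network_config(width_scale = width, seg_len = seg, in_channels = ch)

test_that("output shape equals input shape for any width", {
  for (w in c(1 / 16, 1 / 8)) {
    m <- build_model(small_cfg(w), seed = 1)
    x <- array(rnorm(2 * 256 * 4), dim = c(2, 256, 4))
    y <- predict_segments(m, x)
    expect_equal(dim(y), dim(x))
  }
})

test_that("zeroed weights reduce the network to the identity map", {
  m <- build_model(small_cfg(), seed = 1)
  zero_weights(m)
  x <- array(rnorm(3 * 256 * 4), dim = c(3, 256, 4))
  y <- predict_segments(m, x)
  expect_equal(y, x, tolerance = 1e-6)
})

test_that("encoder/decoder schedules mirror and halve/double temporal lengths", {
  m <- build_model(small_cfg(), seed = 1)
  sh <- model_shapes(m)
  enc <- sh$length[sh$stage == "encoder"]
  dec <- sh$length[sh$stage == "decoder"]
  expect_equal(enc, 256 / c(1, 2, 4, 8, 16, 32, 64, 128))
  expect_equal(dec, rev(c(256, enc[-8])))
  expect_equal(sh$channels[16], 4L)
})

test_that("width_scale floors filter counts at one and rejects nonsense", {
  cfg <- network_config(width_scale = 1e-4)
  expect_true(all(cfg$filters >= 1L))
  expect_error(network_config(width_scale = 0), "positive")
  expect_error(network_config(seg_len = 1000), "divisible")
})

test_that("normalized MSE loss matches hand computations and brute force", {
  expect_equal(nmse_loss(c(1, -1), c(1, -1)), 0)
  # clean (1,-1), denoised (0,0): msq = 1, loss = 1
  expect_equal(nmse_loss(c(1, -1), c(0, 0)), 1)
  # brute-force oracle on random arrays
  set.seed(7)
  cl <- array(rnorm(3 * 10 * 2), dim = c(3, 10, 2))
  de <- array(rnorm(3 * 10 * 2), dim = c(3, 10, 2))
  brute <- 0
  for (n in 1:3) for (l in 1:2) {
    msq <- mean(cl[n, , l]^2)
    brute <- brute + sum((cl[n, , l] - de[n, , l])^2) / msq
  }
  brute <- brute / (3 * 2 * 10)
  expect_equal(nmse_loss(cl, de), brute, tolerance = 1e-12)
  # invariance under common rescaling
  expect_equal(nmse_loss(2.7 * cl, 2.7 * de), nmse_loss(cl, de),
               tolerance = 1e-12)
  expect_error(nmse_loss(array(0, c(1, 4, 1)), array(1, c(1, 4, 1))),
               "zero-power")
})

test_that("C++ training loss agrees with the R loss definition", {
  m <- build_model(small_cfg(), seed = 2)
  set.seed(3)
  no <- array(rnorm(4 * 256 * 4), dim = c(4, 256, 4))
  cl <- array(rnorm(4 * 256 * 4), dim = c(4, 256, 4))
  pred <- predict_segments(m, no)
  expect_equal(
    fecgdenoise:::.nn_loss(m$ptr, as.numeric(no), as.numeric(cl),
                           dim(no), 4L),
    nmse_loss(cl, pred),
    tolerance = 1e-5
  )
})

test_that("backprop gradients match finite differences (directional derivative)", {
  cfg <- small_cfg(width = 1 / 32, ch = 2)
  m <- build_model(cfg, seed = 3)
  set.seed(42)
  no <- array(rnorm(2 * 256 * 2), dim = c(2, 256, 2))
  cl <- array(no + 0.1 * rnorm(2 * 256 * 2), dim = c(2, 256, 2))
  g <- fecgdenoise:::.nn_grads(m$ptr, as.numeric(no), as.numeric(cl), dim(no))
  w <- get_weights(m)
  gn2 <- sum(vapply(seq_along(w), function(li)
    sum(g[[li]]$dW^2) + sum(g[[li]]$db^2), numeric(1)))
  eps <- 1e-3
  wp <- w; wm <- w
  for (li in seq_along(w)) {
    wp[[li]]$W <- w[[li]]$W + eps * g[[li]]$dW
    wp[[li]]$b <- w[[li]]$b + eps * g[[li]]$db
    wm[[li]]$W <- w[[li]]$W - eps * g[[li]]$dW
    wm[[li]]$b <- w[[li]]$b - eps * g[[li]]$db
  }
  loss_at <- function(wts) {
    set_weights(m, wts)
    fecgdenoise:::.nn_loss(m$ptr, as.numeric(no), as.numeric(cl), dim(no), 2L)
  }
  fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
  expect_equal(fd, gn2, tolerance = 5e-3)
})

test_that("gradient flows all the way to the first encoder layer", {
  m <- build_model(small_cfg(), seed = 4)
  set.seed(5)
  no <- array(rnorm(2 * 256 * 4), dim = c(2, 256, 4))
  cl <- array(rnorm(2 * 256 * 4), dim = c(2, 256, 4))
  gn <- gradient_norms(m, no, cl)
  expect_equal(nrow(gn), 16L)
  expect_true(all(gn$grad_norm > 0))
})

test_that("a tiny model overfits a single fixed batch", {
  cfg <- network_config(width_scale = 1 / 16, seg_len = 256, in_channels = 2)
  m <- build_model(cfg, seed = 6)
  set.seed(8)
  cl <- array(rnorm(4 * 256 * 2), dim = c(4, 256, 2))
  no <- array(cl + rnorm(4 * 256 * 2), dim = c(4, 256, 2))
  m <- train_denoiser(m, no, cl,
                      config = train_config(batch_size = 4,
                                            learning_rate = 2e-3,
                                            epochs = 500, seed = 9))
  expect_lt(tail(m$history$train_loss, 1), 0.01)
})

test_that("training is deterministic under fixed seeds", {
  set.seed(11)
  cl <- array(rnorm(8 * 256 * 4), dim = c(8, 256, 4))
  no <- array(cl + rnorm(8 * 256 * 4), dim = c(8, 256, 4))
  run <- function() {
    m <- build_model(small_cfg(), seed = 12)
    m <- train_denoiser(m, no, cl, no, cl,
                        config = train_config(4, 1e-3, 3, seed = 13))
    m$history
  }
  expect_identical(run(), run())
})

test_that("training beats the identity map on held-out noisy data", {
  set.seed(14)
  n <- 40
  cl <- array(0, dim = c(n, 256, 4))
  base <- sin(2 * pi * 4 * (0:255) / 256)
  for (i in 1:n) for (ch in 1:4)
    cl[i, , ch] <- base * runif(1, 0.5, 1.5)
  no <- array(cl + 0.7 * rnorm(length(cl)), dim = dim(cl))
  tr <- 1:30; va <- 31:40
  m <- build_model(small_cfg(), seed = 15)
  m <- train_denoiser(m, no[tr, , , drop = FALSE], cl[tr, , , drop = FALSE],
                      no[va, , , drop = FALSE], cl[va, , , drop = FALSE],
                      config = train_config(8, 2e-3, 30, seed = 16))
  identity_loss <- nmse_loss(cl[va, , , drop = FALSE], no[va, , , drop = FALSE])
  expect_lt(tail(m$history$val_loss, 1), identity_loss)
})

test_that("analytic receptive field matches a perturbation oracle", {
  # brute-force oracle: which input samples can influence output sample j?
  cfg <- small_cfg(width = 1 / 32, ch = 1)
  m <- build_model(cfg, seed = 17)
  probe <- function(model, seg, pos) {
    x0 <- array(0, dim = c(1, seg, 1))
    y0 <- predict_segments(model, x0)
    hits <- logical(seg)
    for (s in seq_len(seg)) {
      x <- x0
      x[1, s, 1] <- 1
      y <- predict_segments(model, x)
      hits[s] <- abs(y[1, pos, 1] - y0[1, pos, 1]) > 1e-9
    }
    hits
  }
  # centre output of a 256-sample window; analytic rf for this schedule
  rf <- receptive_field(cfg)
  hits <- probe(m, 256, 128)
  span <- range(which(hits))
  measured <- span[2] - span[1] + 1
  # rf caps at the window length when the field exceeds it
  expect_equal(measured, min(rf, 256))
  # base cases of the recursion (schedule = encoder + mirrored decoder):
  # one stride-1 stage: conv rf 15, tconv adds (k-1)*1 -> 29
  one_layer <- structure(list(kernel_size = 15L, strides = 1L),
                         class = "network_config")
  expect_equal(receptive_field(one_layer), 29L)
  # stages (1, 2): enc 15 -> 29 (jump 2); dec jump 1: +14 -> 43; +14 -> 57
  two_layer <- structure(list(kernel_size = 15L, strides = c(1L, 2L)),
                         class = "network_config")
  expect_equal(receptive_field(two_layer), 57L)
})

test_that("single-channel variant denoises each channel independently", {
  cfg1 <- small_cfg(ch = 1)
  m <- build_model(cfg1, seed = 18)
  zero_weights(m)
  x <- mcecg(matrix(rnorm(512 * 4), ncol = 4), 500)
  y <- denoise(m, x)
  expect_equal(y$samples, x$samples, tolerance = 1e-5)
})

test_that("denoise preserves length, rate and units end to end", {
  m <- build_model(network_config(width_scale = 1 / 16), seed = 19)
  zero_weights(m)
  x <- mcecg(matrix(100 * rnorm(4000 * 4), ncol = 4), 500)
  y <- denoise(m, x)
  expect_equal(dim(y$samples), dim(x$samples))
  expect_equal(y$fs, 500)
  # zero-weight network is identity, so even the remainder tail matches
  expect_equal(y$samples, x$samples, tolerance = 1e-4)
})

test_that("model weights survive a get/set round trip", {
  m <- build_model(small_cfg(), seed = 20)
  x <- array(rnorm(256 * 4), dim = c(1, 256, 4))
  y1 <- predict_segments(m, x)
  w <- get_weights(m)
  m2 <- build_model(small_cfg(), seed = 99)
  set_weights(m2, w)
  expect_equal(predict_segments(m2, x), y1)
})

test_that("checkpoints embed config and weights and restore inference exactly", {
  m <- build_model(small_cfg(), seed = 21)
  x <- array(rnorm(2 * 256 * 4), dim = c(2, 256, 4))
  y1 <- predict_segments(m, x)
  path <- file.path(tempdir(), "ckpt.rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$config, m$config)
  expect_equal(predict_segments(m2, x), y1)
})
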