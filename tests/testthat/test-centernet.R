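sm <- asNamespace("spinemark")

test_that("the center network has the contracted output shapes and finite values", {
  m <- build_centernet(centernet_config(base_channels = 2), seed = 1)
  fw <- sm$centernet_forward(m, matrix(0, 512, 512))
  expect_equal(dim(fw$pre), c(64, 64))
  expect_equal(dim(fw$out), c(64, 64, 6))
  expect_true(all(is.finite(fw$pre)) && all(is.finite(fw$out)))
  expect_s3_class(predict_centers(m, matrix(0, 512, 512)), "confidence_stack")
})

test_that("initialization is seeded and architecture contracts hold", {
  cfg <- centernet_config(base_channels = 2)
  a <- build_centernet(cfg, seed = 5)
  b <- build_centernet(cfg, seed = 5)
  d <- build_centernet(cfg, seed = 6)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, d$params))
  expect_gt(param_count(a), 0)

  ## the two wide-kernel convolutions sit at the bottleneck
  expect_equal(a$params$wide1$k, 13L)
  expect_equal(a$params$wide2$k, 13L)
  ## at the heatmap scale they span k * (out_size / bottleneck_size)
  ## = 13 * 2 = 26 heatmap pixels >= 13, i.e. about twice the ~7-px
  ## inter-center spacing
  bottleneck_scale <- 2^a$cfg$depth
  expect_gte(a$cfg$wide_kernel * bottleneck_scale, 13)

  ## every block carries normalization parameters ahead of its convolution
  for (blk in a$params) {
    expect_true(all(c("gamma", "beta", "W", "b") %in% names(blk)))
  }
  expect_error(centernet_config(in_size = 512, out_size = 32))
  expect_error(centernet_config(wide_kernel = 12))
})

test_that("the center loss matches a brute-force elementwise oracle", {
  set.seed(52)
  gt <- array(runif(16 * 16 * 6), c(16, 16, 6))
  pre <- matrix(runif(256), 16, 16)
  out <- array(runif(16 * 16 * 6), c(16, 16, 6))

  ## independent accumulation with explicit loops
  oracle <- 0
  for (i in 1:16) for (j in 1:16) oracle <- oracle + (gt[i, j, 5] - pre[i, j])^2
  acc <- 0
  for (k in 1:6) for (i in 1:16) for (j in 1:16) {
    acc <- acc + (gt[i, j, k] - out[i, j, k])^2
  }
  oracle <- oracle + acc / 6
  expect_equal(center_loss(gt, pre, out), oracle, tolerance = 1e-6)

  ## exact fit gives zero
  expect_equal(center_loss(gt, gt[, , 5], gt), 0)
  ## perfect final maps, intermediate off by a constant-1 map:
  ## only the ||1||^2 term remains
  expect_equal(center_loss(gt, gt[, , 5] + 1, gt), 16 * 16)
  expect_error(center_loss(gt, pre, out[, , 1:3]))
})

test_that("centernet gradients exist, are finite, and match finite differences", {
  cfg <- centernet_config(base_channels = 2, depth = 1, wide_kernel = 5,
                          in_size = 32, out_size = 4)
  m <- build_centernet(cfg, seed = 7)
  set.seed(53)
  ## output convolutions initialize at zero; randomize them so gradients
  ## reach every block
  m$params$pre$W[] <- rnorm(length(m$params$pre$W), 0, 0.1)
  m$params$head$W[] <- rnorm(length(m$params$head$W), 0, 0.1)
  x <- matrix(runif(32 * 32, 0, 255), 32, 32)
  gt <- array(runif(4 * 4 * 6), c(4, 4, 6))
  fw <- sm$centernet_forward(m, x, keep_cache = TRUE)
  g <- sm$center_loss_grads(gt, fw$pre, fw$out)
  grads <- sm$centernet_backward(m, fw$cache, g$dpre, g$dout)
  lossf <- function(params) {
    f <- sm$centernet_forward(list(cfg = cfg, params = params), x)
    center_loss(gt, f$pre, f$out)
  }
  for (blk in names(m$params)) {
    expect_true(all(vapply(grads[[blk]], function(g) all(is.finite(g)), TRUE)))
    idx <- sample(length(m$params[[blk]]$W), 3)
    ng <- vapply(idx, function(i) {
      p1 <- m$params; p1[[blk]]$W[i] <- p1[[blk]]$W[i] + 1e-5
      p2 <- m$params; p2[[blk]]$W[i] <- p2[[blk]]$W[i] - 1e-5
      (lossf(p1) - lossf(p2)) / 2e-5
    }, 0)
    expect_lt(max(abs(ng - grads[[blk]]$W[idx])), 1e-4)
  }
})

test_that("a tiny center detector fits a small phantom set", {
  ## reduced input scale keeps this a fast wiring check
  cfg <- centernet_config(base_channels = 2, in_size = 128, out_size = 16,
                          wide_kernel = 7)
  samples <- lapply(1:16, function(i) generate_phantom(easy_spec(), i))
  ds <- make_center_dataset(samples, cfg)
  fit <- train_centernet(ds, cfg,
                         train_config(lr = 2e-3, batch = 4, max_epochs = 4,
                                      patience = 3, seed = 2),
                         val_fraction = 0.25)
  h <- fit$history
  expect_lte(nrow(h), 4)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))
  expect_error(train_centernet(list(), cfg), "empty")
})
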