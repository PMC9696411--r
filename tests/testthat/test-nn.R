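# Finite-difference validation of the network engine's backward passes.

sm <- asNamespace("spinemark")

num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

test_that("convolution gradients match finite differences", {
  set.seed(21)
  for (case in list(c(k = 3, s = 1), c(k = 3, s = 2), c(k = 5, s = 1))) {
    x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    p <- sm$nn_conv_init(case["k"], 2, 3, stride = case["s"])
    y <- sm$nn_conv_fwd(p, x)
    tgt <- array(rnorm(length(y)), dim(y))
    loss <- function(pp, xx) sum((sm$nn_conv_fwd(pp, xx) - tgt)^2)
    b <- sm$nn_conv_bwd(p, x, 2 * (y - tgt))
    gx <- num_grad(function(v) { x2 <- x; x2[] <- v; loss(p, x2) }, as.vector(x))
    gw <- num_grad(function(v) { p2 <- p; p2$W[] <- v; loss(p2, x) },
                   as.vector(p$W))
    gb <- num_grad(function(v) { p2 <- p; p2$b[] <- v; loss(p2, x) }, p$b)
    expect_lt(max(abs(gx - as.vector(b$dx))), 1e-6)
    expect_lt(max(abs(gw - as.vector(b$dW))), 1e-6)
    expect_lt(max(abs(gb - as.numeric(b$db))), 1e-6)
  }
})

test_that("instance-norm gradients match finite differences", {
  set.seed(22)
  x <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  p <- sm$nn_in_init(3)
  p$gamma <- runif(3, 0.5, 1.5); p$beta <- rnorm(3)
  fw <- sm$nn_in_fwd(p, x)
  tgt <- array(rnorm(length(fw$y)), dim(fw$y))
  loss <- function(pp, xx) sum((sm$nn_in_fwd(pp, xx)$y - tgt)^2)
  b <- sm$nn_in_bwd(p, fw, 2 * (fw$y - tgt))
  gx <- num_grad(function(v) { x2 <- x; x2[] <- v; loss(p, x2) }, as.vector(x))
  gg <- num_grad(function(v) { p2 <- p; p2$gamma[] <- v; loss(p2, x) }, p$gamma)
  expect_lt(max(abs(gx - as.vector(b$dx))), 1e-6)
  expect_lt(max(abs(gg - b$dgamma)), 1e-6)
})

test_that("nearest upsampling and its backward form an adjoint pair", {
  set.seed(23)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  y <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  ## <up(x), y> == <x, up_bwd(y)>
  expect_equal(sum(sm$nn_up2(x) * y), sum(x * sm$nn_up2_bwd(y)),
               tolerance = 1e-12)
  expect_equal(dim(sm$nn_up2(x)), c(8, 8, 2))
})

test_that("pre-activation block order is norm -> activation -> convolution", {
  set.seed(24)
  p <- sm$nn_block_init(3, 2, 2)
  expect_named(p, c("gamma", "beta", "W", "b", "k", "stride", "pad"))
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  got <- sm$nn_block_fwd(p, x)$y
  ## explicit recomposition in the stated order
  manual <- sm$nn_conv_fwd(p, pmax(sm$nn_in_fwd(p, x)$y, 0))
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("adam updates trainable leaves only and minimizes a quadratic", {
  params <- list(blk = c(sm$nn_in_init(1),
                         sm$nn_conv_init(3, 1, 1)))
  st <- sm$adam_init(params)
  k0 <- params$blk$k
  target <- matrix(0.3, 9, 1)
  for (i in 1:300) {
    grads <- list(blk = list(gamma = 0, beta = 0,
                             W = 2 * (params$blk$W - target), b = 0))
    up <- sm$adam_step(params, grads, st, lr = 0.05)
    params <- up$params; st <- up$state
  }
  expect_lt(max(abs(params$blk$W - target)), 1e-3)
  expect_identical(params$blk$k, k0)       # hyperparameters untouched
  expect_identical(params$blk$stride, 1L)
})

test_that("the training loop stops after patience epochs without improvement", {
  counter <- new.env(); counter$n <- 0
  grad_fn <- function(params, item) {
    list(loss = 0, grads = list(blk = list(W = matrix(0, 1, 1), b = 0)))
  }
  loss_fn <- function(params, item) {
    counter$n <- counter$n + 1
    counter$n  # strictly increasing validation loss
  }
  params <- list(blk = sm$nn_conv_init(1, 1, 1))
  params$blk$W <- matrix(0, 1, 1)
  fit <- sm$fit_network(params, list(1), list(1),
                        train_config(lr = 1e-3, batch = 1, max_epochs = 50,
                                     patience = 2),
                        grad_fn, loss_fn)
  expect_equal(nrow(fit$history), 3)  # epoch 1 best, then 2 bad epochs
  expect_equal(fit$best_epoch, 1)
  expect_error(sm$fit_network(params, list(), list(1),
                              train_config(max_epochs = 2, patience = 1),
                              grad_fn, loss_fn),
               "empty")
})
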