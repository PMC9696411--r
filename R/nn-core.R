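#' @title Compact CPU convolutional-network engine
#'
#' @description
#' Feature maps are `H x W x C` arrays. Convolutions use square kernels,
#' zero padding and uniform stride, computed by im2col + GEMM in C++;
#' every layer has an analytic backward pass (checked against finite
#' differences in the test suite). Blocks follow the pre-activation
#' ordering: instance normalization, ReLU, convolution.
#' @name nn
NULL

as_cube <- function(x) {
  if (length(dim(x)) == 2L) array(x, dim = c(dim(x), 1L)) else x
}

nn_conv_init <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(W = matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad))
}

nn_conv_fwd <- function(p, x) {
  conv_fwd_cpp(as_cube(x), p$W, p$b, p$k, p$stride, p$pad)
}

nn_conv_bwd <- function(p, x, dy) {
  conv_bwd_cpp(as_cube(x), p$W, as_cube(dy), p$k, p$stride, p$pad)
}

## training-path variants: forward keeps the im2col matrix (as an external
## pointer) so backward can skip rebuilding it
nn_conv_fwd_keep <- function(p, x) {
  conv_fwd_keep_cpp(as_cube(x), p$W, p$b, p$k, p$stride, p$pad)
}

nn_conv_bwd_cached <- function(p, cols, xdim, dy) {
  conv_bwd_cached_cpp(cols, xdim[1], xdim[2], xdim[3], p$W, as_cube(dy),
                      p$k, p$stride, p$pad)
}

nn_in_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

## Instance norm: per-channel spatial standardization of a single sample.
nn_in_fwd <- function(p, x, eps = 1e-5) {
  x <- as_cube(x)
  C <- dim(x)[3]
  xhat <- x
  inv_sd <- numeric(C)
  for (c in seq_len(C)) {
    xc <- x[, , c]
    mu <- mean(xc)
    v <- mean((xc - mu)^2)
    inv_sd[c] <- 1 / sqrt(v + eps)
    xhat[, , c] <- (xc - mu) * inv_sd[c]
  }
  y <- xhat
  for (c in seq_len(C)) y[, , c] <- xhat[, , c] * p$gamma[c] + p$beta[c]
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

nn_in_bwd <- function(p, cache, dy) {
  dy <- as_cube(dy)
  C <- dim(dy)[3]
  dx <- dy
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dyc <- dy[, , c]; xh <- cache$xhat[, , c]
    dgamma[c] <- sum(dyc * xh)
    dbeta[c] <- sum(dyc)
    dxhat <- dyc * p$gamma[c]
    dx[, , c] <- cache$inv_sd[c] *
      (dxhat - mean(dxhat) - xh * mean(dxhat * xh))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nn_relu_fwd <- function(x) pmax(x, 0)
nn_relu_bwd <- function(x, dy) dy * (x > 0)

## Pre-activation block: instance norm -> ReLU -> conv.
nn_block_init <- function(k, cin, cout, stride = 1L) {
  c(nn_in_init(cin), nn_conv_init(k, cin, cout, stride = stride))
}

nn_block_fwd <- function(p, x, keep_cols = TRUE) {
  inn <- nn_in_fwd(p, x)
  a <- nn_relu_fwd(inn$y)
  if (keep_cols) {
    cv <- nn_conv_fwd_keep(p, a)
    list(y = cv$y, cols = cv$cols, adim = dim(as_cube(a)), inn = inn, a = a)
  } else {
    list(y = nn_conv_fwd(p, a), inn = inn, a = a)
  }
}

nn_block_bwd <- function(p, cache, dy) {
  cv <- if (!is.null(cache$cols)) {
    nn_conv_bwd_cached(p, cache$cols, cache$adim, dy)
  } else {
    nn_conv_bwd(p, cache$a, dy)
  }
  da <- nn_relu_bwd(cache$inn$y, cv$dx)
  inb <- nn_in_bwd(p, cache$inn, da)
  list(dx = inb$dx,
       grads = list(gamma = inb$dgamma, beta = inb$dbeta,
                    W = cv$dW, b = as.numeric(cv$db)))
}

## Nearest-neighbour 2x upsampling and its adjoint.
nn_up2 <- function(x) {
  x <- as_cube(x)
  x[rep(seq_len(dim(x)[1]), each = 2), rep(seq_len(dim(x)[2]), each = 2), ,
    drop = FALSE]
}

nn_up2_bwd <- function(dy) {
  dy <- as_cube(dy)
  H <- dim(dy)[1] / 2; W <- dim(dy)[2] / 2; C <- dim(dy)[3]
  out <- array(0, dim = c(H, W, C))
  for (c in seq_len(C)) {
    m <- dy[, , c]
    out[, , c] <- m[seq(1, 2 * H, 2), seq(1, 2 * W, 2)] +
      m[seq(2, 2 * H, 2), seq(1, 2 * W, 2)] +
      m[seq(1, 2 * H, 2), seq(2, 2 * W, 2)] +
      m[seq(2, 2 * H, 2), seq(2, 2 * W, 2)]
  }
  out
}

## 2x average pooling (used for constant multi-scale image inputs only,
## so no backward pass is needed).
nn_avgpool2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  0.25 * (x[seq(1, h, 2), seq(1, w, 2)] + x[seq(2, h, 2), seq(1, w, 2)] +
            x[seq(1, h, 2), seq(2, w, 2)] + x[seq(2, h, 2), seq(2, w, 2)])
}

nn_concat <- function(...) {
  xs <- lapply(list(...), as_cube)
  H <- dim(xs[[1]])[1]; W <- dim(xs[[1]])[2]
  array(unlist(xs, use.names = FALSE),
        dim = c(H, W, sum(vapply(xs, function(x) dim(x)[3], 1L))))
}

nn_split <- function(x, sizes) {
  x <- as_cube(x)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_along(sizes), function(i) {
    x[, , starts[i]:ends[i], drop = FALSE]
  })
}

## ---- parameter-tree utilities ---------------------------------------------

## Trainable leaves are identified by name; conv hyperparameters
## (k, stride, pad) ride along untouched.
nn_trainable <- c("W", "b", "gamma", "beta")

param_map <- function(a, f) {
  if (!is.list(a)) return(a)
  for (k in seq_along(a)) {
    nm <- names(a)[k]
    if (is.list(a[[k]])) a[[k]] <- param_map(a[[k]], f)
    else if (nm %in% nn_trainable) a[[k]] <- f(a[[k]])
  }
  a
}

param_map2 <- function(a, b, f) {
  if (!is.list(a)) return(a)
  for (k in seq_along(a)) {
    nm <- names(a)[k]
    if (is.list(a[[k]])) a[[k]] <- param_map2(a[[k]], b[[nm]], f)
    else if (nm %in% nn_trainable) a[[k]] <- f(a[[k]], b[[nm]])
  }
  a
}

grads_add <- function(a, b) param_map2(a, b, `+`)
grads_scale <- function(a, s) param_map(a, function(x) x * s)

#' Number of trainable parameters in a network
#' @param model a built network (from [build_centernet()] or
#'   [build_landmarknet()]).
#' @return Integer parameter count (normalization and convolution weights).
#' @export
param_count <- function(model) {
  n <- 0L
  walk <- function(a, nm) {
    if (is.list(a)) {
      for (k in seq_along(a)) walk(a[[k]], names(a)[k])
    } else if (is.numeric(a) && nm %in% c("W", "b", "gamma", "beta")) {
      n <<- n + length(a)
    }
  }
  walk(model$params, "")
  n
}

adam_init <- function(params) {
  list(m = param_map(params, function(x) x * 0),
       v = param_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(state$m, state$v,
                    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- param_map2(params, upd, `-`)
  list(params = params, state = state)
}
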