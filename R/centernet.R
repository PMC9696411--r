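#' Center-detector network configuration
#'
#' An encoder with three stride-2 stages takes the 512-square enhanced
#' radiograph down to the 64-square heatmap scale; with `depth = 1` a
#' fourth stride-2 stage and a nearest-upsample/skip-fusion stage form a
#' U-shaped bottleneck, where two wide-kernel (default 13 x 13)
#' pre-activation convolutions give the trunk a receptive field spanning
#' about twice the typical inter-center spacing at heatmap scale. An
#' intermediate branch pre-predicts the L5 center map, which is
#' concatenated back into the trunk before the 6-channel head.
#'
#' @param base_channels trunk width multiplier.
#' @param depth 0 (bottleneck at the 64 scale) or 1 (extra stride-2
#'   stage; bottleneck at 32, then upsample + skip fusion).
#' @param wide_kernel odd kernel size of the two bottleneck convolutions.
#' @param in_size,out_size input/heatmap sides; their ratio must be 8.
#' @param out_channels number of center channels (6: L1-L5 + S1).
#' @return Object of class `centernet_config`.
#' @export
centernet_config <- function(base_channels = 8L, depth = 1L,
                             wide_kernel = 13L, in_size = 512L,
                             out_size = 64L, out_channels = 6L) {
  stopifnot(in_size / out_size == 8, wide_kernel %% 2 == 1,
            depth %in% c(0L, 1L), base_channels >= 1)
  structure(list(base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 wide_kernel = as.integer(wide_kernel),
                 in_size = as.integer(in_size),
                 out_size = as.integer(out_size),
                 out_channels = as.integer(out_channels)),
            class = "centernet_config")
}

#' Build the center-detector network
#'
#' @param cfg a [centernet_config()].
#' @param seed seed for the parameter initialization.
#' @return A model object (class `centernet`) with elements `cfg` and
#'   `params`.
#' @export
build_centernet <- function(cfg = centernet_config(), seed = 1L) {
  c1 <- cfg$base_channels
  params <- with_seed(seed, {
    p <- list(
      enc1 = nn_block_init(3, 1, c1, stride = 2),
      enc2 = nn_block_init(3, c1, 2 * c1, stride = 2),
      enc3 = nn_block_init(3, 2 * c1, 4 * c1, stride = 2)
    )
    if (cfg$depth == 1L) {
      p$down <- nn_block_init(3, 4 * c1, 4 * c1, stride = 2)
      p$wide1 <- nn_block_init(cfg$wide_kernel, 4 * c1, 4 * c1)
      p$wide2 <- nn_block_init(cfg$wide_kernel, 4 * c1, 4 * c1)
      p$fuse <- nn_block_init(3, 8 * c1, 4 * c1)
    } else {
      p$wide1 <- nn_block_init(cfg$wide_kernel, 4 * c1, 4 * c1)
      p$wide2 <- nn_block_init(cfg$wide_kernel, 4 * c1, 4 * c1)
    }
    p$pre <- nn_block_init(3, 4 * c1, 1)
    p$head <- nn_block_init(3, 4 * c1 + 1, cfg$out_channels)
    ## zero-initialized output convolutions: predictions start at the
    ## zero map (the loss starts at the target's own mass) instead of
    ## at initialization noise
    p$pre$W[] <- 0; p$head$W[] <- 0
    p
  })
  structure(list(cfg = cfg, params = params), class = "centernet")
}

#' @export
print.centernet <- function(x, ...) {
  cat(sprintf("<centernet %d->%d, %d channels, wide kernel %d, %d parameters>\n",
              x$cfg$in_size, x$cfg$out_size, x$cfg$base_channels,
              x$cfg$wide_kernel, param_count(x)))
  invisible(x)
}

## Forward pass. x: in_size x in_size matrix in [0, 255].
## Returns pre (H x W matrix), out (H x W x 6), and caches for backward.
centernet_forward <- function(model, x, keep_cache = FALSE) {
  blk <- function(pp, xx) nn_block_fwd(pp, xx, keep_cols = keep_cache)
  p <- model$params
  xin <- as_cube(x / 255)
  f1 <- blk(p$enc1, xin)
  f2 <- blk(p$enc2, f1$y)
  f3 <- blk(p$enc3, f2$y)
  if (model$cfg$depth == 1L) {
    fd <- blk(p$down, f3$y)
    w1 <- blk(p$wide1, fd$y)
    w2 <- blk(p$wide2, w1$y)
    up <- nn_up2(w2$y)
    cat64 <- nn_concat(up, f3$y)
    ff <- blk(p$fuse, cat64)
    trunk <- ff$y
  } else {
    w1 <- blk(p$wide1, f3$y)
    w2 <- blk(p$wide2, w1$y)
    fd <- NULL; ff <- NULL
    trunk <- w2$y
  }
  fp <- blk(p$pre, trunk)
  cath <- nn_concat(trunk, fp$y)
  fh <- blk(p$head, cath)
  cache <- if (keep_cache) {
    list(f1 = f1, f2 = f2, f3 = f3, fd = fd, w1 = w1, w2 = w2, ff = ff,
         fp = fp, fh = fh)
  }
  list(pre = fp$y[, , 1], out = fh$y, cache = cache)
}

## Backward pass from gradients on the two outputs; returns a grads tree
## aligned with model$params.
centernet_backward <- function(model, cache, dpre, dout) {
  p <- model$params
  c4 <- 4L * model$cfg$base_channels
  bh <- nn_block_bwd(p$head, cache$fh, as_cube(dout))
  sp <- nn_split(bh$dx, c(c4, 1L))
  bp <- nn_block_bwd(p$pre, cache$fp, as_cube(dpre) + sp[[2]])
  dtrunk <- sp[[1]] + bp$dx
  grads <- list()
  if (model$cfg$depth == 1L) {
    bf <- nn_block_bwd(p$fuse, cache$ff, dtrunk)
    spf <- nn_split(bf$dx, c(c4, c4))
    dup <- nn_up2_bwd(spf[[1]])
    bw2 <- nn_block_bwd(p$wide2, cache$w2, dup)
    bw1 <- nn_block_bwd(p$wide1, cache$w1, bw2$dx)
    bd <- nn_block_bwd(p$down, cache$fd, bw1$dx)
    d3 <- bd$dx + spf[[2]]
    grads$down <- bd$grads; grads$wide1 <- bw1$grads
    grads$wide2 <- bw2$grads; grads$fuse <- bf$grads
  } else {
    bw2 <- nn_block_bwd(p$wide2, cache$w2, dtrunk)
    bw1 <- nn_block_bwd(p$wide1, cache$w1, bw2$dx)
    d3 <- bw1$dx
    grads$wide1 <- bw1$grads; grads$wide2 <- bw2$grads
  }
  b3 <- nn_block_bwd(p$enc3, cache$f3, d3)
  b2 <- nn_block_bwd(p$enc2, cache$f2, b3$dx)
  b1 <- nn_block_bwd(p$enc1, cache$f1, b2$dx)
  grads$enc1 <- b1$grads; grads$enc2 <- b2$grads; grads$enc3 <- b3$grads
  grads$pre <- bp$grads; grads$head <- bh$grads
  grads[names(model$params)]
}

#' Center-detection loss
#'
#' `L = L_pre + L_final` where `L_pre` is the squared error of the
#' intermediate L5 map and `L_final` averages the per-channel squared
#' errors of the six final maps.
#'
#' @param gt ground-truth stack: `H x W x 6` array or [confidence_stack()]
#'   with channels L1..L5, S1 (channel 5 supervises the intermediate
#'   branch).
#' @param pre intermediate L5 prediction (`H x W` matrix).
#' @param out final prediction (`H x W x 6`).
#' @return Nonnegative scalar; zero iff both predictions equal the targets.
#' @export
center_loss <- function(gt, pre, out) {
  if (inherits(gt, "confidence_stack")) gt <- gt$maps
  stopifnot(all(dim(gt) == dim(out)), all(dim(gt)[1:2] == dim(as_cube(pre))[1:2]))
  lpre <- sum((gt[, , 5] - pre)^2)
  lfinal <- sum((gt - out)^2) / dim(gt)[3]
  lpre + lfinal
}

center_loss_grads <- function(gt, pre, out) {
  if (inherits(gt, "confidence_stack")) gt <- gt$maps
  list(dpre = 2 * (as_cube(pre)[, , 1] - gt[, , 5]),
       dout = 2 * (out - gt) / dim(gt)[3])
}

#' Build a center-training dataset from annotated images
#'
#' Preprocesses each sample (resize/pad to the network input, Gaussian
#' blur + CLAHE) and constructs the ground-truth center maps at heatmap
#' scale with the center sigma rule (half the L5 height in heatmap
#' pixels).
#'
#' @param samples list of `annotated_image` objects.
#' @param cfg a [centernet_config()] (for the input/heatmap sizes).
#' @param blur_sigma,clahe_clip,clahe_tile passed to [enhance()].
#' @return List of items with `x` (input matrix), `gt` (heatmap stack
#'   array), `boxes` (vertebra boxes in the input frame, for cutout
#'   augmentation), `transform` (original -> input), and `sample`.
#' @export
make_center_dataset <- function(samples, cfg = centernet_config(),
                                blur_sigma = 1, clahe_clip = 2,
                                clahe_tile = 8) {
  hm <- input_to_heatmap(cfg$in_size)
  lapply(samples, function(s) {
    rp <- resize_and_pad(s$pixels, target = cfg$in_size)
    x <- enhance(rp$image, blur_sigma, clahe_clip, clahe_tile)
    chain <- list(rp$transform, hm)
    centers_hm <- map_points(s$centers, chain)
    l5_hm <- map_points(s$landmarks$L5, chain)
    sig <- sigma_for("center", l5_hm)
    gt <- gaussian_map(centers_hm, sig,
                       c(cfg$out_size, cfg$out_size),
                       frame = "heatmap", channel_labels = vertebra_labels())
    boxes <- lapply(s$vertebra_boxes, function(b) {
      m <- unname(map_points(rbind(b[c("x0", "y0")], b[c("x1", "y1")]),
                             rp$transform))
      c(x0 = m[1, 1], y0 = m[1, 2], x1 = m[2, 1], y1 = m[2, 2])
    })
    list(x = x, gt = gt$maps, boxes = boxes, transform = rp$transform,
         sample = s)
  })
}

## Zero a cutout rectangle inside a randomly chosen candidate vertebra box
## (boxes already in the input frame). Used as training-time augmentation.
apply_rsc_input <- function(x, boxes, ratio = 0.6,
                            candidates = c("L1", "L2", "L3", "L4")) {
  lab <- candidates[sample.int(length(candidates), 1)]
  b <- boxes[[lab]]
  bx0 <- ceiling(b["x0"]); by0 <- ceiling(b["y0"])
  bw <- floor(b["x1"]) - bx0 + 1; bh <- floor(b["y1"]) - by0 + 1
  mw <- round(ratio * bw); mh <- round(ratio * bh)
  if (mw < 1 || mh < 1) return(x)
  x0 <- bx0 + sample.int(bw - mw + 1, 1) - 1
  y0 <- by0 + sample.int(bh - mh + 1, 1) - 1
  x[(y0 + 1):(y0 + mh), (x0 + 1):(x0 + mw)] <- 0
  x
}

#' Train the center detector
#'
#' @param dataset list from [make_center_dataset()] (or compatible items
#'   with `x` and `gt`).
#' @param cfg a [centernet_config()].
#' @param tcfg a [train_config()]; `tcfg$rsc_prob > 0` enables random
#'   spine cutout on training inputs.
#' @param val_fraction fraction of `dataset` held out for validation when
#'   `val_data` is NULL.
#' @param val_data optional explicit validation list.
#' @param model optional pre-built [build_centernet()] model to continue.
#' @return List with `model` (best-validation weights) and `history`
#'   (per-epoch data.frame).
#' @export
train_centernet <- function(dataset, cfg = centernet_config(),
                            tcfg = train_config(), val_fraction = 0.2,
                            val_data = NULL, model = NULL) {
  if (length(dataset) == 0L) stop("empty dataset")
  if (is.null(model)) model <- build_centernet(cfg, seed = tcfg$seed)
  if (is.null(val_data)) {
    nval <- max(1L, round(val_fraction * length(dataset)))
    val_idx <- with_seed(tcfg$seed + 1L,
                         sample.int(length(dataset), nval))
    val_data <- dataset[val_idx]
    dataset <- dataset[-val_idx]
  }
  grad_fn <- function(params, item) {
    m <- list(cfg = model$cfg, params = params)
    x <- item$x
    if (tcfg$rsc_prob > 0 && !is.null(item$boxes) &&
        runif(1) < tcfg$rsc_prob) {
      x <- apply_rsc_input(x, item$boxes)
    }
    fw <- centernet_forward(m, x, keep_cache = TRUE)
    loss <- center_loss(item$gt, fw$pre, fw$out)
    g <- center_loss_grads(item$gt, fw$pre, fw$out)
    grads <- centernet_backward(m, fw$cache, g$dpre, g$dout)
    list(loss = loss, grads = grads)
  }
  loss_fn <- function(params, item) {
    m <- list(cfg = model$cfg, params = params)
    fw <- centernet_forward(m, item$x)
    center_loss(item$gt, fw$pre, fw$out)
  }
  fit <- fit_network(model$params, dataset, val_data, tcfg, grad_fn, loss_fn)
  model$params <- fit$params
  list(model = model, history = fit$history, best_epoch = fit$best_epoch,
       best_val_loss = fit$best_val_loss)
}

#' Predict center confidence maps for one image
#'
#' @param model a trained `centernet`.
#' @param x preprocessed input matrix (`in_size` square, `[0, 255]`).
#' @return A [confidence_stack()] in the heatmap frame (values clipped to
#'   `[0, 1]` at decode time, not here).
#' @export
predict_centers <- function(model, x) {
  fw <- centernet_forward(model, x)
  confidence_stack(fw$out, frame = "heatmap",
                   channel_labels = vertebra_labels())
}
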