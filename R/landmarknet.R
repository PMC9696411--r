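#' Normalized coordinate channels
#'
#' Two constant channels holding each pixel's normalized position: the x
#' channel runs linearly from -1 (left column) to 1 (right column), the y
#' channel from -1 (top row) to 1 (bottom row). Concatenating them to a
#' convolution's input breaks translation invariance so the network can
#' learn the location prior of the landmarks inside a centered crop.
#'
#' @param height,width raster size (both >= 2).
#' @return `height x width x 2` array (x channel first).
#' @export
coord_channels <- function(height, width) {
  stopifnot(height >= 2, width >= 2)
  xs <- seq(-1, 1, length.out = width)
  ys <- seq(-1, 1, length.out = height)
  out <- array(0, dim = c(height, width, 2))
  out[, , 1] <- matrix(xs, height, width, byrow = TRUE)
  out[, , 2] <- matrix(ys, height, width)
  out
}

#' Landmark-detector network configuration
#'
#' An M-shaped encoder-decoder on 256-square vertebra crops: four
#' stride-2 encoder stages with downsampled copies of the input injected
#' at each scale (multi-scale inputs), coordinate channels concatenated at
#' the first `coordconv_stages` encoder stages, and a decoder with skip
#' connections back to full resolution. One head emits the landmark
#' confidence maps plus a single shared part-affinity channel: 4 + 1
#' channels for a lumbar vertebra, 2 + 1 for the sacrum, so predicting
#' the affinity field costs exactly one extra output channel.
#'
#' @param kind `"lumbar"` or `"sacrum"`.
#' @param base_channels trunk width multiplier.
#' @param coordconv_stages number of leading encoder stages using
#'   coordinate channels (0-2, default 2).
#' @param in_size input crop side (default 256).
#' @param multiscale inject downsampled input copies at each encoder
#'   stage (default TRUE).
#' @param alpha,beta affinity-loss weights for the lumbar and sacrum
#'   losses (defaults 0.001 and 0.01).
#' @return Object of class `landmarknet_config`.
#' @export
landmarknet_config <- function(kind = c("lumbar", "sacrum"),
                               base_channels = 8L, coordconv_stages = 2L,
                               in_size = 256L, multiscale = TRUE,
                               alpha = 0.001, beta = 0.01) {
  kind <- match.arg(kind)
  stopifnot(coordconv_stages %in% 0:2, alpha > 0, beta > 0)
  cm <- if (kind == "lumbar") 4L else 2L
  structure(list(kind = kind, base_channels = as.integer(base_channels),
                 coordconv_stages = as.integer(coordconv_stages),
                 in_size = as.integer(in_size),
                 multiscale = isTRUE(multiscale),
                 cm_channels = cm, out_channels = cm + 1L,
                 alpha = alpha, beta = beta),
            class = "landmarknet_config")
}

#' Build a landmark-detector network
#'
#' @param cfg a [landmarknet_config()].
#' @param seed parameter-initialization seed.
#' @return Model object of class `landmarknet` with `cfg` and `params`.
#' @export
build_landmarknet <- function(cfg = landmarknet_config(), seed = 1L) {
  c1 <- cfg$base_channels
  cc <- cfg$coordconv_stages
  ms <- as.integer(cfg$multiscale)
  params <- with_seed(seed, list(
    enc1 = nn_block_init(3, 1 + 2 * (cc >= 1), c1, stride = 2),
    enc2 = nn_block_init(3, c1 + ms + 2 * (cc >= 2), 2 * c1, stride = 2),
    enc3 = nn_block_init(3, 2 * c1 + ms, 4 * c1, stride = 2),
    enc4 = nn_block_init(3, 4 * c1 + ms, 4 * c1, stride = 2),
    bott = nn_block_init(3, 4 * c1, 4 * c1),
    dec1 = nn_block_init(3, 8 * c1, 4 * c1),
    dec2 = nn_block_init(3, 6 * c1, 2 * c1),
    dec3 = nn_block_init(3, 3 * c1, c1),
    dec4 = nn_block_init(3, c1 + 1, c1),
    head = nn_block_init(3, c1, cfg$out_channels)
  ))
  params$head$W[] <- 0  # predictions start at the zero map
  structure(list(cfg = cfg, params = params), class = "landmarknet")
}

#' @export
print.landmarknet <- function(x, ...) {
  cat(sprintf(
    "<landmarknet %s %d-square, %d+1 channels, coordconv %d, %d parameters>\n",
    x$cfg$kind, x$cfg$in_size, x$cfg$cm_channels, x$cfg$coordconv_stages,
    param_count(x)))
  invisible(x)
}

## Forward pass. x: in_size square matrix in [0, 255]. Returns cm
## (H x W x cm_channels), paf (H x W), cache.
landmarknet_forward <- function(model, x, keep_cache = FALSE) {
  blk <- function(pp, xx) nn_block_fwd(pp, xx, keep_cols = keep_cache)
  p <- model$params
  cfg <- model$cfg
  cc <- cfg$coordconv_stages
  ms <- cfg$multiscale
  xin <- as_cube(x / 255)
  H <- dim(xin)[1]
  x2 <- nn_avgpool2(xin[, , 1]); x4 <- nn_avgpool2(x2); x8 <- nn_avgpool2(x4)
  in1 <- if (cc >= 1) nn_concat(xin, coord_channels(H, H)) else xin
  f1 <- blk(p$enc1, in1)
  in2 <- f1$y
  if (ms) in2 <- nn_concat(in2, x2)
  if (cc >= 2) in2 <- nn_concat(in2, coord_channels(H / 2, H / 2))
  f2 <- blk(p$enc2, in2)
  in3 <- if (ms) nn_concat(f2$y, x4) else f2$y
  f3 <- blk(p$enc3, in3)
  in4 <- if (ms) nn_concat(f3$y, x8) else f3$y
  f4 <- blk(p$enc4, in4)
  fb <- blk(p$bott, f4$y)
  d1 <- blk(p$dec1, nn_concat(nn_up2(fb$y), f3$y))
  d2 <- blk(p$dec2, nn_concat(nn_up2(d1$y), f2$y))
  d3 <- blk(p$dec3, nn_concat(nn_up2(d2$y), f1$y))
  d4 <- blk(p$dec4, nn_concat(nn_up2(d3$y), xin))
  fh <- blk(p$head, d4$y)
  cm <- fh$y[, , seq_len(cfg$cm_channels), drop = FALSE]
  paf <- fh$y[, , cfg$out_channels]
  cache <- if (keep_cache) {
    list(f1 = f1, f2 = f2, f3 = f3, f4 = f4, fb = fb,
         d1 = d1, d2 = d2, d3 = d3, d4 = d4, fh = fh)
  }
  list(cm = cm, paf = paf, cache = cache)
}

## Backward pass; dcm: H x W x cm_channels, dpaf: H x W.
landmarknet_backward <- function(model, cache, dcm, dpaf) {
  p <- model$params
  cfg <- model$cfg
  c1 <- cfg$base_channels
  dy <- nn_concat(dcm, dpaf)
  bh <- nn_block_bwd(p$head, cache$fh, dy)
  b4d <- nn_block_bwd(p$dec4, cache$d4, bh$dx)
  s4 <- nn_split(b4d$dx, c(c1, 1L))
  b3d <- nn_block_bwd(p$dec3, cache$d3, nn_up2_bwd(s4[[1]]))
  s3 <- nn_split(b3d$dx, c(2L * c1, c1))
  b2d <- nn_block_bwd(p$dec2, cache$d2, nn_up2_bwd(s3[[1]]))
  s2 <- nn_split(b2d$dx, c(4L * c1, 2L * c1))
  b1d <- nn_block_bwd(p$dec1, cache$d1, nn_up2_bwd(s2[[1]]))
  s1 <- nn_split(b1d$dx, c(4L * c1, 4L * c1))
  bb <- nn_block_bwd(p$bott, cache$fb, nn_up2_bwd(s1[[1]]))
  b4 <- nn_block_bwd(p$enc4, cache$f4, bb$dx)
  d3in <- b4$dx[, , seq_len(4L * c1), drop = FALSE] + s1[[2]]
  b3 <- nn_block_bwd(p$enc3, cache$f3, d3in)
  d2in <- b3$dx[, , seq_len(2L * c1), drop = FALSE] + s2[[2]]
  b2 <- nn_block_bwd(p$enc2, cache$f2, d2in)
  d1in <- b2$dx[, , seq_len(c1), drop = FALSE] + s3[[2]]
  b1 <- nn_block_bwd(p$enc1, cache$f1, d1in)
  list(enc1 = b1$grads, enc2 = b2$grads, enc3 = b3$grads, enc4 = b4$grads,
       bott = bb$grads, dec1 = b1d$grads, dec2 = b2d$grads,
       dec3 = b3d$grads, dec4 = b4d$grads, head = bh$grads)
}

#' Landmark-detection loss
#'
#' Channel-averaged squared error on the landmark confidence maps plus a
#' weighted squared error on the part-affinity channel: weight `alpha`
#' (default 0.001) for the 4-landmark lumbar head, `beta` (default 0.01)
#' for the 2-landmark sacrum head.
#'
#' @param pred_cm,pred_paf predictions (`H x W x K` array; `H x W` map).
#' @param gt_cm,gt_paf ground truth ([confidence_stack()]/array and
#'   [paf_map()]/matrix).
#' @param cfg a [landmarknet_config()] providing `kind` and the weights.
#' @return Nonnegative scalar, zero iff both predictions are exact.
#' @export
landmark_loss <- function(pred_cm, pred_paf, gt_cm, gt_paf, cfg) {
  if (inherits(gt_cm, "confidence_stack")) gt_cm <- gt_cm$maps
  if (inherits(gt_paf, "paf_map")) gt_paf <- gt_paf$map
  stopifnot(all(dim(pred_cm) == dim(gt_cm)),
            dim(pred_cm)[3] == cfg$cm_channels)
  wt <- if (cfg$kind == "lumbar") cfg$alpha else cfg$beta
  sum((gt_cm - pred_cm)^2) / cfg$cm_channels + wt * sum((gt_paf - pred_paf)^2)
}

landmark_loss_grads <- function(pred_cm, pred_paf, gt_cm, gt_paf, cfg) {
  if (inherits(gt_cm, "confidence_stack")) gt_cm <- gt_cm$maps
  if (inherits(gt_paf, "paf_map")) gt_paf <- gt_paf$map
  wt <- if (cfg$kind == "lumbar") cfg$alpha else cfg$beta
  list(dcm = 2 * (pred_cm - gt_cm) / cfg$cm_channels,
       dpaf = 2 * wt * (pred_paf - gt_paf))
}

#' Decode landmarks from predicted confidence maps
#'
#' Per-channel global argmax (row-major tie-break; constant channels fall
#' back to the weighted centroid with a warning), mapped through the crop
#' transform into the source frame.
#'
#' @param pred_cm `H x W x K` array (K = 4 or 2) or [confidence_stack()].
#' @param crop_transform [frame_transform()] `crop -> original` from
#'   [crop_vertebra()] (identity transform to stay in crop coordinates).
#' @return `K x 2` matrix of `(x, y)` points in the target frame.
#' @export
decode_landmarks <- function(pred_cm, crop_transform = NULL) {
  pts <- extract_maxima(pred_cm)
  if (!is.null(crop_transform)) pts <- map_points(pts, crop_transform)
  colnames(pts) <- c("x", "y")
  pts
}

#' Build a landmark-training dataset of ground-truth-centered crops
#'
#' Crops each vertebra from the (zero-padded) original raster using the
#' ground-truth centers and spacing-derived square windows, and builds
#' the Gaussian landmark maps (sigma: 1/10 mean diagonal for lumbar, 1/6
#' inter-landmark distance for sacrum) and the shared part-affinity
#' channel in crop coordinates. Training crops always use ground-truth
#' centers; inference uses predicted centers — that asymmetry is part of
#' the method and is preserved by construction.
#'
#' @param samples list of `annotated_image` objects.
#' @param kind `"lumbar"` (one item per L1-L5 crop) or `"sacrum"`.
#' @param cfg a [landmarknet_config()] of the same kind.
#' @param paf_width affinity band width in crop pixels (default 4).
#' @param blur_sigma crop blur (default 1).
#' @return List of items with `x` (crop), `gt_cm`, `gt_paf`, `transform`
#'   (crop -> original), `vertebra`, `sample_id`, and `gt_landmarks`
#'   (original frame).
#' @export
make_landmark_dataset <- function(samples, kind = c("lumbar", "sacrum"),
                                  cfg = landmarknet_config(kind),
                                  paf_width = 4, blur_sigma = 1) {
  kind <- match.arg(kind)
  labs <- if (kind == "lumbar") paste0("L", 1:5) else "S1"
  items <- list()
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    sides <- crop_sizes(s$centers)
    for (lab in labs) {
      cr <- crop_vertebra(s$pixels, s$centers[lab, ], sides[[lab]],
                          out_size = cfg$in_size, blur_sigma = blur_sigma)
      lm <- map_points(s$landmarks[[lab]], ft_invert(cr$transform))
      shape <- c(cfg$in_size, cfg$in_size)
      if (any(lm < 0 | lm > cfg$in_size - 1)) next  # landmark outside crop
      sig <- sigma_for(if (kind == "lumbar") "lumbar" else "sacrum", lm)
      gt_cm <- gaussian_map(lm, sig, shape, frame = "crop")
      gt_paf <- paf_map(plate_segments(lm), width = paf_width, shape = shape)
      items[[length(items) + 1L]] <-
        list(x = cr$crop, gt_cm = gt_cm$maps, gt_paf = gt_paf$map,
             transform = cr$transform, vertebra = lab, sample_id = si,
             gt_landmarks = s$landmarks[[lab]])
    }
  }
  items
}

#' Train a landmark detector
#'
#' @param dataset list from [make_landmark_dataset()].
#' @param cfg a [landmarknet_config()].
#' @param tcfg a [train_config()].
#' @param val_fraction,val_data validation split as in [train_centernet()].
#' @param model optional pre-built model to continue training.
#' @return List with `model`, `history`, `best_epoch`, `best_val_loss`.
#' @export
train_landmarknet <- function(dataset, cfg = landmarknet_config(),
                              tcfg = train_config(), val_fraction = 0.2,
                              val_data = NULL, model = NULL) {
  if (length(dataset) == 0L) stop("empty dataset")
  if (is.null(model)) model <- build_landmarknet(cfg, seed = tcfg$seed)
  if (is.null(val_data)) {
    nval <- max(1L, round(val_fraction * length(dataset)))
    val_idx <- with_seed(tcfg$seed + 1L, sample.int(length(dataset), nval))
    val_data <- dataset[val_idx]
    dataset <- dataset[-val_idx]
  }
  grad_fn <- function(params, item) {
    m <- list(cfg = model$cfg, params = params)
    fw <- landmarknet_forward(m, item$x, keep_cache = TRUE)
    loss <- landmark_loss(fw$cm, fw$paf, item$gt_cm, item$gt_paf, model$cfg)
    g <- landmark_loss_grads(fw$cm, fw$paf, item$gt_cm, item$gt_paf, model$cfg)
    grads <- landmarknet_backward(m, fw$cache, g$dcm, g$dpaf)
    list(loss = loss, grads = grads)
  }
  loss_fn <- function(params, item) {
    m <- list(cfg = model$cfg, params = params)
    fw <- landmarknet_forward(m, item$x)
    landmark_loss(fw$cm, fw$paf, item$gt_cm, item$gt_paf, model$cfg)
  }
  fit <- fit_network(model$params, dataset, val_data, tcfg, grad_fn, loss_fn)
  model$params <- fit$params
  list(model = model, history = fit$history, best_epoch = fit$best_epoch,
       best_val_loss = fit$best_val_loss)
}
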