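#' Augmentation configuration
#'
#' @param rsc_ratio fraction of the vertebra box width/height removed by
#'   random spine cutout (default 0.6).
#' @param rsc_candidates vertebra labels eligible for cutout (default the
#'   often-occluded L1-L4).
#' @param rsc_prob per-sample probability of applying RSC during training.
#' @param cutout_size `c(w, h)` of the conventional cutout rectangle (px).
#' @param brightness_range additive intensity jitter range.
#' @param contrast_range multiplicative contrast jitter range.
#' @param rotation_sd rotation jitter sd in degrees.
#' @param scale_range uniform scale jitter range.
#' @param translation_range max absolute translation per axis (px).
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(rsc_ratio = 0.6,
                           rsc_candidates = c("L1", "L2", "L3", "L4"),
                           rsc_prob = 0.5,
                           cutout_size = c(40, 28),
                           brightness_range = c(-20, 20),
                           contrast_range = c(0.85, 1.15),
                           rotation_sd = 3,
                           scale_range = c(0.95, 1.05),
                           translation_range = 10) {
  stopifnot(rsc_ratio > 0, rsc_ratio <= 1,
            all(rsc_candidates %in% c("L1", "L2", "L3", "L4", "L5")),
            length(rsc_candidates) >= 1)
  structure(list(rsc_ratio = rsc_ratio, rsc_candidates = rsc_candidates,
                 rsc_prob = rsc_prob, cutout_size = cutout_size,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range, rotation_sd = rotation_sd,
                 scale_range = scale_range,
                 translation_range = translation_range),
            class = "augment_config")
}

#' Random spine cutout
#'
#' Chooses one vertebra uniformly from `cfg$rsc_candidates` and zeroes a
#' rectangle of `ratio * box_w` by `ratio * box_h` pixels placed uniformly
#' at random fully inside that vertebra's axis-aligned box. Annotations
#' are unchanged: the network must still localize the center of the
#' masked vertebra, which is what makes the detector robust to the
#' occlusions common on radiographs.
#'
#' @param sample an `annotated_image` with `vertebra_boxes`.
#' @param cfg an [augment_config()].
#' @param seed optional integer seed for a reproducible draw.
#' @return The augmented `annotated_image`; `$rsc` records the chosen
#'   vertebra and mask rectangle `c(x0, y0, w, h)` (0-based pixels).
#' @export
random_spine_cutout <- function(sample, cfg = augment_config(), seed = NULL) {
  if (is.null(sample$vertebra_boxes)) stop("vertebra_boxes missing")
  cand <- cfg$rsc_candidates
  if (length(cand) == 0L) stop("empty candidate set")
  with_seed(seed, {
    lab <- cand[sample.int(length(cand), 1)]
    box <- sample$vertebra_boxes[[lab]]
    bx0 <- ceiling(box["x0"]); by0 <- ceiling(box["y0"])
    bw <- floor(box["x1"]) - bx0 + 1; bh <- floor(box["y1"]) - by0 + 1
    mw <- round(cfg$rsc_ratio * bw); mh <- round(cfg$rsc_ratio * bh)
    x0 <- bx0 + sample.int(bw - mw + 1, 1) - 1L
    y0 <- by0 + sample.int(bh - mh + 1, 1) - 1L
    sample$pixels[(y0 + 1):(y0 + mh), (x0 + 1):(x0 + mw)] <- 0
    sample$rsc <- list(vertebra = lab,
                       rect = c(x0 = unname(x0), y0 = unname(y0),
                                w = unname(mw), h = unname(mh)))
    sample
  })
}

#' Conventional cutout
#'
#' Zeroes one rectangle of the configured size at a uniformly random
#' position anywhere in the raster (so, unlike [random_spine_cutout()],
#' it frequently falls on background).
#'
#' @inheritParams random_spine_cutout
#' @return The augmented `annotated_image`; `$cutout` records the mask.
#' @export
conventional_cutout <- function(sample, cfg = augment_config(), seed = NULL) {
  h <- nrow(sample$pixels); w <- ncol(sample$pixels)
  mw <- round(cfg$cutout_size[1]); mh <- round(cfg$cutout_size[2])
  if (mw <= 0 || mh <= 0) stop("cutout_size must be positive")
  if (mw > w || mh > h) stop("cutout larger than raster")
  with_seed(seed, {
    x0 <- sample.int(w - mw + 1, 1) - 1L
    y0 <- sample.int(h - mh + 1, 1) - 1L
    sample$pixels[(y0 + 1):(y0 + mh), (x0 + 1):(x0 + mw)] <- 0
    sample$cutout <- c(x0 = x0, y0 = y0, w = mw, h = mh)
    sample
  })
}

## Similarity warp about the image center: rotation (deg), scale,
## translation (px). Pixels are inverse-mapped with bilinear sampling and
## reflection padding; annotations get the same forward map.
similarity_warp <- function(sample, rotation = 0, scale = 1, translation = c(0, 0)) {
  h <- nrow(sample$pixels); w <- ncol(sample$pixels)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  R <- rot2(rotation) * scale
  fwd <- function(p) sweep(sweep(p, 2, ctr) %*% t(R), 2, ctr + translation, "+")
  if (rotation != 0 || scale != 1 || any(translation != 0)) {
    Rin <- rot2(-rotation) / scale
    px <- matrix(0:(w - 1), h, w, byrow = TRUE)
    py <- matrix(0:(h - 1), h, w)
    sx <- (px - ctr[1] - translation[1])
    sy <- (py - ctr[2] - translation[2])
    ox <- Rin[1, 1] * sx + Rin[1, 2] * sy + ctr[1]
    oy <- Rin[2, 1] * sx + Rin[2, 2] * sy + ctr[2]
    ## reflect out-of-range coordinates back into the raster
    reflect <- function(v, n) {
      v <- abs(v)
      m <- 2 * (n - 1)
      v <- v %% m
      ifelse(v > n - 1, m - v, v)
    }
    ox <- reflect(ox, w); oy <- reflect(oy, h)
    x0 <- pmin(floor(ox), w - 2); y0 <- pmin(floor(oy), h - 2)
    fx <- ox - x0; fy <- oy - y0
    img <- sample$pixels
    idx <- function(yy, xx) img[cbind(as.vector(yy) + 1, as.vector(xx) + 1)]
    vals <- idx(y0, x0) * (1 - fy) * (1 - fx) + idx(y0, x0 + 1) * (1 - fy) * fx +
      idx(y0 + 1, x0) * fy * (1 - fx) + idx(y0 + 1, x0 + 1) * fy * fx
    sample$pixels <- matrix(vals, h, w)
  }
  sample$centers <- {
    m <- fwd(sample$centers); dimnames(m) <- dimnames(sample$centers); m
  }
  sample$landmarks <- lapply(sample$landmarks, function(m) {
    out <- fwd(m); dimnames(out) <- dimnames(m); out
  })
  sample$vertebra_boxes <- lapply(sample$landmarks, function(m) {
    c(x0 = min(m[, 1]), y0 = min(m[, 2]), x1 = max(m[, 1]), y1 = max(m[, 2]))
  })
  sample
}

#' Photometric and geometric jitter
#'
#' Draws brightness, contrast, rotation, scale and translation jitter from
#' `cfg` and applies the pixel transform together with the identical
#' similarity map on all annotations, so image and ground truth stay
#' consistent.
#'
#' @inheritParams random_spine_cutout
#' @return The augmented `annotated_image`.
#' @export
photometric_geometric <- function(sample, cfg = augment_config(), seed = NULL) {
  with_seed(seed, {
    rot <- rnorm(1, 0, cfg$rotation_sd)
    sc <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
    tr <- runif(2, -cfg$translation_range, cfg$translation_range)
    br <- runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
    co <- runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
    out <- similarity_warp(sample, rotation = rot, scale = sc, translation = tr)
    mu <- mean(out$pixels)
    out$pixels <- pmin(pmax((out$pixels - mu) * co + mu + br, 0), 255)
    h <- nrow(out$pixels); w <- ncol(out$pixels)
    pts <- rbind(out$centers, do.call(rbind, out$landmarks))
    if (all(pts[, 1] < 0 | pts[, 1] > w - 1 | pts[, 2] < 0 | pts[, 2] > h - 1)) {
      stop("transform pushed all annotations outside the raster")
    }
    out
  })
}
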