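#' @title Coordinate frames and image preprocessing
#'
#' @description
#' Conventions used throughout the package:
#' * images are numeric matrices `[nrow = height, ncol = width]` with
#'   intensities in `[0, 255]`;
#' * points are `n x 2` matrices with columns `(x, y)` in 0-based
#'   pixel-center coordinates, x rightward, y downward, so pixel `(x, y)`
#'   is `image[y + 1, x + 1]`;
#' * frame transforms are similarity maps `p' = scale * p + offset` with a
#'   uniform scale and no rotation, chained by frame identifiers.
#'
#' The canonical frames are `"original"` (the raw radiograph),
#' `"padded"` (original scaled and zero-padded to the square network
#' input, identical scale factor on both axes), `"input"` (alias of
#' padded, 512 x 512 by default), `"heatmap"` (the 64 x 64 center map
#' grid, exactly 1/8 of the input) and `"crop"` (a per-vertebra 256 x 256
#' window).
#' @name prep
NULL

#' Create a similarity frame transform
#'
#' @param scale positive uniform scale factor.
#' @param offset numeric length-2 `(dx, dy)` translation, applied after
#'   scaling.
#' @param source,target frame identifiers.
#' @return An object of class `frame_transform`.
#' @export
frame_transform <- function(scale, offset = c(0, 0), source = "a", target = "b") {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0,
            length(offset) == 2L)
  structure(list(scale = as.numeric(scale), offset = as.numeric(offset),
                 source = source, target = target),
            class = "frame_transform")
}

#' @export
print.frame_transform <- function(x, ...) {
  cat(sprintf("<frame_transform %s -> %s: p' = %.6g * p + (%.4g, %.4g)>\n",
              x$source, x$target, x$scale, x$offset[1], x$offset[2]))
  invisible(x)
}

#' Invert a frame transform
#'
#' @param tf a [frame_transform()].
#' @return The inverse transform, mapping target frame back to source.
#' @export
ft_invert <- function(tf) {
  frame_transform(1 / tf$scale, -tf$offset / tf$scale,
                  source = tf$target, target = tf$source)
}

#' Compose two frame transforms
#'
#' `ft_compose(a, b)` applies `a` first, then `b`; `b$source` must equal
#' `a$target`.
#' @param a,b [frame_transform()] objects.
#' @return The composed transform `a$source -> b$target`.
#' @export
ft_compose <- function(a, b) {
  if (!identical(a$target, b$source)) {
    stop(sprintf("frame mismatch: cannot chain %s->%s with %s->%s",
                 a$source, a$target, b$source, b$target))
  }
  frame_transform(a$scale * b$scale, b$scale * a$offset + b$offset,
                  source = a$source, target = b$target)
}

#' Map points through a chain of frame transforms
#'
#' @param points `n x 2` matrix of `(x, y)` coordinates (0-based pixel
#'   centers); a length-2 vector is treated as one point.
#' @param chain a single [frame_transform()] or a list of them, applied in
#'   order; consecutive frames must match.
#' @return An `n x 2` matrix of mapped coordinates.
#' @export
map_points <- function(points, chain) {
  if (inherits(chain, "frame_transform")) chain <- list(chain)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  if (nrow(points) == 0L) return(points)
  tf <- Reduce(ft_compose, chain)
  out <- points * tf$scale
  out[, 1] <- out[, 1] + tf$offset[1]
  out[, 2] <- out[, 2] + tf$offset[2]
  dimnames(out) <- dimnames(points)
  out
}

## Bilinear resize with the package's pure-scale convention: the output
## pixel at (x', y') samples the input at (x'/sx, y'/sy), clamped at the
## borders, so that image resampling and point mapping share one transform.
bilinear_resize <- function(image, out_h, out_w) {
  h <- nrow(image); w <- ncol(image)
  sy <- out_h / h; sx <- out_w / w
  ys <- pmin(pmax((seq_len(out_h) - 1) / sy, 0), h - 1)
  xs <- pmin(pmax((seq_len(out_w) - 1) / sx, 0), w - 1)
  y0 <- pmin(floor(ys), h - 2); x0 <- pmin(floor(xs), w - 2)
  if (h == 1L) y0 <- rep(0, out_h)
  if (w == 1L) x0 <- rep(0, out_w)
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  a <- image[y0 + 1, x0 + 1, drop = FALSE]
  b <- image[y0 + 1, x1 + 1, drop = FALSE]
  cc <- image[y1 + 1, x0 + 1, drop = FALSE]
  d <- image[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w)
  wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + cc * wy * (1 - wx) + d * wy * wx
}

#' Resize an image to the square network input with zero padding
#'
#' The content is scaled uniformly by `target / max(h, w)` (preserving the
#' aspect ratio exactly), anchored at the top-left corner, and the right
#' and bottom are zero-padded to `target x target`. The returned transform
#' is a pure scale (zero offset) mapping original to input-frame
#' coordinates.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param target side of the square output, default 512.
#' @return A list with elements `image` (the `target x target` matrix) and
#'   `transform` (a [frame_transform()] `original -> input`).
#' @export
resize_and_pad <- function(image, target = 512L) {
  h <- nrow(image); w <- ncol(image)
  if (is.null(h) || h == 0L || w == 0L) stop("empty image")
  s <- target / max(h, w)
  nh <- round(h * s); nw <- round(w * s)
  content <- if (nh == h && nw == w) image else bilinear_resize(image, nh, nw)
  out <- matrix(0, target, target)
  out[seq_len(nh), seq_len(nw)] <- content
  list(image = out,
       transform = frame_transform(s, c(0, 0), source = "original", target = "input"))
}

#' Gaussian blur and CLAHE contrast enhancement
#'
#' Applies Gaussian blurring followed by contrast limited adaptive
#' histogram equalization, the standard denoise-and-enhance step before
#' heatmap regression on radiographs.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param blur_sigma Gaussian blur standard deviation in pixels (default 1).
#' @param clahe_clip CLAHE clip limit (default 2).
#' @param clahe_tile number of CLAHE tiles per axis (default 8).
#' @return Matrix of the same shape, clipped to `[0, 255]`.
#' @export
enhance <- function(image, blur_sigma = 1, clahe_clip = 2, clahe_tile = 8) {
  stopifnot(blur_sigma > 0, clahe_clip > 0, clahe_tile >= 1)
  x <- image / 255
  x <- EBImage::gblur(x, sigma = blur_sigma)
  x <- pmin(pmax(x, 0), 1)
  x <- EBImage::clahe(x, nx = as.integer(clahe_tile), ny = as.integer(clahe_tile),
                      limit = clahe_clip, keep.range = TRUE)
  x <- as.matrix(x)
  pmin(pmax(x * 255, 0), 255)
}

#' Gaussian blur only
#'
#' @inheritParams enhance
#' @return Blurred matrix, same shape, clipped to `[0, 255]`.
#' @export
blur <- function(image, blur_sigma = 1) {
  x <- EBImage::gblur(image / 255, sigma = blur_sigma)
  pmin(pmax(as.matrix(x) * 255, 0), 255)
}

#' The fixed input-to-heatmap transform
#'
#' The center network consumes a `in_size` square input and emits
#' `in_size / 8` heatmaps; the mapping is an exact scale of 1/8 with no
#' half-pixel offset.
#' @param in_size network input side (default 512).
#' @return A [frame_transform()] `input -> heatmap`.
#' @export
input_to_heatmap <- function(in_size = 512L) {
  frame_transform(1 / 8, c(0, 0), source = "input", target = "heatmap")
}
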