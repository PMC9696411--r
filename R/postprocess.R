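## Global argmax of a matrix, ties broken by row-major (reading-order)
## first occurrence. Returns c(x, y), 0-based.
argmax_px <- function(m) {
  mx <- max(m)
  idx <- which(m == mx, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])  # smallest row, then column
  c(x = unname(idx[ord[1], 2] - 1), y = unname(idx[ord[1], 1] - 1))
}

## Intensity-weighted centroid, the documented fallback for degenerate
## (constant) channels.
centroid_px <- function(m) {
  h <- nrow(m); w <- ncol(m)
  tot <- sum(m)
  if (tot <= 0) return(c(x = (w - 1) / 2, y = (h - 1) / 2))
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  c(x = sum(colSums(m) * xs) / tot, y = sum(rowSums(m) * ys) / tot)
}

#' Per-channel maxima of a confidence-map stack
#'
#' @param stack a [confidence_stack()] or `H x W x K` array.
#' @return `K x 2` matrix of `(x, y)` heatmap coordinates; global argmax
#'   per channel with row-major tie-breaking. A constant channel falls
#'   back to the channel centroid with a warning.
#' @export
extract_maxima <- function(stack) {
  maps <- if (inherits(stack, "confidence_stack")) stack$maps else stack
  maps <- as_cube(maps)
  K <- dim(maps)[3]
  out <- matrix(0, K, 2)
  for (k in seq_len(K)) {
    m <- maps[, , k]
    if (max(m) == min(m)) {
      warning("constant channel ", k, ": falling back to centroid")
      out[k, ] <- centroid_px(m)
    } else {
      out[k, ] <- argmax_px(m)
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Gap-statistic check for a shifted center set
#'
#' Computes the Euclidean gaps `d_i` between consecutive channel maxima
#' and flags the set when the largest gap exceeds 1.4 times the mean of
#' the remaining gaps — the signature of a detection shifted one vertebra
#' up (e.g. T12 detected in the L1 channel).
#'
#' @param maxima `6 x 2` matrix of per-channel maxima, channel order
#'   L1..L5, S1.
#' @param factor flag threshold multiplier (default 1.4).
#' @return List of class `gap_stats`: `maxima`, `d` (5 gaps), `j` (index
#'   of the largest gap), `mean_rest`, `flagged`.
#' @export
gap_check <- function(maxima, factor = 1.4) {
  maxima <- as.matrix(maxima)
  stopifnot(nrow(maxima) == 6L)
  d <- sqrt(rowSums((maxima[-1, , drop = FALSE] -
                       maxima[-6, , drop = FALSE])^2))
  j <- which.max(d)
  mean_rest <- mean(d[-j])
  structure(list(maxima = maxima, d = d, j = j, mean_rest = mean_rest,
                 flagged = max(d) > factor * mean_rest),
            class = "gap_stats")
}

#' @export
print.gap_stats <- function(x, ...) {
  cat(sprintf("<gap_stats flagged=%s j=%d max(d)=%.3f mean_rest=%.3f>\n",
              x$flagged, x$j, max(x$d), x$mean_rest))
  invisible(x)
}

#' Repair a shifted center set from the channel-sum map
#'
#' For a flagged stack: sums all channels, zeroes every pixel row closer
#' than `band_factor * dmax` (in y) to either side of the widest gap
#' (`dmax` is the y-distance between the two maxima bounding that gap),
#' takes the argmax of the masked sum as the recovered center, removes
#' the topmost original maximum, and inserts the recovered point between
#' the gap's endpoints. Only the upward-shift mode (a spurious extra top
#' detection) is repaired; if the surviving band is empty the original
#' maxima are returned with a warning and `attr(, "repaired") = FALSE`.
#'
#' @param stack the 6-channel [confidence_stack()] (or array).
#' @param gap a flagged [gap_check()] result.
#' @param band_factor exclusion band fraction (default 0.4).
#' @return `6 x 2` matrix of repaired centers with attribute `repaired`.
#' @export
repair_centers <- function(stack, gap, band_factor = 0.4) {
  if (!inherits(gap, "gap_stats") || !isTRUE(gap$flagged)) {
    stop("repair_centers requires a flagged gap_check result")
  }
  maps <- if (inherits(stack, "confidence_stack")) stack$maps else stack
  maps <- as_cube(maps)
  maxima <- gap$maxima
  j <- gap$j
  csum <- apply(maps, c(1, 2), sum)
  yj <- maxima[j, 2]; yj1 <- maxima[j + 1, 2]
  dmax <- abs(yj - yj1)
  ys <- 0:(nrow(csum) - 1)
  kill <- ys < yj + band_factor * dmax | ys > yj1 - band_factor * dmax
  csum[kill, ] <- 0
  if (max(csum) <= 0) {
    warning("repair abandoned: masked channel sum is identically zero")
    out <- maxima
    attr(out, "repaired") <- FALSE
    return(out)
  }
  max_new <- argmax_px(csum)
  if (which.min(maxima[, 2]) != 1L) {
    warning("topmost maximum is not in channel 1; repairing the head anyway")
  }
  upper <- if (j >= 2) maxima[2:j, , drop = FALSE] else maxima[0, , drop = FALSE]
  out <- rbind(upper, max_new, maxima[(j + 1):6, , drop = FALSE])
  rownames(out) <- NULL
  colnames(out) <- c("x", "y")
  attr(out, "repaired") <- TRUE
  out
}

#' Square crop side lengths from the six center coordinates
#'
#' Sides are proportional to the local inter-center spacing in y:
#' `1.5 * |y1 - y2|` for L1, `0.75 * (|y_{i-1} - y_i| + |y_i - y_{i+1}|)`
#' for L2-L4, and `1.5 * |y4 - y5|` for both L5 and S1 (the L5-S1 spacing
#' itself is too variable to be a stable scale).
#'
#' @param centers `6 x 2` matrix ordered L1..L5, S1.
#' @return Numeric vector of 6 side lengths (same units as the centers).
#' @export
crop_sizes <- function(centers) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 6L)
  y <- centers[, 2]
  gaps <- abs(diff(y))
  sides <- c(1.5 * gaps[1],
             0.75 * (gaps[1] + gaps[2]),
             0.75 * (gaps[2] + gaps[3]),
             0.75 * (gaps[3] + gaps[4]),
             1.5 * gaps[4],
             1.5 * gaps[4])
  if (any(sides <= 0)) stop("coincident neighbor y-coordinates: zero crop side")
  stats::setNames(sides, vertebra_labels())
}

#' Crop one vertebra window and resize to the landmark-network input
#'
#' Extracts a square window centered on the given point, zero-fills where
#' the window exceeds the raster, resizes to `out_size` and applies a
#' light Gaussian blur. The returned transform maps crop coordinates back
#' to the source frame.
#'
#' @param image source raster (the zero-padded original).
#' @param center `(x, y)` window center in the source frame.
#' @param side window side in source pixels.
#' @param out_size output side (default 256).
#' @param blur_sigma crop blur (default 1; 0 disables).
#' @return List with `crop` (`out_size` square matrix) and `transform`
#'   (a [frame_transform()] `crop -> original`).
#' @export
crop_vertebra <- function(image, center, side, out_size = 256L,
                          blur_sigma = 1) {
  h <- nrow(image); w <- ncol(image)
  center <- as.numeric(center)
  if (side <= 0) stop("crop side must be positive")
  if (center[1] < 0 || center[1] > w - 1 || center[2] < 0 || center[2] > h - 1) {
    stop("crop center outside raster")
  }
  side_px <- max(2L, round(side))
  x0 <- round(center[1] - side_px / 2)
  y0 <- round(center[2] - side_px / 2)
  win <- matrix(0, side_px, side_px)
  xs <- x0:(x0 + side_px - 1); ys <- y0:(y0 + side_px - 1)
  vx <- xs >= 0 & xs <= w - 1; vy <- ys >= 0 & ys <= h - 1
  win[which(vy), which(vx)] <- image[ys[vy] + 1, xs[vx] + 1]
  crop <- bilinear_resize(win, out_size, out_size)
  if (blur_sigma > 0) crop <- blur(crop, blur_sigma)
  list(crop = crop,
       transform = frame_transform(side_px / out_size, c(x0, y0),
                                   source = "crop", target = "original"))
}
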