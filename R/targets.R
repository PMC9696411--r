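#' Construct a confidence-map stack
#'
#' A stack is an `H x W x K` array of per-keypoint maps in `[0, 1]` with
#' ordered channel labels; ground-truth stacks peak at exactly 1 at the
#' annotated pixel.
#'
#' @param maps `H x W x K` array (or `H x W` matrix for K = 1).
#' @param frame frame identifier the maps live in.
#' @param channel_labels ordered channel names.
#' @return Object of class `confidence_stack`.
#' @export
confidence_stack <- function(maps, frame = "heatmap", channel_labels = NULL) {
  if (length(dim(maps)) == 2L) maps <- array(maps, dim = c(dim(maps), 1L))
  stopifnot(length(dim(maps)) == 3L)
  if (is.null(channel_labels)) channel_labels <- as.character(seq_len(dim(maps)[3]))
  structure(list(maps = maps, frame = frame, channel_labels = channel_labels),
            class = "confidence_stack")
}

#' @export
print.confidence_stack <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<confidence_stack %dx%dx%d frame=%s [%s]>\n", d[1], d[2], d[3],
              x$frame, paste(x$channel_labels, collapse = ",")))
  invisible(x)
}

#' Target-map standard deviation rules
#'
#' The spread of the ground-truth Gaussians is tied to the local anatomy:
#' * `"center"`: half the vertical extent of the L5 corner landmarks
#'   (expressed in the frame the maps are built in, i.e. the 64-heatmap
#'   frame for center maps);
#' * `"lumbar"`: 1/10 of the mean length of the two diagonals connecting
#'   the four corner landmarks (crop frame);
#' * `"sacrum"`: 1/6 of the distance between the two S1 landmarks
#'   (crop frame).
#'
#' @param kind one of `"center"`, `"lumbar"`, `"sacrum"`.
#' @param landmarks landmark matrix already mapped into the frame the maps
#'   will be built in: L5's 4 corners for `"center"`, the vertebra's 4
#'   corners for `"lumbar"`, the 2 S1 points for `"sacrum"`.
#' @return Sigma in pixels of that frame.
#' @export
sigma_for <- function(kind = c("center", "lumbar", "sacrum"), landmarks) {
  kind <- match.arg(kind)
  landmarks <- as.matrix(landmarks)
  s <- switch(kind,
    center = {
      stopifnot(nrow(landmarks) == 4L)
      (max(landmarks[, 2]) - min(landmarks[, 2])) / 2
    },
    lumbar = {
      stopifnot(nrow(landmarks) == 4L)
      d1 <- sqrt(sum((landmarks[1, ] - landmarks[4, ])^2))  # Lt-Rb
      d2 <- sqrt(sum((landmarks[2, ] - landmarks[3, ])^2))  # Rt-Lb
      (d1 + d2) / 2 / 10
    },
    sacrum = {
      stopifnot(nrow(landmarks) == 2L)
      sqrt(sum((landmarks[1, ] - landmarks[2, ])^2)) / 6
    })
  if (!is.finite(s) || s <= 0) stop("degenerate geometry: sigma would be ", s)
  s
}

#' Ground-truth Gaussian confidence maps
#'
#' Builds one channel per keypoint with value
#' `exp(-||x - c||^2 / (2 sigma^2))` at every pixel center `x`. The
#' annotated point is snapped to its nearest pixel center before the
#' closed form is evaluated, so each channel's maximum is exactly 1 at the
#' annotated pixel and the map matches the closed form everywhere.
#'
#' @param points `K x 2` matrix of keypoints `(x, y)` in the map frame.
#' @param sigma Gaussian sd in pixels (scalar, or length K).
#' @param shape `c(H, W)` of each map.
#' @param frame,channel_labels passed to [confidence_stack()].
#' @return A [confidence_stack()] of dimension `H x W x K`.
#' @export
gaussian_map <- function(points, sigma, shape, frame = "heatmap",
                         channel_labels = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  K <- nrow(points)
  stopifnot(all(sigma > 0), length(shape) == 2L)
  sigma <- rep_len(sigma, K)
  H <- shape[1]; W <- shape[2]
  if (any(points[, 1] < 0 | points[, 1] > W - 1 |
          points[, 2] < 0 | points[, 2] > H - 1)) {
    stop("point outside raster")
  }
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  maps <- array(0, dim = c(H, W, K))
  for (k in seq_len(K)) {
    cx <- round(points[k, 1]); cy <- round(points[k, 2])
    dx2 <- matrix((xs - cx)^2, H, W, byrow = TRUE)
    dy2 <- matrix((ys - cy)^2, H, W)
    maps[, , k] <- exp(-(dx2 + dy2) / (2 * sigma[k]^2))
  }
  confidence_stack(maps, frame = frame, channel_labels = channel_labels)
}

#' Create an end-plate segment
#' @param p1,p2 the two endpoints `(x, y)`.
#' @param kind `"top"` (Lt-Rt), `"bottom"` (Lb-Rb) or `"sacrum"` (L-R).
#' @return Object of class `plate_segment`.
#' @export
plate_segment <- function(p1, p2, kind = c("top", "bottom", "sacrum")) {
  kind <- match.arg(kind)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (all(p1 == p2)) stop("segment endpoints must be distinct")
  structure(list(p1 = p1, p2 = p2, kind = kind), class = "plate_segment")
}

#' Rasterize part-affinity segments into a scalar indicator field
#'
#' A pixel is set to 1 iff, for some segment, the perpendicular offset of
#' its center from the segment line lies in `[-width/2, width/2)` and its
#' projection onto the line falls within the segment span (endpoints
#' inclusive). Both end plates of a vertebra share this single channel.
#'
#' @param segments list of [plate_segment()] objects (may be empty).
#' @param width band width in pixels (default 4).
#' @param shape `c(H, W)`.
#' @return A list of class `paf_map` with elements `map` (H x W 0/1
#'   matrix) and `width`.
#' @export
paf_map <- function(segments, width = 4, shape) {
  stopifnot(width > 0, length(shape) == 2L)
  H <- shape[1]; W <- shape[2]
  out <- matrix(0, H, W)
  px <- matrix(0:(W - 1), H, W, byrow = TRUE)
  py <- matrix(0:(H - 1), H, W)
  for (s in segments) {
    d <- s$p2 - s$p1
    len <- sqrt(sum(d^2))
    u <- d / len
    rx <- px - s$p1[1]; ry <- py - s$p1[2]
    t <- rx * u[1] + ry * u[2]          # projection along segment
    perp <- rx * (-u[2]) + ry * u[1]    # signed perpendicular offset
    hit <- (t >= 0) & (t <= len) & (perp >= -width / 2) & (perp < width / 2)
    out[hit] <- 1
  }
  structure(list(map = out, width = width), class = "paf_map")
}

#' End-plate segments of an annotated vertebra
#'
#' @param landmarks 4 x 2 lumbar corner matrix (Lt, Rt, Lb, Rb) or 2 x 2
#'   sacrum matrix (L, R).
#' @return List of [plate_segment()]s: two for a lumbar vertebra (top and
#'   bottom plate), one for the sacrum.
#' @export
plate_segments <- function(landmarks) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) == 4L) {
    list(plate_segment(landmarks[1, ], landmarks[2, ], "top"),
         plate_segment(landmarks[3, ], landmarks[4, ], "bottom"))
  } else if (nrow(landmarks) == 2L) {
    list(plate_segment(landmarks[1, ], landmarks[2, ], "sacrum"))
  } else {
    stop("landmarks must have 2 or 4 rows")
  }
}
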