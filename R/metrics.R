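#' Relative distance error for a lumbar landmark
#'
#' The x and y errors are normalized by the lengths of the ground-truth
#' edges incident to the landmark — `h` the end-plate edge (Lt-Rt or
#' Lb-Rb), `v` the side edge (Lt-Lb or Rt-Rb) — giving an error in
#' percent of the local vertebra size:
#' `100 * sqrt(((pred_x - gt_x)/h)^2 + ((pred_y - gt_y)/v)^2)`.
#'
#' @param pred,gt predicted and ground-truth points `(x, y)`.
#' @param h,v normalizing edge lengths in pixels (> 0).
#' @return Error in percent.
#' @export
rd_lumbar <- function(pred, gt, h, v) {
  stopifnot(h > 0, v > 0)
  pred <- as.numeric(pred); gt <- as.numeric(gt)
  100 * sqrt(((pred[1] - gt[1]) / h)^2 + ((pred[2] - gt[2]) / v)^2)
}

#' Relative distance error for a sacrum landmark
#'
#' `100 * ||pred - gt||_2 / l`, with `l` the length of the sacrum upper
#' end plate (the distance between its two ground-truth landmarks).
#'
#' @param pred,gt predicted and ground-truth points `(x, y)`.
#' @param l sacrum length in pixels (> 0).
#' @return Error in percent.
#' @export
rd_sacrum <- function(pred, gt, l) {
  stopifnot(l > 0)
  pred <- as.numeric(pred); gt <- as.numeric(gt)
  100 * sqrt(sum((pred - gt)^2)) / l
}

## Normalizing edge lengths (h, v) for lumbar corner k (1=Lt,2=Rt,3=Lb,4=Rb)
## from the vertebra's 4 ground-truth corners.
lumbar_hv <- function(gt_corners, k) {
  e <- function(a, b) sqrt(sum((gt_corners[a, ] - gt_corners[b, ])^2))
  h <- if (k %in% c(1, 2)) e(1, 2) else e(3, 4)
  v <- if (k %in% c(1, 3)) e(1, 3) else e(2, 4)
  c(h = h, v = v)
}

#' Center-detection report
#'
#' Per-vertebra mean (sd) pixel distance between predicted and
#' ground-truth centers, reported separately for inlier images and all
#' images. An image is an outlier when the square crops built from its
#' predicted centers (sides from [crop_sizes()]) exclude at least one of
#' that vertebra's ground-truth landmarks — i.e. the second stage could
#' not have seen the landmark, regardless of the distance error.
#'
#' @param preds list of `6 x 2` predicted center matrices in the original
#'   frame, one per image.
#' @param samples matching list of `annotated_image` objects.
#' @param in_size network input side; distances are reported at this
#'   scale (each image's errors are multiplied by its original-to-input
#'   scale factor).
#' @return List with `per_vertebra` (data.frame: vertebra, mean/sd for
#'   inliers and for all), `outlier_ratio` (percent), `outliers` (logical
#'   per image), `distances` (images x 6 matrix, input scale).
#' @export
center_report <- function(preds, samples, in_size = 512L) {
  stopifnot(length(preds) == length(samples))
  n <- length(preds)
  if (n == 0L) stop("empty input")
  labs <- vertebra_labels()
  dist <- matrix(NA_real_, n, 6, dimnames = list(NULL, labs))
  outlier <- logical(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    pc <- as.matrix(preds[[i]])
    scale <- in_size / max(dim(s$pixels))
    dist[i, ] <- sqrt(rowSums((pc - s$centers)^2)) * scale
    ## degenerate predicted geometry: the crops are undefined, so the
    ## image cannot supply every landmark to the second stage
    sides <- tryCatch(crop_sizes(pc), error = function(e) NULL)
    if (is.null(sides)) {
      outlier[i] <- TRUE
      next
    }
    for (k in seq_len(6)) {
      half <- round(sides[k]) / 2
      lm <- s$landmarks[[labs[k]]]
      inside <- lm[, 1] >= pc[k, 1] - half & lm[, 1] <= pc[k, 1] + half &
        lm[, 2] >= pc[k, 2] - half & lm[, 2] <= pc[k, 2] + half
      if (!all(inside)) outlier[i] <- TRUE
    }
  }
  agg <- function(rows) {
    if (!any(rows)) return(data.frame(mean = rep(NA_real_, 6), sd = NA_real_))
    m <- dist[rows, , drop = FALSE]
    data.frame(mean = colMeans(m), sd = apply(m, 2, stats::sd))
  }
  inl <- agg(!outlier); all_ <- agg(rep(TRUE, n))
  per <- data.frame(vertebra = labs,
                    inlier_mean = inl$mean, inlier_sd = inl$sd,
                    all_mean = all_$mean, all_sd = all_$sd,
                    row.names = NULL)
  list(per_vertebra = per,
       outlier_ratio = 100 * mean(outlier),
       outliers = outlier, distances = dist)
}

#' Landmark-detection report
#'
#' Pixel distance (D) and relative distance (RD, percent) per landmark;
#' a vertebra is an outlier when the mean RD of its landmarks exceeds 20.
#' The reported `accuracy` is `100 - outlier ratio` over all scored
#' vertebrae.
#'
#' @param preds list (one per image) of named lists of predicted landmark
#'   matrices (`L1`..`L5` 4 x 2, `S1` 2 x 2) in the original frame;
#'   vertebrae may be missing (skipped).
#' @param samples matching list of `annotated_image` objects.
#' @param outlier_rd per-vertebra mean-RD outlier threshold (default 20).
#' @return List with `per_landmark` (long data.frame), `per_vertebra`
#'   (mean/sd of D and RD and outlier percentage per label), `total_rd`,
#'   `total_d`, `outlier_ratio` (percent of vertebra instances), and
#'   `accuracy`.
#' @export
landmark_report <- function(preds, samples, outlier_rd = 20) {
  stopifnot(length(preds) == length(samples))
  if (length(preds) == 0L) stop("empty input")
  rows <- list()
  for (i in seq_along(preds)) {
    s <- samples[[i]]
    for (lab in names(preds[[i]])) {
      pm <- as.matrix(preds[[i]][[lab]])
      gm <- s$landmarks[[lab]]
      if (is.null(gm)) next
      for (k in seq_len(nrow(gm))) {
        d <- sqrt(sum((pm[k, ] - gm[k, ])^2))
        rd <- if (lab == "S1") {
          l <- sqrt(sum((gm[1, ] - gm[2, ])^2))
          rd_sacrum(pm[k, ], gm[k, ], l)
        } else {
          hv <- lumbar_hv(gm, k)
          rd_lumbar(pm[k, ], gm[k, ], hv["h"], hv["v"])
        }
        rows[[length(rows) + 1L]] <-
          data.frame(image = i, vertebra = lab, landmark = k, d = d, rd = rd)
      }
    }
  }
  per_lm <- do.call(rbind, rows)
  if (is.null(per_lm)) stop("no matching vertebrae between preds and samples")
  key <- interaction(per_lm$image, per_lm$vertebra, drop = TRUE)
  vert_rd <- tapply(per_lm$rd, key, mean)
  vert_lab <- tapply(as.character(per_lm$vertebra), key, `[`, 1)
  vert_out <- vert_rd > outlier_rd
  per_vert <- do.call(rbind, lapply(unique(per_lm$vertebra), function(lab) {
    sel <- per_lm$vertebra == lab
    vs <- vert_lab == lab
    data.frame(vertebra = lab,
               d_mean = mean(per_lm$d[sel]), d_sd = stats::sd(per_lm$d[sel]),
               rd_mean = mean(per_lm$rd[sel]), rd_sd = stats::sd(per_lm$rd[sel]),
               outlier_pct = 100 * mean(vert_out[vs]))
  }))
  list(per_landmark = per_lm, per_vertebra = per_vert,
       total_rd = mean(per_lm$rd), total_d = mean(per_lm$d),
       outlier_ratio = 100 * mean(vert_out),
       accuracy = 100 - 100 * mean(vert_out))
}
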