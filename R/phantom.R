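#' Specification of a synthetic lateral lumbar spine phantom
#'
#' The phantom emulates the statistical structure the detector relies on:
#' six stacked bright quadrilateral vertebral bodies (L1-L5 plus the S1
#' upper end plate rendered as a tilted wedge) on a darker soft-tissue
#' background, roughly vertical center stacking with inter-center spacing
#' near 1/9 of the image height, per-vertebra interior mean intensities
#' following the caudally increasing brightness observed on lateral
#' radiographs, Gaussian pixel noise, and an optional darkening band
#' emulating rib/diaphragm occlusion of the upper vertebrae.
#'
#' @param image_height,image_width raster size in pixels (default 640 x 512,
#'   deliberately non-square so the pad/resize path is exercised).
#' @param spacing_mean,spacing_sd inter-center spacing mean and jitter sd
#'   (px). The default mean is `image_height / 9`.
#' @param width_mean,width_sd,height_mean,height_sd lumbar vertebral body
#'   width/height mean and jitter sd (px).
#' @param interior_means 6 interior mean intensities in `[0, 255]`,
#'   ordered L1..L5, S1.
#' @param background_mean background intensity.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param occlusion_prob probability in `[0, 1]` that an image receives an
#'   occlusion band.
#' @param occlusion_strength multiplicative darkening of the band (0-1).
#' @param tilt_sd per-vertebra tilt jitter sd in degrees.
#' @param corner_jitter_sd independent corner jitter sd (px).
#' @param s1_tilt mean tilt of the S1 upper end plate in degrees.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height = 640L, image_width = 512L,
                         spacing_mean = image_height / 9, spacing_sd = 3,
                         width_mean = 64, width_sd = 3,
                         height_mean = 44, height_sd = 3,
                         interior_means = c(137.11, 132.20, 130.83,
                                            140.09, 163.02, 168),
                         background_mean = 80, noise_sd = 8,
                         occlusion_prob = 0.35, occlusion_strength = 0.45,
                         tilt_sd = 3, corner_jitter_sd = 1,
                         s1_tilt = 25) {
  stopifnot(spacing_mean > 0, length(interior_means) == 6L,
            all(interior_means >= 0 & interior_means <= 255),
            background_mean >= 0, background_mean <= 255,
            occlusion_prob >= 0, occlusion_prob <= 1,
            noise_sd >= 0, spacing_sd >= 0, tilt_sd >= 0)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_vertebrae = 6L,
                 spacing_mean = spacing_mean, spacing_sd = spacing_sd,
                 width_mean = width_mean, width_sd = width_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 interior_means = interior_means,
                 background_mean = background_mean, noise_sd = noise_sd,
                 occlusion_prob = occlusion_prob,
                 occlusion_strength = occlusion_strength,
                 tilt_sd = tilt_sd, corner_jitter_sd = corner_jitter_sd,
                 s1_tilt = s1_tilt),
            class = "phantom_spec")
}

vertebra_labels <- function() c("L1", "L2", "L3", "L4", "L5", "S1")

## Run expr with a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

## Fill a convex polygon (vertices nx2, (x,y), 0-based pixel centers) with a
## constant value. Pixels whose centers lie inside or on the boundary are set.
fill_polygon <- function(image, poly, value) {
  h <- nrow(image); w <- ncol(image)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- max(0, floor(xr[1])):min(w - 1, ceiling(xr[2]))
  ys <- max(0, floor(yr[1])):min(h - 1, ceiling(yr[2]))
  if (length(xs) == 0L || length(ys) == 0L) return(image)
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- rep(TRUE, length(px))
  n <- nrow(poly)
  ## half-plane test with the polygon's own orientation (shoelace sign)
  nx <- poly[c(2:n, 1), 1]; ny <- poly[c(2:n, 1), 2]
  sgn <- sign(sum(poly[, 1] * ny - nx * poly[, 2]))
  if (sgn == 0) sgn <- 1
  for (k in seq_len(n)) {
    a <- poly[k, ]; b <- poly[k %% n + 1, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & (sgn * cr >= -1e-9)
  }
  image[cbind(py[inside] + 1, px[inside] + 1)] <- value
  image
}

#' Generate one synthetic lumbar spine phantom
#'
#' Deterministic for a fixed `(spec, seed)` pair. Returns the raster plus
#' exact ground truth: 6 ordered centers (L1..L5, S1, strictly increasing
#' y), 4 corner landmarks per lumbar vertebra in the order (Lt, Rt, Lb,
#' Rb), the 2 endpoints (L, R) of the S1 upper end plate, and per-vertebra
#' axis-aligned boxes used by augmentation.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @return An object of class `annotated_image`: a list with `pixels`,
#'   `frame` (`"original"`), `centers` (6 x 2), `landmarks` (named list),
#'   `vertebra_boxes` (named list of `c(x0, y0, x1, y1)`), and `occluded`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_height; W <- spec$image_width
  need_h <- 5 * spec$spacing_mean + 2.5 * spec$height_mean
  if (H < need_h || W < 2 * spec$width_mean) {
    stop("raster too small to hold 6 vertebrae at the requested spacing")
  }
  with_seed(seed, {
    labs <- vertebra_labels()
    spacing <- rnorm(5, spec$spacing_mean, spec$spacing_sd)
    y0 <- (H - sum(spacing)) / 2
    cy <- y0 + c(0, cumsum(spacing))
    cx <- W / 2 + rnorm(6, 0, spec$spacing_sd)
    widths <- rnorm(5, spec$width_mean, spec$width_sd)
    heights <- rnorm(5, spec$height_mean, spec$height_sd)
    tilts <- rnorm(6, 0, spec$tilt_sd)

    polys <- vector("list", 6)
    landmarks <- vector("list", 6)
    names(polys) <- names(landmarks) <- labs
    for (i in 1:5) {
      w2 <- widths[i] / 2; h2 <- heights[i] / 2
      base <- rbind(c(-w2, -h2), c(w2, -h2), c(-w2, h2), c(w2, h2))
      jit <- matrix(rnorm(8, 0, spec$corner_jitter_sd), 4, 2)
      corners <- (base + jit) %*% t(rot2(tilts[i]))
      corners[, 1] <- corners[, 1] + cx[i]
      corners[, 2] <- corners[, 2] + cy[i]
      landmarks[[i]] <- corners            # (Lt, Rt, Lb, Rb)
      polys[[i]] <- corners[c(1, 2, 4, 3), ]  # boundary order
    }
    ## S1: wedge whose annotated points are the upper end plate endpoints
    s1w <- 0.95 * spec$width_mean
    s1h <- 1.2 * spec$height_mean
    th <- spec$s1_tilt + tilts[6]
    R <- rot2(th)
    up <- rbind(c(-s1w / 2, 0), c(s1w / 2, 0)) %*% t(R)
    lo <- rbind(c(-0.55 * s1w / 2, s1h), c(0.55 * s1w / 2, s1h)) %*% t(R)
    ## anchor so the wedge's corner centroid is exactly the S1 center
    anchor <- c(cx[6], cy[6]) - colMeans(rbind(up, lo))
    up <- sweep(up, 2, anchor, "+"); lo <- sweep(lo, 2, anchor, "+")
    s1poly <- rbind(up[1, ], up[2, ], lo[2, ], lo[1, ])
    polys[["S1"]] <- s1poly
    landmarks[["S1"]] <- up
    centers <- t(vapply(polys, colMeans, numeric(2)))

    img <- matrix(spec$background_mean, H, W)
    for (i in 1:6) img <- fill_polygon(img, polys[[i]], spec$interior_means[i])

    occluded <- runif(1) < spec$occlusion_prob
    if (occluded) {
      boxes_y <- vapply(polys[1:4], function(p) range(p[, 2]), numeric(2))
      a <- sample.int(4, 1)
      b <- a + sample.int(4 - a + 1, 1) - 1L
      r0 <- max(0, floor(boxes_y[1, a] - 4))
      r1 <- min(H - 1, ceiling(boxes_y[2, b] + 4))
      img[(r0 + 1):(r1 + 1), ] <- img[(r0 + 1):(r1 + 1), ] *
        (1 - spec$occlusion_strength)
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
    }
    img <- pmin(pmax(img, 0), 255)

    boxes <- lapply(polys, function(p) {
      c(x0 = min(p[, 1]), y0 = min(p[, 2]), x1 = max(p[, 1]), y1 = max(p[, 2]))
    })
    ann <- lapply(landmarks, function(m) {
      dimnames(m) <- list(NULL, c("x", "y")); m
    })
    dimnames(centers) <- list(labs, c("x", "y"))
    pts <- rbind(centers, do.call(rbind, ann))
    if (any(pts[, 1] < 0 | pts[, 1] > W - 1 | pts[, 2] < 0 | pts[, 2] > H - 1)) {
      stop("raster too small: annotated points fall outside the image")
    }
    structure(list(pixels = img, frame = "original", centers = centers,
                   landmarks = ann, vertebra_boxes = boxes,
                   occluded = occluded, spec = spec, seed = seed),
              class = "annotated_image")
  })
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image %dx%d frame=%s occluded=%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$frame, x$occluded))
  invisible(x)
}

annotation_to_list <- function(sample, image_file = "") {
  list(image = image_file, frame = sample$frame,
       centers = unname(lapply(seq_len(nrow(sample$centers)),
                               function(i) unname(sample$centers[i, ]))),
       landmarks = lapply(sample$landmarks, function(m) {
         unname(lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
       }))
}

annotation_from_list <- function(x) {
  centers <- do.call(rbind, lapply(x$centers, unlist))
  dimnames(centers) <- list(vertebra_labels(), c("x", "y"))
  landmarks <- lapply(x$landmarks, function(m) {
    out <- do.call(rbind, lapply(m, unlist))
    dimnames(out) <- list(NULL, c("x", "y"))
    out
  })
  list(image = x$image, frame = x$frame, centers = centers,
       landmarks = landmarks)
}

#' Write an annotation to JSON
#'
#' Schema: `{"image": str, "frame": "original", "centers": [[x,y] x 6],
#' "landmarks": {"L1": [[x,y] x 4], ..., "S1": [[x,y] x 2]}}`, coordinates
#' 0-based pixel-center floats.
#' @param sample an `annotated_image` (or compatible list).
#' @param path output file.
#' @param image_file value for the `image` field.
#' @export
write_annotation <- function(sample, path, image_file = "") {
  jsonlite::write_json(annotation_to_list(sample, image_file), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotation JSON
#' @param path annotation file written by [write_annotation()].
#' @return A list with `image`, `frame`, `centers` (6 x 2 matrix) and
#'   `landmarks` (named list of matrices).
#' @export
read_annotation <- function(path) {
  annotation_from_list(jsonlite::read_json(path))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` 8-bit grayscale PNGs, one annotation JSON per image, and a
#' `manifest.json` listing every pair with its occlusion flag.
#'
#' @param spec a [phantom_spec()].
#' @param n number of images (>= 1).
#' @param seed base seed; image `i` uses `seed + i - 1`.
#' @param out_dir output directory (created if missing).
#' @return The manifest as a data.frame (invisibly also written to disk).
#' @export
generate_dataset <- function(spec, n, seed, out_dir) {
  stopifnot(n >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("unwritable directory: ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_phantom(spec, seed = seed + i - 1L)
    img_file <- sprintf("phantom_%04d.png", i)
    ann_file <- sprintf("phantom_%04d.json", i)
    png::writePNG(round(s$pixels) / 255, file.path(out_dir, img_file))
    write_annotation(s, file.path(out_dir, ann_file), image_file = img_file)
    rows[[i]] <- data.frame(image = img_file, annotation = ann_file,
                            seed = seed + i - 1L, occluded = s$occluded)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read a grayscale image (PNG or TIFF) as a `[0, 255]` matrix
#' @param path image file.
#' @return Numeric matrix `[height, width]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package required")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x * 255
}
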