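sm <- asNamespace("spinemark")

test_that("coordinate channels span (-1, 1) exactly", {
  cc <- coord_channels(3, 3)
  expect_equal(cc[2, 2, ], c(0, 0))                  # center pixel
  expect_equal(cc[1, 1, ], c(-1, -1))                # top-left
  expect_equal(cc[3, 3, ], c(1, 1))                  # bottom-right
  big <- coord_channels(256, 256)
  expect_equal(big[1, 2, 1] - big[1, 1, 1], 2 / 255) # column step
  expect_equal(big[2, 1, 2] - big[1, 1, 2], 2 / 255) # row step
  expect_error(coord_channels(1, 5))
})

test_that("lumbar and sacrum heads differ only in channel count", {
  lum <- build_landmarknet(landmarknet_config("lumbar", base_channels = 2),
                           seed = 1)
  sac <- build_landmarknet(landmarknet_config("sacrum", base_channels = 2),
                           seed = 1)
  x <- matrix(runif(256 * 256, 0, 255), 256, 256)
  fl <- sm$landmarknet_forward(lum, x)
  fs <- sm$landmarknet_forward(sac, x)
  expect_equal(dim(fl$cm), c(256, 256, 4))
  expect_equal(dim(fs$cm), c(256, 256, 2))
  expect_equal(dim(fl$paf), c(256, 256))
  expect_true(all(is.finite(fl$cm)) && all(is.finite(fs$cm)))
  ## one shared trunk: affinity prediction costs one extra head channel
  expect_equal(ncol(lum$params$head$W), 5)
  expect_equal(ncol(sac$params$head$W), 3)
  for (blk in setdiff(names(lum$params), "head")) {
    expect_equal(dim(lum$params[[blk]]$W), dim(sac$params[[blk]]$W))
  }
})

test_that("without coordinate channels the network is shift-equivariant, with them it is not", {
  mk_input <- function(shift) {
    x <- matrix(0, 256, 256)
    ys <- 109:148; xs <- 109:148
    blob <- outer(seq_along(ys), seq_along(xs), function(i, j) {
      200 * exp(-((i - 20)^2 + (j - 20)^2) / 60)
    })
    x[ys + shift, xs + shift] <- blob
    x
  }
  x0 <- mk_input(0); x1 <- mk_input(32)
  inner <- 97:160  # region far from borders at every scale

  plain <- build_landmarknet(
    landmarknet_config("lumbar", base_channels = 2, coordconv_stages = 0),
    seed = 11)
  ## the head initializes at zero; give it random weights so the probe
  ## sees a non-degenerate output
  set.seed(12); plain$params$head$W[] <- rnorm(length(plain$params$head$W), 0, 0.2)
  y0 <- sm$landmarknet_forward(plain, x0)$cm
  y1 <- sm$landmarknet_forward(plain, x1)$cm
  diff_plain <- max(abs(y1[inner + 32, inner + 32, ] - y0[inner, inner, ]))
  expect_lt(diff_plain, 1e-4)

  cc <- build_landmarknet(
    landmarknet_config("lumbar", base_channels = 2, coordconv_stages = 2),
    seed = 11)
  set.seed(12); cc$params$head$W[] <- rnorm(length(cc$params$head$W), 0, 0.2)
  z0 <- sm$landmarknet_forward(cc, x0)$cm
  z1 <- sm$landmarknet_forward(cc, x1)$cm
  diff_cc <- max(abs(z1[inner + 32, inner + 32, ] - z0[inner, inner, ]))
  expect_gt(diff_cc, 1e-3)
})

test_that("the landmark loss matches a brute-force oracle and the stated weights", {
  set.seed(61)
  lcfg <- landmarknet_config("lumbar")
  scfg <- landmarknet_config("sacrum")
  gt_cm <- array(runif(16 * 16 * 4), c(16, 16, 4))
  gt_paf <- matrix(rbinom(256, 1, 0.2), 16, 16)
  pr_cm <- array(runif(16 * 16 * 4), c(16, 16, 4))
  pr_paf <- matrix(runif(256), 16, 16)

  acc <- 0
  for (k in 1:4) for (i in 1:16) for (j in 1:16) {
    acc <- acc + (gt_cm[i, j, k] - pr_cm[i, j, k])^2
  }
  pafe <- 0
  for (i in 1:16) for (j in 1:16) pafe <- pafe + (gt_paf[i, j] - pr_paf[i, j])^2
  expect_equal(landmark_loss(pr_cm, pr_paf, gt_cm, gt_paf, lcfg),
               acc / 4 + 0.001 * pafe, tolerance = 1e-6)

  ## exact prediction is zero; an affinity-only error is weighted alpha/beta
  expect_equal(landmark_loss(gt_cm, gt_paf, gt_cm, gt_paf, lcfg), 0)
  E <- sum((gt_paf - pr_paf)^2)
  expect_equal(landmark_loss(gt_cm, pr_paf, gt_cm, gt_paf, lcfg), 0.001 * E)
  gt2 <- gt_cm[, , 1:2, drop = FALSE]
  expect_equal(landmark_loss(gt2, pr_paf, gt2, gt_paf, scfg), 0.01 * E)
  expect_error(landmark_loss(pr_cm, pr_paf, gt_cm, gt_paf, scfg))
})

test_that("landmarknet gradients match finite differences", {
  lcfg <- landmarknet_config("lumbar", base_channels = 2, in_size = 32)
  m <- build_landmarknet(lcfg, seed = 3)
  set.seed(62)
  m$params$head$W[] <- rnorm(length(m$params$head$W), 0, 0.1)
  x <- matrix(runif(32 * 32, 0, 255), 32, 32)
  gcm <- array(runif(32 * 32 * 4), c(32, 32, 4))
  gp <- matrix(runif(32 * 32), 32, 32)
  fw <- sm$landmarknet_forward(m, x, keep_cache = TRUE)
  g <- sm$landmark_loss_grads(fw$cm, fw$paf, gcm, gp, lcfg)
  grads <- sm$landmarknet_backward(m, fw$cache, g$dcm, g$dpaf)
  lossf <- function(params) {
    f <- sm$landmarknet_forward(list(cfg = lcfg, params = params), x)
    landmark_loss(f$cm, f$paf, gcm, gp, lcfg)
  }
  for (blk in c("enc1", "enc2", "bott", "dec2", "dec4", "head")) {
    idx <- sample(length(m$params[[blk]]$W), 3)
    ng <- vapply(idx, function(i) {
      p1 <- m$params; p1[[blk]]$W[i] <- p1[[blk]]$W[i] + 1e-5
      p2 <- m$params; p2[[blk]]$W[i] <- p2[[blk]]$W[i] - 1e-5
      (lossf(p1) - lossf(p2)) / 2e-5
    }, 0)
    expect_lt(max(abs(ng - grads[[blk]]$W[idx])), 1e-4)
  }
})

test_that("landmark decoding maps ground-truth stacks back within 0.51 px", {
  s <- generate_phantom(clean_spec(), 6)
  sides <- crop_sizes(s$centers)
  cr <- crop_vertebra(s$pixels, s$centers["L3", ], sides[["L3"]])
  lm_crop <- map_points(s$landmarks$L3, ft_invert(cr$transform))
  gt <- gaussian_map(lm_crop, sigma_for("lumbar", lm_crop), c(256, 256))
  dec <- decode_landmarks(gt, cr$transform)
  err <- sqrt(rowSums((dec - s$landmarks$L3)^2))
  expect_true(all(err < 0.51))

  ## without a transform the decode stays in crop coordinates
  dec_crop <- decode_landmarks(gt)
  expect_equal(unname(dec_crop), unname(round(lm_crop)))

  ## constant channel falls back to the centroid with a warning
  flat <- array(0.2, c(64, 64, 2))
  expect_warning(expect_warning(d <- decode_landmarks(flat), "centroid"))
  expect_equal(unname(d[1, ]), c(31.5, 31.5))

  ## transform arithmetic: crop argmax (128, 128), side 128 -> half-window
  ## offset from the window origin
  tf <- frame_transform(0.5, c(100, 200), "crop", "original")
  one <- gaussian_map(c(128, 128), 3, c(256, 256))
  expect_equal(unname(decode_landmarks(one, tf)[1, ]), c(164, 264))
})

test_that("ground-truth-centered crops train a tiny landmark detector", {
  lcfg <- landmarknet_config("lumbar", base_channels = 2, in_size = 64)
  samples <- lapply(1:6, function(i) generate_phantom(easy_spec(), i))
  ds <- make_landmark_dataset(samples, "lumbar", lcfg)
  expect_equal(length(ds), 30)  # 5 lumbar crops per phantom
  expect_equal(dim(ds[[1]]$x), c(64, 64))
  expect_equal(dim(ds[[1]]$gt_cm), c(64, 64, 4))
  expect_true(all(ds[[1]]$gt_paf %in% c(0, 1)))

  fit <- train_landmarknet(ds, lcfg,
                           train_config(lr = 2e-3, batch = 5, max_epochs = 3,
                                        patience = 2, seed = 1),
                           val_fraction = 0.2)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])

  ## sacrum dataset from the same samples
  scfg <- landmarknet_config("sacrum", base_channels = 2, in_size = 64)
  dss <- make_landmark_dataset(samples, "sacrum", scfg)
  expect_equal(length(dss), 6)
  expect_equal(dim(dss[[1]]$gt_cm)[3], 2)
  expect_error(train_landmarknet(list(), lcfg), "empty")
})
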