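test_that("per-channel maxima decode ground-truth stacks exactly", {
  centers <- cbind(x = c(25, 26, 26, 25, 26, 27),
                   y = c(14, 21, 28, 35, 43, 50))
  st <- stack_at(centers)
  expect_equal(unname(extract_maxima(st)), unname(centers))

  ## row-major tie-break: two equal maxima, first in reading order wins
  m <- matrix(0, 8, 8)
  m[3, 6] <- 1  # (x=5, y=2)
  m[5, 2] <- 1  # (x=1, y=4)
  mx <- extract_maxima(array(m, c(8, 8, 1)))
  expect_equal(unname(mx[1, ]), c(5, 2))

  ## constant channel: centroid fallback with warning
  expect_warning(mx2 <- extract_maxima(array(0.5, c(9, 9, 1))), "centroid")
  expect_equal(unname(mx2[1, ]), c(4, 4))
})

test_that("the gap statistic flags exactly the 1.4-rule violations", {
  mk <- function(ys) cbind(x = 32, y = ys)
  g <- gap_check(mk(c(10, 18, 26, 34, 42, 50)))   # d = 8,8,8,8,8
  expect_false(g$flagged)
  expect_equal(g$d, rep(8, 5))

  g2 <- gap_check(mk(c(10, 18, 26, 34, 50, 58)))  # d = 8,8,8,16,8
  expect_true(g2$flagged)
  expect_equal(g2$j, 4)
  expect_equal(g2$mean_rest, 8)
  expect_gt(max(g2$d), 1.4 * g2$mean_rest)        # 16 > 11.2

  g3 <- gap_check(matrix(5, 6, 2))                # all coincident, d = 0
  expect_false(g3$flagged)                        # 0 > 0 is false
})

test_that("center repair recovers the planted center on the worked stack", {
  ys <- c(10, 18, 26, 34, 50, 58)
  st <- stack_at(cbind(x = 32, y = ys))
  ## weak (0.5) response at the missing center (32, 42) in channel 4
  blob <- gaussian_map(c(32, 42), 1.5, c(64, 64))$maps[, , 1]
  st$maps[, , 4] <- pmin(1, st$maps[, , 4] + 0.5 * blob)
  gap <- gap_check(extract_maxima(st))
  expect_true(gap$flagged)
  expect_equal(gap$j, 4)
  fixed <- repair_centers(st, gap)
  expect_true(attr(fixed, "repaired"))
  expect_equal(unname(fixed[, 2]), c(18, 26, 34, 42, 50, 58))
  expect_equal(unname(fixed[, 1]), rep(32, 6))

  ## surviving band rows: dmax = 16, exclusion 6.4 each side -> rows 41-43
  ylo <- 34 + 0.4 * 16; yhi <- 50 - 0.4 * 16
  expect_equal(setdiff(0:63, which(0:63 < ylo | 0:63 > yhi) - 1), 41:43)

  ## unflagged input violates the precondition
  clean <- stack_at(cbind(x = 32, y = c(10, 18, 26, 34, 42, 50)))
  expect_error(repair_centers(clean, gap_check(extract_maxima(clean))),
               "flagged")
})

test_that("repair abandons gracefully when the masked band is empty", {
  ## compact blobs (no Gaussian tails) so the masked channel sum can be 0
  maps <- array(0, c(64, 64, 6))
  ys <- c(10, 18, 26, 34, 50, 58)
  for (k in 1:6) maps[ys[k] + 1, 33, k] <- 1
  gap <- gap_check(extract_maxima(maps))
  expect_true(gap$flagged)
  expect_warning(out <- repair_centers(maps, gap), "abandoned")
  expect_false(attr(out, "repaired"))
  expect_equal(unname(out[, 2]), ys)
})

test_that("clean uniformly spaced stacks pass through the repair stage untouched", {
  set.seed(31)
  for (i in 1:20) {
    s <- runif(1, 7, 9)
    y0 <- runif(1, 8, 12)
    centers <- cbind(x = round(runif(6, 30, 33)),
                     y = round(y0 + s * (0:5)))
    st <- stack_at(centers, sigma = runif(1, 1.2, 2.5))
    mx <- extract_maxima(st)
    expect_equal(unname(mx), unname(centers))
    expect_false(gap_check(mx)$flagged)
  }
})

test_that("crop sides follow the spacing rule and its symmetries", {
  y <- c(100, 164, 232, 304, 380, 470)
  sides <- crop_sizes(cbind(x = 250, y = y))
  expect_equal(unname(sides), c(96, 99, 105, 111, 114, 114))
  ## the sacrum side equals the L4-L5-derived value
  expect_equal(sides[["S1"]], 1.5 * (380 - 304))

  ## uniform spacing s gives 1.5 s everywhere
  u <- crop_sizes(cbind(x = 0, y = 100 + 64 * (0:5)))
  expect_equal(unname(u), rep(96, 6))

  ## homogeneity and x-invariance
  expect_equal(crop_sizes(cbind(x = 9, y = 2.5 * y)), 2.5 * sides)
  expect_equal(crop_sizes(cbind(x = runif(6), y = y)), sides)
  expect_error(crop_sizes(cbind(x = 0, y = c(1, 1, 2, 3, 4, 5))), "zero")
})

test_that("vertebra crops round-trip landmarks within half an original pixel", {
  img <- matrix(runif(640 * 512, 0, 255), 640, 512)
  cr <- crop_vertebra(img, c(250, 300), 107.3, blur_sigma = 0)
  expect_equal(dim(cr$crop), c(256, 256))
  pt <- c(265.7, 312.2)
  in_crop <- map_points(pt, ft_invert(cr$transform))
  ## decoding at integer crop pixels loses at most 0.5 crop px = ~0.21 orig px
  back <- map_points(round(in_crop), cr$transform)
  expect_lt(sqrt(sum((back - pt)^2)), 0.51)

  ## window fully inside the raster introduces no zero-fill
  cr2 <- crop_vertebra(img, c(250, 300), 100, blur_sigma = 0)
  expect_true(all(cr2$crop > 0))
  ## side 128 gives an exact crop->original scale of 0.5
  cr3 <- crop_vertebra(img, c(250, 300), 128, blur_sigma = 0)
  expect_equal(cr3$transform$scale, 0.5)
  ## zero-fill appears when the window exceeds the raster
  cr4 <- crop_vertebra(img, c(5, 5), 64, blur_sigma = 0)
  expect_true(any(cr4$crop == 0))
  expect_error(crop_vertebra(img, c(-10, 5), 64), "outside")
})
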