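test_that("random spine cutout masks exactly the configured fraction inside the box", {
  s <- boxed_sample(box_w = 80, box_h = 50)
  cfg <- augment_config(rsc_ratio = 0.6)
  out <- random_spine_cutout(s, cfg, seed = 1)
  r <- out$rsc$rect
  expect_equal(unname(r["w"]), 48)  # 0.6 * 80
  expect_equal(unname(r["h"]), 30)  # 0.6 * 50
  ## masked pixels are exactly zero; nothing outside the rectangle changed
  reg <- out$pixels[(r["y0"] + 1):(r["y0"] + r["h"]),
                    (r["x0"] + 1):(r["x0"] + r["w"])]
  expect_true(all(reg == 0))
  expect_equal(sum(out$pixels == 0), 48 * 30)
  expect_equal(sum(out$pixels == 0) / (80 * 50), 0.36)
  ## annotations untouched
  expect_identical(out$centers, s$centers)

  ## mask always fully inside the chosen vertebra's box
  for (seed in 1:50) {
    o <- random_spine_cutout(s, cfg, seed = seed)
    b <- s$vertebra_boxes[[o$rsc$vertebra]]
    r <- o$rsc$rect
    expect_gte(r["x0"], b["x0"]); expect_gte(r["y0"], b["y0"])
    expect_lte(r["x0"] + r["w"] - 1, b["x1"])
    expect_lte(r["y0"] + r["h"] - 1, b["y1"])
  }
})

test_that("cutout vertebra choice is uniform over L1-L4 and never L5/S1", {
  s <- boxed_sample()
  cfg <- augment_config()
  n <- 10000
  picks <- withr::with_seed(7, vapply(seq_len(n), function(i) {
    random_spine_cutout(s, cfg)$rsc$vertebra
  }, ""))
  tab <- table(factor(picks, levels = c("L1", "L2", "L3", "L4", "L5", "S1")))
  expect_equal(sum(tab[c("L5", "S1")]), 0)
  ## multinomial 3-sigma bound around n/4
  sd3 <- 3 * sqrt(n * 0.25 * 0.75)
  for (lab in c("L1", "L2", "L3", "L4")) {
    expect_lt(abs(tab[[lab]] - n / 4), sd3)
  }
  ## ratio 1.0 leaves no placement freedom: the whole box is zeroed
  full <- random_spine_cutout(s, augment_config(rsc_ratio = 1), seed = 3)
  b <- s$vertebra_boxes[[full$rsc$vertebra]]
  expect_equal(unname(full$rsc$rect[c("x0", "y0")]),
               unname(b[c("x0", "y0")]))
  cfg_bad <- augment_config(); cfg_bad$rsc_candidates <- character(0)
  expect_error(random_spine_cutout(s, cfg_bad), "empty candidate")
})

test_that("conventional cutout is position-free and reproducible", {
  s <- boxed_sample()
  cfg <- augment_config(cutout_size = c(48, 30))
  a <- conventional_cutout(s, cfg, seed = 5)
  b <- conventional_cutout(s, cfg, seed = 5)
  expect_identical(a$pixels, b$pixels)
  expect_equal(sum(a$pixels == 0), 48 * 30)

  ## unlike RSC, the mask lands outside every vertebra box with positive
  ## frequency, close to the geometric background fraction
  in_any_box <- function(o) {
    r <- o$cutout
    any(vapply(s$vertebra_boxes, function(bx) {
      r["x0"] <= bx["x1"] && r["x0"] + r["w"] - 1 >= bx["x0"] &&
        r["y0"] <= bx["y1"] && r["y0"] + r["h"] - 1 >= bx["y0"]
    }, TRUE))
  }
  hits <- withr::with_seed(11, vapply(1:300, function(i) {
    in_any_box(conventional_cutout(s, cfg))
  }, TRUE))
  expect_gt(mean(!hits), 0)
  expect_error(conventional_cutout(s, augment_config(cutout_size = c(500, 10))),
               "larger than raster")
})

test_that("photometric/geometric jitter moves pixels and annotations together", {
  s <- generate_phantom(clean_spec(), 4)
  ## zero-magnitude configuration is the identity
  cfg0 <- augment_config(brightness_range = c(0, 0), contrast_range = c(1, 1),
                         rotation_sd = 0, scale_range = c(1, 1),
                         translation_range = 0)
  out0 <- photometric_geometric(s, cfg0, seed = 1)
  expect_equal(out0$pixels, s$pixels)
  expect_equal(out0$centers, s$centers)

  ## pure translation shifts every annotated point by exactly (dx, dy)
  warp <- spinemark:::similarity_warp
  tr <- warp(s, translation = c(7, -4))
  expect_equal(tr$centers, s$centers + rep(c(7, -4), each = 6))
  expect_equal(tr$landmarks$L2, s$landmarks$L2 + rep(c(7, -4), each = 4))

  ## rotation by theta then -theta restores annotations
  r1 <- warp(s, rotation = 13)
  r2 <- warp(r1, rotation = -13)
  expect_lt(max(abs(r2$centers - s$centers)), 1e-6)
  expect_lt(max(abs(r2$landmarks$L5 - s$landmarks$L5)), 1e-6)

  ## ordering of annotations survives jitter
  out <- photometric_geometric(s, augment_config(), seed = 9)
  expect_true(all(diff(out$centers[, 2]) > 0))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
})
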