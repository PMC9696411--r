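# Shared fixtures: phantom specs at the conditions the tests assume, and
# constructors for hand-built heatmap stacks.

# deterministic geometry, clean intensities
clean_spec <- function(...) {
  phantom_spec(noise_sd = 0, occlusion_prob = 0, ...)
}

# "easy" condition: no occlusion, fixed spacing (centers on a rigid grid)
easy_spec <- function(...) {
  phantom_spec(occlusion_prob = 0, spacing_sd = 0, ...)
}

# 6-channel stack of Gaussians at given (x, y) centers
stack_at <- function(centers, sigma = 1.5, shape = c(64, 64)) {
  gaussian_map(centers, sigma, shape, frame = "heatmap")
}

# Corrupted center stack emulating the upward-shifted failure mode:
# channels 1..j show the vertebra above (channel 1 shows T12), channels
# j+1..6 are correct, and a weak secondary response of amplitude `amp`
# remains at the missing center in channel j.
shifted_stack <- function(true_centers, j, amp = 0.5, sigma = 1.5,
                          shape = c(64, 64)) {
  t12 <- true_centers[1, ] - (true_centers[2, ] - true_centers[1, ])
  shown <- rbind(t12, true_centers)[c(seq_len(j), (j + 2):7), , drop = FALSE]
  st <- gaussian_map(shown, sigma, shape, frame = "heatmap")
  weak <- gaussian_map(true_centers[j, , drop = FALSE], sigma, shape)
  st$maps[, , j] <- pmin(1, st$maps[, , j] + amp * weak$maps[, , 1])
  st
}

# A minimal annotated sample with exact axis-aligned vertebra boxes, for
# cutout tests where box dimensions must be controlled precisely.
boxed_sample <- function(h = 200, w = 260, box_w = 80, box_h = 50) {
  boxes <- list()
  labs <- c("L1", "L2", "L3", "L4", "L5", "S1")
  for (i in seq_along(labs)) {
    y0 <- 10 + (i - 1) * 30
    boxes[[labs[i]]] <- c(x0 = 40, y0 = y0, x1 = 40 + box_w - 1,
                          y1 = y0 + box_h - 1)
  }
  structure(list(pixels = matrix(100, h, w), frame = "original",
                 centers = cbind(x = rep(80, 6), y = 10 + (0:5) * 30 + box_h / 2),
                 landmarks = list(), vertebra_boxes = boxes),
            class = "annotated_image")
}
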