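#' Scaled-down end-to-end smoke experiment
#'
#' A fixed, reproducible desk-scale experiment exercising the whole
#' pipeline: 200 training phantoms under the easy condition (no
#' occlusion, fixed inter-center spacing), 40 validation and 50 held-out
#' test phantoms; a narrow center detector trained at full 512 input
#' resolution; and a narrow lumbar landmark detector trained on the
#' ground-truth-centered crops of a subset of the training phantoms. The
#' center stage is scored with [center_report()] (crop outliers and mean
#' distance at the 512 input scale) and the landmark stage with
#' [landmark_report()] on ground-truth-centered crops of the test
#' phantoms (mean relative distance and the 20% vertebra-outlier rule).
#'
#' The problem sizes and network widths are the package's desk-scale
#' defaults; they are deliberately small so the experiment verifies the
#' wiring of every stage rather than chasing the accuracy a full-scale
#' training run would reach.
#'
#' @param seed integer seed driving phantom generation, initialization
#'   and shuffling.
#' @param n_train,n_val,n_test split sizes.
#' @param center_epochs,landmark_epochs training epochs for the two
#'   stages.
#' @param lumbar_train_images number of training phantoms whose crops
#'   feed the lumbar detector.
#' @param quiet suppress progress messages.
#' @return List with `center` (a [center_report()]), `lumbar_rd`,
#'   `lumbar_outliers` (percent), `models`, `histories` and the sizes
#'   used.
#' @export
smoke_experiment <- function(seed = 1L, n_train = 200L, n_val = 20L,
                             n_test = 50L, center_epochs = 14L,
                             landmark_epochs = 10L,
                             lumbar_train_images = 40L, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  spec <- phantom_spec(occlusion_prob = 0, spacing_sd = 0)
  seed <- as.integer(seed)

  say("generating phantoms")
  train_s <- lapply(seq_len(n_train),
                    function(i) generate_phantom(spec, seed + i - 1L))
  val_s <- lapply(seq_len(n_val),
                  function(i) generate_phantom(spec, seed + 100000L + i - 1L))
  test_s <- lapply(seq_len(n_test),
                   function(i) generate_phantom(spec, seed + 200000L + i - 1L))

  ## -- center stage ---------------------------------------------------------
  say("training center detector")
  ccfg <- centernet_config(base_channels = 4L)
  tr <- make_center_dataset(train_s, ccfg)
  va <- make_center_dataset(val_s, ccfg)
  ## single-sample batches: the easy-condition samples are nearly
  ## identical, so gradient noise is negligible and more optimizer
  ## updates per epoch buy convergence directly
  cfit <- train_centernet(tr, ccfg,
                          train_config(lr = 5e-3, batch = 1L,
                                       max_epochs = center_epochs,
                                       patience = center_epochs - 1L,
                                       seed = seed, lr_floor = 0.5),
                          val_data = va)

  say("decoding centers on held-out phantoms")
  hm <- input_to_heatmap(ccfg$in_size)
  pred_centers <- lapply(test_s, function(s) {
    rp <- resize_and_pad(s$pixels, ccfg$in_size)
    x <- enhance(rp$image)
    st <- predict_centers(cfit$model, x)
    mx <- extract_maxima(st)
    gap <- gap_check(mx)
    if (gap$flagged) {
      fx <- repair_centers(st, gap)
      if (isTRUE(attr(fx, "repaired"))) mx <- fx
    }
    map_points(mx, list(ft_invert(hm), ft_invert(rp$transform)))
  })
  center_eval <- center_report(pred_centers, test_s, in_size = ccfg$in_size)

  ## -- lumbar landmark stage on ground-truth-centered crops -----------------
  say("training lumbar landmark detector")
  lcfg <- landmarknet_config("lumbar", base_channels = 4L)
  tr_lm <- make_landmark_dataset(train_s[seq_len(lumbar_train_images)],
                                 "lumbar", lcfg)
  va_lm <- make_landmark_dataset(val_s[seq_len(10L)], "lumbar", lcfg)
  lfit <- train_landmarknet(tr_lm, lcfg,
                            train_config(lr = 5e-3, batch = 1L,
                                         max_epochs = landmark_epochs,
                                         patience = landmark_epochs - 1L,
                                         seed = seed, lr_floor = 0.5),
                            val_data = va_lm)

  say("decoding landmarks on held-out crops")
  te_lm <- make_landmark_dataset(test_s, "lumbar", lcfg)
  preds <- vector("list", n_test)
  for (item in te_lm) {
    fw <- landmarknet_forward(lfit$model, item$x)
    dec <- decode_landmarks(fw$cm, item$transform)
    preds[[item$sample_id]][[item$vertebra]] <- dec
  }
  keep <- !vapply(preds, is.null, TRUE)
  lm_eval <- landmark_report(preds[keep], test_s[keep])

  list(center = center_eval,
       lumbar_rd = lm_eval$total_rd,
       lumbar_outliers = lm_eval$outlier_ratio,
       lumbar_eval = lm_eval,
       models = list(center = cfit$model, lumbar = lfit$model),
       histories = list(center = cfit$history, lumbar = lfit$history),
       sizes = list(n_train = n_train, n_val = n_val, n_test = n_test,
                    lumbar_train_crops = length(tr_lm)))
}
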