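#' Training configuration
#'
#' Defaults follow the full-scale protocol (Adam, learning rate 1e-4,
#' linear decay, early stopping on validation loss); smoke-scale
#' experiments pass smaller `max_epochs`/`batch`.
#'
#' @param lr initial Adam learning rate.
#' @param batch batch size (gradients averaged over the batch).
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience: training stops once the best
#'   validation loss is `patience` epochs old.
#' @param seed RNG seed controlling shuffling (and any augmentation draws).
#' @param rsc_prob probability of applying random spine cutout to a
#'   training sample (0 disables; only used where the dataset carries
#'   vertebra boxes).
#' @param lr_floor fraction of `lr` the linear decay ends at (0 decays to
#'   zero over `max_epochs`; short runs keep a floor so late epochs still
#'   learn).
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, batch = 16L, max_epochs = 200L,
                         patience = 30L, seed = 1L, rsc_prob = 0,
                         lr_floor = 0) {
  stopifnot(lr > 0, batch >= 1, patience < max_epochs || max_epochs == 1,
            lr_floor >= 0, lr_floor <= 1)
  structure(list(lr = lr, batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 rsc_prob = rsc_prob, lr_floor = lr_floor),
            class = "train_config")
}

## Generic seeded training loop with linear lr decay and early stopping.
## grad_fn(params, item)  -> list(loss = scalar, grads = tree)
## loss_fn(params, item)  -> scalar
fit_network <- function(params, train_data, val_data, tcfg, grad_fn, loss_fn) {
  if (length(train_data) == 0L) stop("empty training dataset")
  if (length(val_data) == 0L) stop("empty validation dataset")
  state <- adam_init(params)
  best <- list(loss = Inf, epoch = 0L, params = params)
  history <- vector("list", tcfg$max_epochs)
  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$max_epochs)) {
      frac <- (epoch - 1) / tcfg$max_epochs
      floor_ <- if (is.null(tcfg$lr_floor)) 0 else tcfg$lr_floor
      lr_e <- tcfg$lr * (1 - (1 - floor_) * frac)
      ord <- sample.int(length(train_data))
      tr_losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[i:min(i + tcfg$batch - 1L, length(ord))]
        gsum <- NULL
        for (id in idx) {
          res <- grad_fn(params, train_data[[id]])
          tr_losses <- c(tr_losses, res$loss)
          gsum <- if (is.null(gsum)) res$grads else grads_add(gsum, res$grads)
        }
        gavg <- grads_scale(gsum, 1 / length(idx))
        st <- adam_step(params, gavg, state, lr_e)
        params <- st$params; state <- st$state
        i <- i + tcfg$batch
      }
      val_loss <- mean(vapply(val_data, function(it) loss_fn(params, it), 0))
      history[[epoch]] <- data.frame(epoch = epoch,
                                     train_loss = mean(tr_losses),
                                     val_loss = val_loss, lr = lr_e)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, epoch = epoch, params = params)
      }
      if (epoch - best$epoch >= tcfg$patience) break
    }
  })
  list(params = best$params,
       history = do.call(rbind, history[!vapply(history, is.null, TRUE)]),
       best_epoch = best$epoch, best_val_loss = best$loss)
}
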