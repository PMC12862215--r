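# Training regimen: stratified coding/noncoding batches, masked cross-entropy,
# Adam with plateau-halving learning-rate schedule, early stopping, and
# best-by-validation-loss checkpointing.

#' Training configuration
#'
#' Defaults follow the published regimen: at most 50 epochs, batch size 4,
#' Adam at 1e-3, learning rate halved after 3 consecutive non-improving
#' validation epochs, training stopped after 5, best epoch kept.
#'
#' @param max_epochs,batch_size,learning_rate optimizer basics.
#' @param plateau_factor,plateau_patience learning-rate schedule.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param seed integer governing batch shuffling.
#' @param mix_noncoding stratify batches by biotype (TRUE when training on
#'   mixed coding + noncoding data).
#' @param improve_tol minimum decrease in validation loss that counts as an
#'   improvement.
#' @return an `orf_train_config` list.
#' @export
train_config <- function(max_epochs = 50L, batch_size = 4L,
                         learning_rate = 1e-3, plateau_factor = 0.5,
                         plateau_patience = 3L, early_stop_patience = 5L,
                         seed = 1L, mix_noncoding = TRUE,
                         improve_tol = 1e-6) {
  stopifnot(plateau_patience >= 1, early_stop_patience >= plateau_patience,
            batch_size >= 1, max_epochs >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 mix_noncoding = isTRUE(mix_noncoding),
                 improve_tol = improve_tol),
            class = "orf_train_config")
}

#' Stratified batch order
#'
#' Returns a permutation of sample indices such that, read in consecutive
#' chunks of `batch_size`, every batch's coding fraction deviates from the
#' global coding fraction by at most 1/batch_size.  Coding and noncoding
#' samples are shuffled independently, then interleaved by largest-remainder
#' so the two streams stay proportional.
#'
#' @param biotype character vector ("coding"/"noncoding"), one per sample.
#' @param batch_size samples per batch.
#' @param seed integer seed.
#' @return integer vector: sample indices in batch order.
#' @export
stratified_batches <- function(biotype, batch_size, seed = 1L) {
  n <- length(biotype)
  if (n == 0) stop("no samples to batch")
  coding_idx <- which(biotype == "coding")
  nonc_idx <- which(biotype != "coding")
  withr::with_seed(seed, {
    coding_idx <- sample(coding_idx)
    nonc_idx <- sample(nonc_idx)
  })
  frac <- length(coding_idx) / n
  order <- integer(n)
  ci <- 0L
  ni <- 0L
  for (i in seq_len(n)) {
    # keep the running coding count tracking i * frac (Bresenham merge)
    take_coding <- (ci < round(i * frac) && ci < length(coding_idx)) ||
      ni >= length(nonc_idx)
    if (take_coding) {
      ci <- ci + 1L
      order[i] <- coding_idx[ci]
    } else {
      ni <- ni + 1L
      order[i] <- nonc_idx[ni]
    }
  }
  order
}

#' Masked cross-entropy loss
#'
#' Mean over non-padding positions of the negative log-probability of the
#' true class; positions at or beyond `valid_length` contribute nothing.
#' This is the reference implementation used for testing; the compiled
#' training loop computes the identical quantity.
#'
#' @param logits array (positions x 3 x batch) or matrix (positions x 3).
#' @param labels integer matrix (positions x batch) of class codes 1..3.
#' @param valid_length integer vector, one per batch element.
#' @return scalar loss.
#' @export
masked_cross_entropy <- function(logits, labels, valid_length) {
  if (length(dim(logits)) == 2) logits <- array(logits, dim = c(dim(logits), 1))
  if (is.vector(labels)) labels <- matrix(labels, ncol = 1)
  stopifnot(dim(logits)[1] == nrow(labels), dim(logits)[3] == ncol(labels),
            length(valid_length) == ncol(labels))
  total <- 0
  count <- 0
  for (b in seq_len(ncol(labels))) {
    vl <- valid_length[b]
    if (vl == 0) next
    p <- to_probabilities(matrix(logits[seq_len(vl), , b], ncol = 3))
    total <- total - sum(log(p[cbind(seq_len(vl), labels[seq_len(vl), b])]))
    count <- count + vl
  }
  if (count == 0) 0 else total / count
}

# Pure scheduler/early-stopping logic over a sequence of validation losses.
# Processes losses epoch by epoch and returns per-epoch learning rates, the
# best epoch, and the stopping epoch.  "Improvement" means lower than the
# best so far by at least `tol`; the plateau counter resets on improvement or
# on a learning-rate reduction.
plateau_schedule <- function(val_losses, lr0, factor, plateau_patience,
                             early_stop_patience, tol = 1e-6) {
  lr <- lr0
  lrs <- numeric(0)
  best <- Inf
  best_epoch <- 0L
  since_improve <- 0L   # for early stopping: epochs since last improvement
  since_plateau <- 0L   # for the scheduler: resets on lr reduction too
  stopped <- length(val_losses)
  for (e in seq_along(val_losses)) {
    lrs[e] <- lr
    if (val_losses[e] < best - tol) {
      best <- val_losses[e]
      best_epoch <- e
      since_improve <- 0L
      since_plateau <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_plateau <- since_plateau + 1L
      if (since_improve >= early_stop_patience) {
        stopped <- e
        break
      }
      if (since_plateau >= plateau_patience) {
        lr <- lr * factor
        since_plateau <- 0L
      }
    }
  }
  list(lrs = lrs, best_epoch = best_epoch, stopped_epoch = stopped,
       next_lr = lr)
}

#' Train a labeler
#'
#' Runs the full regimen: stratified batches each epoch, masked cross-entropy
#' with Adam, validation loss after every epoch, plateau-halving learning
#' rate, early stopping, and restoration of the weights from the epoch with
#' the lowest validation loss.
#'
#' @param model an `orf_model` (modified in place; also returned).
#' @param train_data,val_data encoded sets from [encode_transcripts()].
#' @param config an `orf_train_config`.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best weights restored), `history` (data.frame
#'   epoch/train_loss/val_loss/lr) and `best_epoch`.
#' @export
train_model <- function(model, train_data, val_data, config = train_config(),
                        verbose = TRUE) {
  stopifnot(inherits(config, "orf_train_config"))
  if (ncol(train_data$tokens) == 0 || ncol(val_data$tokens) == 0)
    stop("train and validation sets must be non-empty")
  labels0 <- function(lab) {
    m <- lab
    m[is.na(m)] <- 0L
    m - 1L  # engine codes: 0 TIS, 1 TTS, 2 NONE, -1 masked
  }
  tr_lab <- labels0(train_data$labels)
  va_lab <- labels0(val_data$labels)
  lr <- config$learning_rate
  best <- Inf
  best_epoch <- 0L
  best_state <- NULL
  since_improve <- 0L
  since_plateau <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  biotype <- if (config$mix_noncoding) train_data$records$biotype
             else rep("coding", ncol(tr_lab))
  # deterministic, class-balanced subset used to re-estimate batch-norm
  # population statistics after every epoch (small batches leave the running
  # averages lagging behind the weights in a deep normalized stack)
  calib_idx <- unique(round(seq(1, ncol(train_data$tokens),
                                length.out = min(256L, ncol(train_data$tokens)))))
  for (epoch in seq_len(config$max_epochs)) {
    order <- stratified_batches(biotype, config$batch_size,
                                seed = config$seed + epoch)
    train_loss <- .nn_train_epoch(model$ptr, train_data$tokens, tr_lab,
                                  order, config$batch_size, lr)
    .nn_recalibrate_bn(model$ptr,
                       train_data$tokens[, calib_idx, drop = FALSE], 16L)
    val_loss <- .nn_eval_loss(model$ptr, val_data$tokens, va_lab, 16L)
    if (!is.finite(train_loss) || !is.finite(val_loss))
      stop("training diverged at epoch ", epoch, " (non-finite loss)")
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %d: train %.5f  val %.5f  lr %.2e",
                      epoch, train_loss, val_loss, lr))
    if (val_loss < best - config$improve_tol) {
      best <- val_loss
      best_epoch <- epoch
      best_state <- model_state(model)
      since_improve <- 0L
      since_plateau <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_plateau <- since_plateau + 1L
      if (since_improve >= config$early_stop_patience) break
      if (since_plateau >= config$plateau_patience) {
        lr <- lr * config$plateau_factor
        since_plateau <- 0L
        if (verbose) message(sprintf("  plateau: lr reduced to %.2e", lr))
      }
    }
  }
  if (!is.null(best_state)) set_model_state(model, best_state)
  model$meta$train <- list(best_epoch = best_epoch, best_val_loss = best)
  list(model = model, history = history, best_epoch = best_epoch,
       best_val_loss = best)
}
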