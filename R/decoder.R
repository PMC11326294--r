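#' Select reversals long enough for decoding
#'
#' Keeps reversals spanning at least 1.5 head-swing cycles (three complete
#' half-cycles, inclusive at the boundary) of the aligned clock.
#'
#' @param events event table with `reversal_start`, `reversal_end` (frames).
#' @param crossings output of [detect_crossings()] for the paired curvature.
#' @param frame_rate Hz.
#' @param min_cycles minimum reversal length in head-swing cycles.
#' @return logical vector, one entry per event.
#' @export
eligible_reversals <- function(events, crossings, frame_rate,
                               min_cycles = 1.5) {
  t0 <- (events$reversal_start - 1L) / frame_rate
  t1 <- (events$reversal_end - 1L) / frame_rate
  vapply(seq_len(nrow(events)), function(e) {
    inside <- crossings$time >= t0[e] & crossings$time <= t1[e]
    n_half <- max(0L, sum(inside) - 1L)
    n_half >= ceiling(2 * min_cycles)
  }, TRUE)
}

#' Build the decoder dataset from one recording
#'
#' Warps the activity trace and the head curvature onto the uniform
#' head-swing phase grid, restricts them to each eligible reversal, and
#' labels every event by its upcoming turn direction
#' ([turn_dv_label()]).  Each retained event carries its full within-reversal
#' aligned series; 4-frame decoder windows are drawn from it later.
#'
#' @param activity numeric activity vector (e.g. one neuron's trace).
#' @param head_curvature signed curvature on the same clock.
#' @param time time vector, s.
#' @param events event table with `reversal_start`, `reversal_end`, and
#'   optionally `plate`.
#' @param points_per_half aligned grid points per half-cycle; the default 4
#'   makes one decoder frame half of a head swing quarter-cycle.
#' @param target_period uniform cycle period, s.
#' @return an object of class `decoder_dataset`: list of per-event records
#'   (`series` L x 2 matrix [activity, behavior], `label`, `event_id`,
#'   `plate`).
#' @export
build_decoder_dataset <- function(activity, head_curvature, time, events,
                                  points_per_half = 4L, target_period = 4.8) {
  fs <- 1 / mean(diff(time))
  cr <- detect_crossings(head_curvature, time = time)
  keep <- eligible_reversals(events, cr, fs)
  lab <- turn_dv_label(head_curvature, events$reversal_end)
  wa <- warp_to_uniform_cycles(activity, time, cr, target_period,
                               points_per_half, min_frames = 1L)
  wb <- warp_to_uniform_cycles(head_curvature, time, cr, target_period,
                               points_per_half, min_frames = 1L)
  t0 <- (events$reversal_start - 1L) / fs
  t1 <- (events$reversal_end - 1L) / fs
  recs <- list()
  for (e in which(keep & !is.na(lab))) {
    segs <- which(wa$t_start >= t0[e] & wa$t_end <= t1[e])
    if (length(segs) < 3L) next
    series <- cbind(
      activity = as.vector(t(wa$values[segs, , drop = FALSE])),
      behavior = as.vector(t(wb$values[segs, , drop = FALSE])))
    if (anyNA(series)) next
    recs[[length(recs) + 1L]] <- list(
      series = series, label = lab[e], event_id = e,
      plate = if (!is.null(events$plate)) events$plate[e] else 1L)
  }
  structure(recs, class = "decoder_dataset")
}

#' @export
print.decoder_dataset <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("<decoder_dataset> %d eligible reversals (%d dorsal, %d ventral)\n",
              length(x), sum(labs == "dorsal"), sum(labs == "ventral")))
  invisible(x)
}

#' Draw 4-frame decoder windows
#'
#' One window per event, its start drawn uniformly among positions where the
#' window lies fully inside the reversal's aligned series (so windows are
#' not time-locked to reversal endings).
#'
#' @param dataset a `decoder_dataset`.
#' @param seed integer seed (NULL leaves the RNG state alone, for use inside
#'   the training loop).
#' @param width window length in aligned frames.
#' @return list with `X` (array events x width x 2) and `labels` (1 =
#'   dorsal, 0 = ventral).
#' @export
extract_windows <- function(dataset, seed = 1L, width = 4L) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(dataset)
  X <- array(NA_real_, c(n, width, 2L))
  labels <- numeric(n)
  for (i in seq_len(n)) {
    L <- nrow(dataset[[i]]$series)
    if (L < width) stop("event series shorter than the window width")
    s <- if (L == width) 1L else sample.int(L - width + 1L, 1L)
    X[i, , ] <- dataset[[i]]$series[s:(s + width - 1L), ]
    labels[i] <- as.numeric(dataset[[i]]$label == "dorsal")
  }
  list(X = X, labels = labels)
}

#' Hierarchical stratified split plan
#'
#' Partitions events into 5 rotated 80:20 train/test splits; within each
#' training partition, 4 rotated 75:25 train/validation splits, giving
#' 5 x 4 = 20 train/validation/test variations at 60:20:20.  Splitting is
#' stratified by turn label at the event level (each fold holds the global
#' dorsal:ventral ratio to within one event per class), and every event
#' appears in exactly one outer test fold.
#'
#' @param labels per-event labels (anything with two levels, e.g.
#'   "dorsal"/"ventral").
#' @param seed integer seed.
#' @return an object of class `split_plan`: list of 5 outer folds, each
#'   with `test`, and `inner`, a list of 4 (train, val) index pairs.
#' @export
build_split_plan <- function(labels, seed = 1L) {
  set.seed(seed)
  n <- length(labels)
  classes <- split(seq_len(n), labels)
  if (length(classes) != 2L) stop("need exactly two classes")
  chunk <- function(idx, k) {
    idx <- sample(idx)
    split(idx, rep_len(seq_len(k), length(idx)))
  }
  outer_parts <- lapply(classes, chunk, k = 5L)
  folds <- vector("list", 5L)
  for (f in 1:5) {
    test <- sort(unlist(lapply(outer_parts, `[[`, f), use.names = FALSE))
    train_pool <- setdiff(seq_len(n), test)
    inner_parts <- lapply(split(train_pool, labels[train_pool]), chunk, k = 4L)
    inner <- vector("list", 4L)
    for (j in 1:4) {
      val <- sort(unlist(lapply(inner_parts, `[[`, j), use.names = FALSE))
      inner[[j]] <- list(train = setdiff(train_pool, val), val = val)
    }
    folds[[f]] <- list(test = test, inner = inner)
  }
  structure(list(folds = folds, n = n, labels = labels, seed = seed),
            class = "split_plan")
}

#' Decoder configuration
#'
#' @param channels "both" (activity + behavior) or "behavior_only" (the
#'   activity channel is zeroed, not removed).
#' @param hidden_size GRU hidden units.
#' @param dropout dropout rate on the final hidden state.
#' @param epochs training epochs.
#' @param lr learning rate (Adam).
#' @param batch_size minibatch size.
#' @param label_shuffle if TRUE, labels are permuted across events before
#'   splitting (chance-level control).
#' @param redraw_windows if TRUE a fresh window is drawn per reversal each
#'   epoch; FALSE fixes one window per reversal for exact reproducibility.
#' @param width window length in aligned frames.
#' @return list of class `decoder_config`.
#' @export
decoder_config <- function(channels = c("both", "behavior_only"),
                           hidden_size = 3L, dropout = 0.2, epochs = 250L,
                           lr = 1e-3, batch_size = 16L,
                           label_shuffle = FALSE, redraw_windows = TRUE,
                           width = 4L) {
  channels <- match.arg(channels)
  structure(list(channels = channels, hidden_size = hidden_size,
                 dropout = dropout, epochs = epochs, lr = lr,
                 batch_size = batch_size, label_shuffle = label_shuffle,
                 redraw_windows = redraw_windows, width = width),
            class = "decoder_config")
}

.apply_channels <- function(X, channels) {
  if (channels == "behavior_only") X[, , 1L] <- 0
  X
}

#' Balanced accuracy of binary predictions
#'
#' Outputs >= 0.5 round to dorsal (1), < 0.5 to ventral (0); the score is
#' the mean of the per-class accuracies, so a constant guess scores exactly
#' 0.5 on two-class data.
#'
#' @param prob predicted probabilities of dorsal.
#' @param labels true labels (1 dorsal, 0 ventral).
#' @return balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(prob, labels) {
  pred <- as.numeric(prob >= 0.5)
  correct <- pred == labels
  mean(vapply(split(correct, labels), mean, 1))
}

#' Train the turn-direction decoder on one split
#'
#' Trains the GRU classifier with per-epoch class balancing (a random subset
#' of the majority class equal in size to the minority class), minibatches,
#' Adam, and binary cross-entropy; retains the parameter snapshot from the
#' epoch with minimum validation loss.
#'
#' @param train_data,val_data subsets of a `decoder_dataset`.
#' @param config a [decoder_config()].
#' @param seed integer seed (initialization, balancing, batching, window
#'   redraws).
#' @return list with `par` (best-epoch parameters), `best_epoch`,
#'   `train_loss`, `val_loss` (per epoch).
#' @export
train_decoder <- function(train_data, val_data, config = decoder_config(),
                          seed = 1L) {
  labs <- vapply(train_data, `[[`, "", "label")
  if (length(unique(labs)) < 2L)
    stop("training data must contain both classes")
  set.seed(seed)
  par <- .gru_init(2L, config$hidden_size, seed = seed)
  adam <- .adam_init(par)
  val <- extract_windows(val_data, seed = NULL, width = config$width)
  val$X <- .apply_channels(val$X, config$channels)
  fixed <- extract_windows(train_data, seed = NULL, width = config$width)
  dorsal_idx <- which(labs == "dorsal")
  ventral_idx <- which(labs == "ventral")
  k <- min(length(dorsal_idx), length(ventral_idx))
  best <- list(loss = Inf, par = par, epoch = 0L)
  train_loss <- val_loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    tw <- if (config$redraw_windows)
      extract_windows(train_data, seed = NULL, width = config$width)
    else fixed
    tw$X <- .apply_channels(tw$X, config$channels)
    use <- c(sample(dorsal_idx, k), sample(ventral_idx, k))
    use <- sample(use)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, length(use), by = config$batch_size)) {
      idx <- use[b0:min(b0 + config$batch_size - 1L, length(use))]
      Xb <- tw$X[idx, , , drop = FALSE]
      yb <- tw$labels[idx]
      mask <- if (config$dropout > 0)
        matrix(stats::rbinom(length(idx) * par$H, 1L, 1 - config$dropout) /
                 (1 - config$dropout), length(idx), par$H)
      else NULL
      fwd <- .gru_forward(par, Xb, drop_mask = mask)
      grad <- .gru_backward(par, Xb, fwd, yb)
      upd <- .adam_step(par, grad, adam, lr = config$lr)
      par[names(upd$par)] <- upd$par
      adam <- upd$state
      ep_loss <- ep_loss + .bce_loss(fwd$prob, yb)
      nb <- nb + 1L
    }
    train_loss[ep] <- ep_loss / nb
    vf <- .gru_forward(par, val$X)
    val_loss[ep] <- .bce_loss(vf$prob, val$labels)
    if (val_loss[ep] < best$loss)
      best <- list(loss = val_loss[ep], par = par, epoch = ep)
  }
  list(par = best$par, best_epoch = best$epoch, train_loss = train_loss,
       val_loss = val_loss, config = config)
}

#' Predict dorsal-turn probabilities from a trained decoder
#'
#' @param model output of [train_decoder()].
#' @param X window array (events x width x 2), already channel-masked or
#'   not (`channels` of the model's config is applied).
#' @return numeric vector of probabilities.
#' @export
predict_decoder <- function(model, X) {
  X <- .apply_channels(X, model$config$channels)
  .gru_forward(model$par, X)$prob
}

#' Evaluate the full hierarchical cross-validation plan
#'
#' Trains the 20 models of a [build_split_plan()] and scores each on its
#' outer test fold (windows drawn once per fold, seeded); reports the grand
#' mean balanced accuracy, the per-model fold table, and per-event test
#' correctness (averaged over the fold's four models) for bootstrap
#' comparison.
#'
#' @param dataset a `decoder_dataset`.
#' @param plan a `split_plan` over the same events.
#' @param config a [decoder_config()].
#' @param seed integer seed.
#' @return list with `mean_balanced_accuracy`, `fold_table`,
#'   `per_event` (event index, label, mean correctness).
#' @export
evaluate_plan <- function(dataset, plan, config = decoder_config(),
                          seed = 1L) {
  labs_all <- plan$labels
  n <- plan$n
  correct_sum <- numeric(n); correct_n <- integer(n)
  rows <- list()
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    test_data <- dataset[fold$test]
    class(test_data) <- "decoder_dataset"
    tw <- extract_windows(test_data, seed = seed + 131L * f,
                          width = config$width)
    ytest <- tw$labels
    for (j in seq_along(fold$inner)) {
      tr <- dataset[fold$inner[[j]]$train]
      va <- dataset[fold$inner[[j]]$val]
      class(tr) <- class(va) <- "decoder_dataset"
      model <- train_decoder(tr, va, config,
                             seed = seed + 1000L * f + j)
      prob <- predict_decoder(model, tw$X)
      acc <- balanced_accuracy(prob, ytest)
      rows[[length(rows) + 1L]] <-
        data.frame(outer = f, inner = j, best_epoch = model$best_epoch,
                   balanced_accuracy = acc)
      hit <- as.numeric((prob >= 0.5) == ytest)
      correct_sum[fold$test] <- correct_sum[fold$test] + hit
      correct_n[fold$test] <- correct_n[fold$test] + 1L
    }
  }
  fold_table <- do.call(rbind, rows)
  list(mean_balanced_accuracy = mean(fold_table$balanced_accuracy),
       fold_table = fold_table,
       per_event = data.frame(
         event = seq_len(n),
         label = as.character(labs_all),
         correct = correct_sum / pmax(correct_n, 1L)))
}

#' Fit and cross-validate the upcoming-turn decoder
#'
#' The model-level front end: takes a `decoder_dataset`, builds the
#' stratified 5 x 4 split plan, trains the 20 GRU models for the requested
#' input mode and reports cross-validated balanced accuracy.
#'
#' @param dataset a `decoder_dataset` (see [build_decoder_dataset()]).
#' @param mode "both" (activity + behavior), "behavior_only", or
#'   "label_shuffle" (both channels, labels permuted: chance control).
#' @param seed integer seed.
#' @param ... overrides passed to [decoder_config()].
#' @return object of class `turn_decoder` with the evaluation results.
#' @export
turn_decoder <- function(dataset, mode = c("both", "behavior_only",
                                           "label_shuffle"),
                         seed = 1L, ...) {
  mode <- match.arg(mode)
  config <- decoder_config(
    channels = if (mode == "behavior_only") "behavior_only" else "both",
    label_shuffle = mode == "label_shuffle", ...)
  labs <- vapply(dataset, `[[`, "", "label")
  if (config$label_shuffle) {
    set.seed(seed + 7L)
    labs <- sample(labs)
    for (i in seq_along(dataset)) dataset[[i]]$label <- labs[i]
  }
  plan <- build_split_plan(labs, seed = seed)
  res <- evaluate_plan(dataset, plan, config, seed = seed)
  structure(c(res, list(mode = mode, config = config, plan = plan,
                        n_events = length(dataset), seed = seed)),
            class = "turn_decoder")
}

#' @export
print.turn_decoder <- function(x, ...) {
  cat(sprintf(
    "<turn_decoder> mode = %s | %d events | mean balanced accuracy = %.3f (20 models)\n",
    x$mode, x$n_events, x$mean_balanced_accuracy))
  invisible(x)
}

#' @export
summary.turn_decoder <- function(object, ...) {
  ft <- object$fold_table
  cat(sprintf("Turn-direction decoder (%s), %d events\n", object$mode,
              object$n_events))
  cat(sprintf("  mean balanced accuracy: %.3f\n",
              object$mean_balanced_accuracy))
  cat(sprintf("  per-outer-fold means: %s\n",
              paste(sprintf("%.3f", tapply(ft$balanced_accuracy, ft$outer,
                                           mean)), collapse = ", ")))
  cat(sprintf("  selected epochs: median %d (range %d-%d)\n",
              as.integer(stats::median(ft$best_epoch)), min(ft$best_epoch),
              max(ft$best_epoch)))
  invisible(object)
}
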