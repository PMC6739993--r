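# Training and inference for the segment classifiers.

#' Training hyperparameters
#'
#' The `"paper"` profile is the full recipe (batch 100, 150 epochs, Adam
#' step 1e-5); the `"fast"` profile keeps the batch size and Adam moment
#' constants but trains 12 epochs at step 1e-3, sized for desk-scale
#' runs on synthetic corpora, where the two-class problem is far easier
#' than field data.
#'
#' @param profile `"paper"` or `"fast"`; sets `epochs`/`lr` defaults.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param lr Adam step-size factor.
#' @param beta1,beta2,epsilon Adam moment constants.
#' @param seed RNG seed covering shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(profile = c("paper", "fast"), batch_size = 100L,
                         epochs = NULL, lr = NULL, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-8, seed = 0L) {
  profile <- match.arg(profile)
  if (is.null(epochs)) epochs <- if (profile == "fast") 12L else 150L
  if (is.null(lr)) lr <- if (profile == "fast") 1e-3 else 1e-5
  stopifnot(batch_size >= 1, epochs >= 1, lr > 0)
  structure(list(profile = profile, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon, seed = seed),
            class = "train_config")
}

# per-segment RMS normalization: classification must rest on waveform
# shape, not on echo amplitude (which varies with depth and gain)
normalize_segments <- function(X) {
  r <- sqrt(rowMeans(X^2))
  r[r == 0] <- 1
  X / r
}

#' Train a segment classifier
#'
#' Minimizes the softmax cross-entropy with Adam over minibatches of
#' per-segment RMS-normalized windows.  When the dataset carries a
#' train/test split, held-out accuracy is tracked per epoch and the
#' final test accuracy and AUROC (class-1 probability as score) are
#' stored on the returned model.
#'
#' @param model an untrained (or warm) `ucpwi_model`.
#' @param dataset a `segment_dataset` with labels; rows with `NA` labels
#'   are dropped.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return the trained model, with `history` (per-epoch loss/accuracy),
#'   `test_accuracy` and `test_auc` fields.
#' @export
train_classifier <- function(model, dataset, cfg = train_config("fast"),
                             verbose = FALSE) {
  stopifnot(inherits(model, "ucpwi_model"),
            inherits(dataset, "segment_dataset"),
            inherits(cfg, "train_config"))
  ok <- !is.na(dataset$labels)
  X <- normalize_segments(dataset$segments[ok, , drop = FALSE])
  y <- as.integer(dataset$labels[ok])
  if (length(unique(y)) < 2L)
    stop("degenerate dataset: both classes must be present")
  split <- if (is.null(dataset$split)) rep("train", length(y)) else
    dataset$split[ok]
  itr <- which(split == "train"); ite <- which(split == "test")
  Xtr <- X[itr, , drop = FALSE]; ytr <- y[itr]
  Xte <- X[ite, , drop = FALSE]; yte <- y[ite]
  params <- model$params
  st <- adam_init(params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_accuracy = numeric(0), test_accuracy = numeric(0))
  n <- nrow(Xtr)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hit <- 0
      for (b0 in seq.int(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
        model$params <- params
        fw <- model_forward(model, Xb, train = TRUE)
        loss <- ce_loss(fw$probs, yb)
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", ep)
        grads <- model_backward(model, fw$cache, ce_grad(fw$probs, yb))
        adm <- adam_step(params, grads, st, cfg$lr, cfg$beta1, cfg$beta2,
                         cfg$epsilon)
        params <- adm$params; st <- adm$state
        ep_loss <- ep_loss + loss * length(idx)
        ep_hit <- ep_hit + sum(max.col(t(fw$probs)) - 1L == yb)
      }
      model$params <- params
      te_acc <- if (length(yte))
        mean(predict_classes(model, Xte, normalized = TRUE) == yte) else NA
      hist <- rbind(hist, data.frame(
        epoch = ep, train_loss = ep_loss / n, train_accuracy = ep_hit / n,
        test_accuracy = te_acc))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, train acc %.4f, test acc %s",
                        ep, ep_loss / n, ep_hit / n, format(te_acc)))
    }
  })
  model$params <- params
  model$trained <- TRUE
  model$train_config <- cfg
  model$history <- hist
  if (length(yte)) {
    pte <- predict_proba(model, Xte, normalized = TRUE)
    model$test_accuracy <- mean(as.integer(pte >= 0.5) == yte)
    model$test_auc <- as.numeric(pROC::auc(pROC::roc(
      response = yte, predictor = pte, levels = c(0, 1),
      direction = "<", quiet = TRUE)))
  }
  model
}

#' Class-1 (bubble) probability for a matrix of segments
#'
#' @param model a trained `ucpwi_model`.
#' @param segments matrix, one row per length-60 window.
#' @param batch evaluation minibatch size.
#' @param normalized set when rows are already RMS-normalized.
#' @return numeric vector of bubble probabilities.
#' @export
predict_proba <- function(model, segments, batch = 512L,
                          normalized = FALSE) {
  stopifnot(inherits(model, "ucpwi_model"))
  if (!normalized) segments <- normalize_segments(segments)
  n <- nrow(segments)
  out <- numeric(n)
  for (b0 in seq.int(1L, n, by = batch)) {
    idx <- b0:min(b0 + batch - 1L, n)
    fw <- model_forward(model, segments[idx, , drop = FALSE], train = FALSE)
    out[idx] <- fw$probs[2L, ]
  }
  out
}

predict_classes <- function(model, segments, ...) {
  as.integer(predict_proba(model, segments, ...) >= 0.5)
}

#' Per-sample bubble mask for a channel-data frame
#'
#' Slides length-`length` windows by `step` along every element line,
#' scores each with the classifier, and assigns every RF sample the mean
#' bubble probability of all windows covering it; the mask thresholds
#' that mean at 0.5.  The mean over overlapping windows is independent
#' of scoring order.
#'
#' @param model a trained `ucpwi_model`.
#' @param data a `channel_data` frame.
#' @param length,step segmentation parameters.
#' @return an object of class `bubble_mask` with `mask` (0/1 integer
#'   matrix) and `prob`, both sized like `data$rf`.
#' @export
predict_mask <- function(model, data, length = 60L, step = 5L) {
  stopifnot(inherits(model, "ucpwi_model"), inherits(data, "channel_data"))
  if (!model$trained)
    stop("model has not been trained; call train_classifier() first")
  n <- nrow(data$rf); m <- ncol(data$rf)
  ds <- segment_rf(data, length, step)
  probs <- predict_proba(model, ds$segments)
  starts <- unique(ds$provenance$start)
  n_st <- base::length(starts)
  prob <- matrix(0, n, m)
  acc <- numeric(n + length)
  cnt <- numeric(n + length)
  for (i in seq_len(m)) {
    acc[] <- 0; cnt[] <- 0
    pr <- probs[((i - 1L) * n_st + 1L):(i * n_st)]
    acc[starts] <- pr
    acc[starts + length] <- acc[starts + length] - pr
    cnt[starts] <- 1
    cnt[starts + length] <- cnt[starts + length] - 1
    cum_a <- cumsum(acc)[1:n]
    cum_c <- cumsum(cnt)[1:n]
    prob[, i] <- ifelse(cum_c > 0, cum_a / pmax(cum_c, 1), 0)
  }
  structure(list(mask = (prob >= 0.5) + 0L, prob = prob),
            class = "bubble_mask")
}
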