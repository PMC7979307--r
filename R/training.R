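#' Training configuration
#'
#' Optimization settings for [train()]. Defaults follow the study protocol:
#' Adam with learning rate 0.0001, `beta1 = 0.9`, `beta2 = 0.999`
#' (`epsilon = 1e-8`), softmax cross-entropy loss. Epoch count, batch size
#' and the early-stopping rule are artifact choices (they are not part of
#' the published protocol) and are exposed here.
#'
#' @param learning_rate positive Adam step size.
#' @param beta1,beta2 Adam moment decay rates, in (0, 1).
#' @param epsilon Adam denominator fuzz.
#' @param epochs maximum number of passes over the training split.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling shuffling and dropout.
#' @param early_stop_patience stop after this many epochs without a new
#'   validation-loss minimum; `NULL` disables early stopping.
#' @param bn_momentum exponential-average momentum for batch-norm running
#'   statistics.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, epochs = 50L, batch_size = 32L,
                         seed = 1L, early_stop_patience = 10L,
                         bn_momentum = 0.9) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 early_stop_patience = if (is.null(early_stop_patience)) NULL
                                       else as.integer(early_stop_patience),
                 bn_momentum = bn_momentum),
            class = "train_config")
}

#' Softmax cross-entropy loss
#'
#' Mean over samples of `-log softmax(scores)[true class]`, evaluated in a
#' numerically stable log-sum-exp form (scores of +/-1000 do not overflow).
#' Scores are pre-softmax, one row per sample.
#'
#' @param scores numeric matrix, samples by classes (two columns for the
#'   binary task), or a length-`nclass` vector for a single sample.
#' @param labels integer class labels in `0:(nclass-1)`.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' cross_entropy_loss(c(0, 0), 0)        # log(2)
#' cross_entropy_loss(c(1000, -1000), 0) # 0, no overflow
cross_entropy_loss <- function(scores, labels) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (length(labels) != nrow(scores))
    stop("one label per score row required")
  if (any(!labels %in% (seq_len(ncol(scores)) - 1L)))
    stop("labels must lie in 0..", ncol(scores) - 1L)
  m <- apply(scores, 1, max)
  lse <- m + log(rowSums(exp(scores - m)))
  truth <- scores[cbind(seq_len(nrow(scores)), labels + 1L)]
  mean(lse - truth)
}

# Analytic gradient of cross_entropy_loss w.r.t. the scores (softmax minus
# one-hot, averaged over samples); used by tests against finite differences.
cross_entropy_grad <- function(scores, labels) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  p <- softmax_rows(scores)
  p[cbind(seq_len(nrow(p)), labels + 1L)] <-
    p[cbind(seq_len(nrow(p)), labels + 1L)] - 1
  p / nrow(p)
}

#' Train a model with Adam on softmax cross-entropy
#'
#' The iterative loop of the study design: training volumes are fed forward,
#' the softmax outputs are compared with the labels through cross-entropy,
#' and the weights are updated by Adam. After every epoch the validation
#' split is scored (inference mode); the returned model carries the weights
#' of the epoch with the lowest validation loss (earliest epoch on ties),
#' and training stops early once `early_stop_patience` epochs pass without
#' improvement. Volume intensities are standardized to zero mean / unit
#' variance using statistics of the training split only; the transform is
#' stored on the model and applied to every later input.
#'
#' @param model an untrained [build_model()] handle.
#' @param dataset a [generate_dataset()] result, or a list of volumes.
#' @param splits a [make_splits()] manifest aligned with `dataset` (needs
#'   non-empty train and validation splits).
#' @param config a [train_config()].
#' @param labels 0/1 labels, required when `dataset` is a plain list.
#' @param verbose print one line per epoch.
#' @return List with `model` (trained `cnn_model`) and `history` (data.frame
#'   of class `train_history`: per-epoch train loss, validation loss and
#'   accuracy, with attribute `best_epoch`).
#' @export
train <- function(model, dataset, splits, config = train_config(),
                  labels = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  if (inherits(dataset, "phantom_dataset")) {
    volumes <- lapply(dataset$samples, function(s) s$volume)
    labels <- dataset$labels
  } else {
    volumes <- dataset
    if (is.null(labels)) stop("labels required when dataset is a plain list")
  }
  n <- length(volumes)
  stopifnot(nrow(splits) == n)
  tr <- which(splits$split == "train")
  va <- which(splits$split == "validation")
  if (length(tr) == 0 || length(va) == 0)
    stop("train and validation splits must be non-empty")

  # shape-check and load the splits, then standardize from the training split
  model$standardize <- c(center = 0, scale = 1)
  Xtr <- as_batch_matrix(model, volumes[tr])
  ctr <- mean(Xtr); sc <- stats::sd(Xtr)
  if (!is.finite(sc) || sc == 0) sc <- 1
  model$standardize <- c(center = ctr, scale = sc)
  Xtr <- (Xtr - ctr) / sc
  ytr <- as.integer(labels[tr])
  Xva <- as_batch_matrix(model, volumes[va])
  yva <- as.integer(labels[va])

  comp <- model$compiled
  theta <- model$theta; state <- model$state
  mAdam <- numeric(length(theta)); vAdam <- numeric(length(theta))
  tstep <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric())
  best <- list(loss = Inf, epoch = 0L, theta = theta, state = state)

  for (ep in seq_len(config$epochs)) {
    ord <- run_seeded(config$seed + 7919L * ep, sample.int(length(tr)))
    bstarts <- seq(1L, length(ord), by = config$batch_size)
    ep_loss <- 0
    for (bi in seq_along(bstarts)) {
      idx <- ord[bstarts[bi]:min(bstarts[bi] + config$batch_size - 1L, length(ord))]
      step <- cpp_train_step(comp$desc, comp$drop, theta, state,
                             Xtr[, idx, drop = FALSE], ytr[idx],
                             config$bn_momentum,
                             (config$seed * 131071L + ep * 257L + bi) %% .Machine$integer.max)
      state <- step$state
      tstep <- tstep + 1L
      mAdam <- config$beta1 * mAdam + (1 - config$beta1) * step$grad
      vAdam <- config$beta2 * vAdam + (1 - config$beta2) * step$grad^2
      mhat <- mAdam / (1 - config$beta1^tstep)
      vhat <- vAdam / (1 - config$beta2^tstep)
      theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + config$epsilon)
      ep_loss <- ep_loss + step$loss * length(idx)
    }
    ep_loss <- ep_loss / length(ord)

    sva <- t(cpp_forward(comp$desc, comp$drop, theta, state, Xva))
    vloss <- cross_entropy_loss(sva, yva)
    vacc <- mean((softmax_rows(sva)[, 2] >= 0.5) == (yva == 1))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vloss, val_accuracy = vacc))
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val acc %.3f",
                      ep, ep_loss, vloss, vacc))
    if (vloss < best$loss) {
      best <- list(loss = vloss, epoch = ep, theta = theta, state = state)
    } else if (!is.null(config$early_stop_patience) &&
               ep - best$epoch >= config$early_stop_patience) {
      break
    }
  }

  model$theta <- best$theta
  model$state <- best$state
  model$trained <- TRUE
  model$train_config <- config
  class(hist) <- c("train_history", "data.frame")
  attr(hist, "best_epoch") <- best$epoch
  list(model = model, history = hist)
}

#' Validation-split metrics (repeatable)
#'
#' Scores the validation split of a manifest; may be called as often as the
#' iterate-and-improve loop requires.
#'
#' @param model a trained `cnn_model`.
#' @param dataset a `phantom_dataset` or list of volumes.
#' @param splits a [make_splits()] manifest.
#' @param labels labels when `dataset` is a plain list.
#' @return A [metrics()] report for the validation split.
#' @export
validate <- function(model, dataset, splits, labels = NULL) {
  eval_split(model, dataset, splits, "validation", labels)
}

#' Held-out test-split metrics (single use)
#'
#' The held-out test set exists to be used once, at the very end of the
#' study; this function records each manifest it has scored (keyed by the
#' manifest's content) and emits a warning when the same test split is
#' evaluated again in a session.
#'
#' @inheritParams validate
#' @return A [metrics()] report for the test split.
#' @export
evaluate_test <- function(model, dataset, splits, labels = NULL) {
  key <- paste(substr(splits$split, 1, 2), collapse = "")
  if (!is.null(.test_ledger[[key]])) {
    warning("test split already evaluated once; the held-out set should be used only once",
            call. = FALSE)
  }
  .test_ledger[[key]] <- .test_ledger[[key]] %||% 0L
  .test_ledger[[key]] <- .test_ledger[[key]] + 1L
  eval_split(model, dataset, splits, "test", labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
.test_ledger <- new.env(parent = emptyenv())

eval_split <- function(model, dataset, splits, which_split, labels = NULL) {
  if (inherits(dataset, "phantom_dataset")) {
    volumes <- lapply(dataset$samples, function(s) s$volume)
    labels <- dataset$labels
  } else {
    volumes <- dataset
    if (is.null(labels)) stop("labels required when dataset is a plain list")
  }
  idx <- which(splits$split == which_split)
  if (length(idx) == 0) stop("empty split: ", which_split)
  p <- predict(model, volumes[idx])
  y <- labels[idx]
  auc <- if (length(unique(y)) == 2L) roc_auc(y, p)$auc else NA_real_
  rep <- metrics(confusion(y, p), auc = auc)
  attr(rep, "probabilities") <- p
  attr(rep, "labels") <- y
  rep
}
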