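#' Convolutional block specification
#'
#' One block is conv -> (batch norm) -> activation -> dropout, in that
#' order. Only stride 1 with length-preserving (same) padding is
#' supported: the canonical architecture's printed flatten width of
#' 38,400 = 300 x 128 is only attainable if every block preserves the
#' 300-sample length.
#'
#' @param filters number of convolutional filters (>= 1).
#' @param kernel_size odd kernel length; the engine implements 3.
#' @param stride must be 1.
#' @param activation "relu" or "sigmoid".
#' @param batch_norm logical.
#' @param dropout_rate in [0, 1).
#' @return object of class \code{conv_block_spec}.
#' @export
conv_block_spec <- function(filters, kernel_size = 3, stride = 1,
                            activation = c("relu", "sigmoid"),
                            batch_norm = FALSE, dropout_rate = 0) {
  activation <- match.arg(activation)
  abort_if(filters < 1, "filters must be >= 1")
  abort_if(kernel_size != 3, "only kernel_size = 3 is implemented")
  abort_if(stride != 1, "only stride = 1 (length-preserving) is supported")
  abort_if(dropout_rate < 0 || dropout_rate >= 1, "dropout_rate must be in [0, 1)")
  structure(list(filters = as.integer(filters), kernel_size = 3L, stride = 1L,
                 activation = activation, batch_norm = isTRUE(batch_norm),
                 dropout_rate = dropout_rate),
            class = "conv_block_spec")
}

#' Model specification
#'
#' @param blocks list of [conv_block_spec()]s.
#' @param input_length beat length in samples (300).
#' @param dense_units width of the fully connected block.
#' @param output_classes number of output classes (softmax).
#' @return object of class \code{model_spec}.
#' @export
model_spec <- function(blocks, input_length = 300, dense_units = 32,
                       output_classes = 2) {
  abort_if(length(blocks) < 1, "at least one convolutional block is required")
  stopifnot(all(vapply(blocks, inherits, logical(1), "conv_block_spec")))
  structure(list(input_length = as.integer(input_length), blocks = blocks,
                 dense_units = as.integer(dense_units),
                 output_classes = as.integer(output_classes)),
            class = "model_spec")
}

#' The canonical four-block 1D CNN specification
#'
#' Input of 300 samples; blocks of 128 (ReLU, dropout 0.45), 16 (sigmoid,
#' dropout 0.1), 8 (batch norm, ReLU, dropout 0.05) and 128 (sigmoid,
#' dropout 0.4) filters, all kernel 3 / stride 1; flatten (38,400 units);
#' a 32-unit dense block; and a 2-class softmax output.
#'
#' @return a [model_spec()].
#' @export
canonical_spec <- function() {
  model_spec(list(
    conv_block_spec(128, activation = "relu", dropout_rate = 0.45),
    conv_block_spec(16, activation = "sigmoid", dropout_rate = 0.10),
    conv_block_spec(8, activation = "relu", batch_norm = TRUE,
                    dropout_rate = 0.05),
    conv_block_spec(128, activation = "sigmoid", dropout_rate = 0.40)
  ), input_length = 300, dense_units = 32, output_classes = 2)
}

#' Flatten width by shape propagation
#'
#' Propagates the sequence length through every block using the standard
#' output-length formula for padded convolutions, then multiplies by the
#' final block's filter count. For the canonical specification this yields
#' 38,400.
#'
#' @param spec a [model_spec()].
#' @return integer flatten width.
#' @export
flatten_width <- function(spec = canonical_spec()) {
  len <- spec$input_length
  for (blk in spec$blocks) {
    pad <- (blk$kernel_size - 1) / 2
    len <- floor((len + 2 * pad - blk$kernel_size) / blk$stride) + 1
  }
  as.integer(len * spec$blocks[[length(spec$blocks)]]$filters)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam at learning rate
#' 1e-3, batch size 200, categorical cross-entropy on one-hot labels,
#' Xavier weight initialisation with zero biases, and early stopping with
#' a patience of 30 monitored on the validation set. "Patience" counts
#' epochs by default; \code{patience_unit = "batches"} interprets it as
#' optimisation steps (converted to whole epochs, rounded up).
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param early_stop_patience patience for early stopping.
#' @param patience_unit "epochs" or "batches".
#' @param monitor "val_accuracy" (maximised) or "val_loss" (minimised).
#' @param max_epochs training epoch cap; must exceed the patience.
#' @param dense_activation activation of the dense block: "linear"
#'   (default -- the architecture description names an activation for
#'   every convolutional block and the softmax output but none for the
#'   dense block), "relu" or "sigmoid". A ReLU here can die wholesale
#'   because its inputs are all-positive sigmoid features; see the
#'   methods vignette.
#' @param seed integer seed governing initialisation, shuffling, dropout.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 200,
                         early_stop_patience = 30,
                         patience_unit = c("epochs", "batches"),
                         monitor = c("val_accuracy", "val_loss"),
                         max_epochs = 200,
                         dense_activation = c("linear", "relu", "sigmoid"),
                         seed = 1) {
  patience_unit <- match.arg(patience_unit)
  monitor <- match.arg(monitor)
  dense_activation <- match.arg(dense_activation)
  abort_if(learning_rate <= 0 || batch_size < 1 || early_stop_patience < 1 ||
             max_epochs < 1, "all training parameters must be positive")
  abort_if(patience_unit == "epochs" && early_stop_patience >= max_epochs,
           "early_stop_patience must be smaller than max_epochs")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 patience_unit = patience_unit, monitor = monitor,
                 max_epochs = as.integer(max_epochs),
                 dense_activation = dense_activation,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a model
#'
#' Minibatch Adam on categorical cross-entropy with per-epoch validation
#' monitoring and early stopping that restores the best-validation
#' weights. Fully deterministic under the configuration seed.
#'
#' @param model an untrained [build_model()] result.
#' @param train_split,val_split lists with \code{x} (beats matrix) and
#'   \code{y} (factor), e.g. from [dataset_split()].
#' @param config optional [train_config()] overriding the model's.
#' @param verbose print per-epoch progress.
#' @return the trained \code{beat_cnn}, with a \code{history} element
#'   (data.frame epoch/train_loss/train_acc/val_loss/val_acc) and
#'   \code{best_epoch}.
#' @export
train <- function(model, train_split, val_split, config = NULL,
                  verbose = FALSE) {
  if (!is.null(config)) model$config <- config
  cfg <- model$config
  abort_if(nrow(train_split$x) == 0 || nrow(val_split$x) == 0,
           "train and validation splits must be non-empty")
  abort_if(length(unique(as.character(train_split$y))) < 2,
           "training split contains a single class")
  classes <- c("normal", "obese")
  Ytr <- one_hot(train_split$y, classes)
  Yva <- one_hot(val_split$y, classes)
  # standardise amplitudes with one global centre/scale from the training
  # beats (recorded on the model and reapplied at prediction time); a
  # scalar scale preserves the beat morphology
  model$input_center <- mean(train_split$x)
  model$input_scale <- stats::sd(train_split$x)
  if (!is.finite(model$input_scale) || model$input_scale == 0) {
    model$input_scale <- 1
  }
  xtr <- scale_input(model, train_split$x)
  xva <- val_split$x # scaled by predict_probs
  n <- nrow(train_split$x)
  batches_per_epoch <- ceiling(n / cfg$batch_size)
  patience <- if (cfg$patience_unit == "batches") {
    max(1L, ceiling(cfg$early_stop_patience / batches_per_epoch))
  } else {
    cfg$early_stop_patience
  }
  state <- adam_init(model$params)
  best_val <- if (cfg$monitor == "val_accuracy") -Inf else Inf
  best_params <- model$params
  best_bn <- model$bn
  best_epoch <- 0L
  hist <- list()
  with_seed(derive_seed(cfg$seed, 7L), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0
      for (s in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        xb <- xtr[idx, , drop = FALSE]
        yb <- Ytr[idx, , drop = FALSE]
        fwd <- nn_forward(model, xb, training = TRUE, keep_cache = TRUE)
        ep_loss <- ep_loss + cross_entropy(fwd$probs, yb) * length(idx)
        ep_correct <- ep_correct + sum(max.col(fwd$probs) == max.col(yb))
        dLogits <- (fwd$probs - yb) / length(idx)
        bwd <- nn_backward(model, fwd, dLogits)
        # fold the minibatch statistics into the running batch-norm stats
        for (j in seq_along(model$spec$blocks)) {
          if (model$spec$blocks[[j]]$batch_norm) {
            model$bn[[j]]$mean <- 0.9 * model$bn[[j]]$mean +
              0.1 * fwd$caches[[j]]$batch_mu
            model$bn[[j]]$var <- 0.9 * model$bn[[j]]$var +
              0.1 * fwd$caches[[j]]$batch_var
          }
        }
        upd <- adam_step(model$params, bwd$grads, state, cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      val_probs <- predict_probs(model, xva)
      val_loss <- cross_entropy(val_probs, Yva)
      val_acc <- mean(max.col(val_probs) == max.col(Yva))
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = val_loss, val_acc = val_acc
      )
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, ep_loss / n, ep_correct / n, val_loss, val_acc))
      }
      metric <- if (cfg$monitor == "val_accuracy") val_acc else val_loss
      improved <- if (cfg$monitor == "val_accuracy") metric > best_val else metric < best_val
      if (improved) {
        best_val <- metric
        best_params <- model$params
        best_bn <- model$bn
        best_epoch <- epoch
      }
      if (epoch - best_epoch >= patience) break
    }
  })
  model$params <- best_params
  model$bn <- best_bn
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best_epoch
  model
}

#' Evaluate a model on one split
#'
#' @param model a trained \code{beat_cnn}.
#' @param split list with \code{x} and \code{y}.
#' @return list with \code{confusion} (2x2 matrix, rows = true class,
#'   columns = predicted class), \code{accuracy} and \code{percent}.
#' @export
evaluate <- function(model, split) {
  abort_if(nrow(split$x) == 0, "split is empty")
  pred <- predict_class(model, split$x)
  truth <- factor(as.character(split$y), levels = c("normal", "obese"))
  m <- table(truth, pred)
  cm <- matrix(as.integer(m), 2, 2,
               dimnames = list(true = c("normal", "obese"),
                               predicted = c("normal", "obese")))
  acc <- confusion_accuracy(cm)
  list(confusion = cm, accuracy = acc$fraction, percent = acc$percent)
}

#' Accuracy from a confusion matrix
#'
#' @param m square count matrix, rows = true class, columns = predicted.
#' @return list with \code{correct} (diagonal sum), \code{total},
#'   \code{fraction} and \code{percent} (rounded to the nearest integer).
#' @export
confusion_accuracy <- function(m) {
  m <- as.matrix(m)
  abort_if(length(m) == 0 || sum(m) == 0, "confusion matrix is empty")
  abort_if(nrow(m) != ncol(m), "confusion matrix must be square")
  correct <- sum(diag(m))
  total <- sum(m)
  list(correct = correct, total = total, fraction = correct / total,
       percent = round(100 * correct / total))
}
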