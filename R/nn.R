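# 1D convolutional network engine.
#
# Layers operate on activation matrices of shape (n * L) x C -- row
# (i - 1) * L + t holds sample t of record i, one column per channel. A
# stride-1, kernel-3, length-preserving convolution is one wide GEMM
# (A %*% [Wm Wz Wp], one column block per kernel tap) whose tap outputs
# are shifted by one sample within each record and summed, with zero
# ("same") padding at record edges. The shift/sum plumbing and the
# record-major flatten are compiled (src/conv1d.cpp); everything else is
# plain matrix algebra.

make_shift_idx <- function(n, L) {
  list(n = n, L = L)
}

# W has 3 * C_in rows (taps [t-1; t; t+1], each C_in wide); the compiled
# kernel wants the column-block layout [Wm Wz Wp]
w_to_cat <- function(W, C) {
  cbind(W[1:C, , drop = FALSE],
        W[(C + 1):(2 * C), , drop = FALSE],
        W[(2 * C + 1):(3 * C), , drop = FALSE])
}

conv_forward_k3 <- function(A, W, b, sh) {
  conv1d_fwd(A, w_to_cat(W, ncol(A)), b, sh$L)
}

conv_backward_k3 <- function(A, dY, W, sh, need_dA = TRUE) {
  res <- conv1d_bwd(A, dY, w_to_cat(W, ncol(A)), sh$L, need_dA)
  Cout <- ncol(dY)
  dWcat <- res$dWcat
  dW <- rbind(dWcat[, 1:Cout, drop = FALSE],
              dWcat[, (Cout + 1):(2 * Cout), drop = FALSE],
              dWcat[, (2 * Cout + 1):(3 * Cout), drop = FALSE])
  list(dW = dW, db = as.numeric(res$db),
       dA = if (need_dA) res$dA else NULL)
}

add_rowvec <- function(M, b) {
  M + matrix(b, nrow(M), length(b), byrow = TRUE)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# (n*L) x C  ->  n x (L*C), channel-major within each record
flatten_nlc <- function(A, n, L) {
  flatten_nlc_cpp(A, n, L)
}

unflatten_nlc <- function(Xf, n, L) {
  unflatten_nlc_cpp(Xf, n, L)
}

xavier_init <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained model from a specification
#'
#' Weights use Xavier (Glorot uniform) initialisation, biases start at
#' zero, batch-norm scales at one. Initialisation is drawn under the
#' configuration seed, so identical seeds give identical models.
#'
#' @param spec a [model_spec()].
#' @param config a [train_config()].
#' @return object of class \code{beat_cnn} with elements \code{spec},
#'   \code{config}, \code{params} (flat named list) and \code{bn}
#'   (running batch-norm statistics per block).
#' @export
build_model <- function(spec = canonical_spec(), config = train_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "train_config"))
  L <- spec$input_length
  with_seed(config$seed, {
    params <- list()
    bn <- list()
    c_in <- 1L
    for (j in seq_along(spec$blocks)) {
      blk <- spec$blocks[[j]]
      k <- blk$kernel_size
      params[[sprintf("conv%d.W", j)]] <-
        xavier_init(k * c_in, blk$filters, k * c_in, k * blk$filters)
      params[[sprintf("conv%d.b", j)]] <- numeric(blk$filters)
      if (blk$batch_norm) {
        params[[sprintf("conv%d.gamma", j)]] <- rep(1, blk$filters)
        params[[sprintf("conv%d.beta", j)]] <- numeric(blk$filters)
        bn[[j]] <- list(mean = numeric(blk$filters), var = rep(1, blk$filters))
      } else {
        bn[j] <- list(NULL)
      }
      c_in <- blk$filters
    }
    flat <- L * c_in
    params[["dense.W1"]] <- xavier_init(flat, spec$dense_units, flat,
                                        spec$dense_units)
    params[["dense.b1"]] <- numeric(spec$dense_units)
    params[["dense.W2"]] <- xavier_init(spec$dense_units, spec$output_classes,
                                        spec$dense_units, spec$output_classes)
    params[["dense.b2"]] <- numeric(spec$output_classes)
    structure(list(spec = spec, config = config, params = params, bn = bn),
              class = "beat_cnn")
  })
}

# forward pass; X is n x L. Returns probs, logits and (if keep_cache)
# everything needed for the backward pass. Dropout and batch statistics
# are only active when training = TRUE.
nn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  spec <- model$spec
  n <- nrow(X)
  L <- spec$input_length
  stopifnot(ncol(X) == L)
  sh <- make_shift_idx(n, L)
  A <- matrix(as.vector(t(X)), ncol = 1)
  caches <- list()
  eps <- 1e-5
  for (j in seq_along(spec$blocks)) {
    blk <- spec$blocks[[j]]
    W <- model$params[[sprintf("conv%d.W", j)]]
    b <- model$params[[sprintf("conv%d.b", j)]]
    Z <- conv_forward_k3(A, W, b, sh)
    cache <- list(A_in = if (keep_cache) A else NULL)
    if (blk$batch_norm) {
      gamma <- model$params[[sprintf("conv%d.gamma", j)]]
      beta <- model$params[[sprintf("conv%d.beta", j)]]
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(add_rowvec(Z, -mu)^2)
        cache$batch_mu <- mu
        cache$batch_var <- v
      } else {
        mu <- model$bn[[j]]$mean
        v <- model$bn[[j]]$var
      }
      inv_std <- 1 / sqrt(v + eps)
      Xhat <- add_rowvec(Z, -mu) * matrix(inv_std, nrow(Z), ncol(Z), byrow = TRUE)
      Z <- add_rowvec(Xhat * matrix(gamma, nrow(Z), ncol(Z), byrow = TRUE), beta)
      cache$Xhat <- if (keep_cache) Xhat else NULL
      cache$inv_std <- inv_std
    }
    if (blk$activation == "relu") {
      cache$pre_act <- if (keep_cache) Z else NULL
      A <- pmax(Z, 0)
    } else {
      A <- sigmoid(Z)
      cache$post_act <- if (keep_cache) A else NULL
    }
    if (training && blk$dropout_rate > 0) {
      mask <- (matrix(stats::runif(length(A)), nrow(A), ncol(A)) >=
                 blk$dropout_rate) / (1 - blk$dropout_rate)
      A <- A * mask
      cache$mask <- if (keep_cache) mask else NULL
    }
    caches[[j]] <- cache
  }
  feature_maps <- A # last conv block output, (n*L) x C_last
  Xf <- flatten_nlc(A, n, L)
  W1 <- model$params[["dense.W1"]]
  b1 <- model$params[["dense.b1"]]
  Z1 <- add_rowvec(Xf %*% W1, b1)
  H <- switch(model$config$dense_activation,
              linear = Z1,
              relu = pmax(Z1, 0),
              sigmoid = sigmoid(Z1))
  logits <- add_rowvec(H %*% model$params[["dense.W2"]],
                       model$params[["dense.b2"]])
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits, n = n)
  if (keep_cache) {
    out$caches <- caches
    out$sh <- sh
    out$Xf <- Xf
    out$Z1 <- Z1
    out$H <- H
    out$feature_maps <- feature_maps
  }
  out
}

# backward pass from dLogits; returns grads (named like params) and, when
# stop_at_conv = TRUE, only d(feature maps) of the last conv block without
# touching the convolutional stack (used by Grad-CAM++).
nn_backward <- function(model, fwd, dLogits, stop_at_conv = FALSE) {
  spec <- model$spec
  n <- fwd$n
  L <- spec$input_length
  grads <- list()
  grads[["dense.W2"]] <- crossprod(fwd$H, dLogits)
  grads[["dense.b2"]] <- colSums(dLogits)
  dH <- dLogits %*% t(model$params[["dense.W2"]])
  dZ1 <- switch(model$config$dense_activation,
                linear = dH,
                relu = dH * (fwd$Z1 > 0),
                sigmoid = {
                  s <- sigmoid(fwd$Z1)
                  dH * s * (1 - s)
                })
  grads[["dense.W1"]] <- crossprod(fwd$Xf, dZ1)
  grads[["dense.b1"]] <- colSums(dZ1)
  dXf <- dZ1 %*% t(model$params[["dense.W1"]])
  dA <- unflatten_nlc(dXf, n, L)
  if (stop_at_conv) {
    return(list(d_feature_maps = dA))
  }
  for (j in rev(seq_along(spec$blocks))) {
    blk <- spec$blocks[[j]]
    cache <- fwd$caches[[j]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dZ <- if (blk$activation == "relu") {
      dA * (cache$pre_act > 0)
    } else {
      dA * cache$post_act * (1 - cache$post_act)
    }
    if (blk$batch_norm) {
      gamma <- model$params[[sprintf("conv%d.gamma", j)]]
      Xhat <- cache$Xhat
      grads[[sprintf("conv%d.gamma", j)]] <- colSums(dZ * Xhat)
      grads[[sprintf("conv%d.beta", j)]] <- colSums(dZ)
      m <- nrow(dZ)
      dXhat <- dZ * matrix(gamma, m, ncol(dZ), byrow = TRUE)
      s1 <- colSums(dXhat)
      s2 <- colSums(dXhat * Xhat)
      dZ <- (dXhat - add_rowvec(Xhat * matrix(s2 / m, m, ncol(dZ), byrow = TRUE),
                                s1 / m)) *
        matrix(cache$inv_std, m, ncol(dZ), byrow = TRUE)
    }
    W <- model$params[[sprintf("conv%d.W", j)]]
    cb <- conv_backward_k3(cache$A_in, dZ, W, fwd$sh, need_dA = j > 1)
    grads[[sprintf("conv%d.W", j)]] <- cb$dW
    grads[[sprintf("conv%d.b", j)]] <- colSums(dZ)
    if (j > 1) dA <- cb$dA
  }
  list(grads = grads)
}

cross_entropy <- function(probs, Y) {
  -mean(rowSums(Y * log(probs + 1e-12)))
}

one_hot <- function(y, classes = c("normal", "obese")) {
  Y <- matrix(0, length(y), length(classes))
  Y[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Y
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# apply the input standardisation learned at training time (identity on
# an untrained model)
scale_input <- function(model, x) {
  (x - (model$input_center %||% 0)) / (model$input_scale %||% 1)
}

#' Class-probability predictions
#'
#' Inputs are standardised with the centring/scaling constants estimated
#' from the training split (stored on the model by [train()]).
#'
#' @param model a \code{beat_cnn}.
#' @param x beats matrix (n x input_length).
#' @param batch_size evaluation batch size (memory control only).
#' @return n x 2 matrix of class probabilities (columns normal, obese).
#' @export
predict_probs <- function(model, x, batch_size = 500) {
  x <- scale_input(model, x)
  n <- nrow(x)
  out <- matrix(NA_real_, n, model$spec$output_classes)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1, n)
    out[s:e, ] <- nn_forward(model, x[s:e, , drop = FALSE])$probs
  }
  colnames(out) <- c("normal", "obese")
  out
}

#' Predicted class labels
#' @inheritParams predict_probs
#' @return factor with levels normal, obese.
#' @export
predict_class <- function(model, x, batch_size = 500) {
  p <- predict_probs(model, x, batch_size)
  factor(c("normal", "obese")[max.col(p, ties.method = "first")],
         levels = c("normal", "obese"))
}
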