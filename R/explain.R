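# Grad-CAM++ adapted to 1D signals.
#
# For a class score S_c (the pre-softmax logit) and last-convolution
# feature maps A^k(t), the per-location weights are
#   alpha_k(t) = g_k(t)^2 / (2 g_k(t)^2 + sum_t' A^k(t') g_k(t')^3)
# with g_k(t) = dS_c / dA^k(t), the importance of map k is
#   w_k = sum_t alpha_k(t) * relu(g_k(t)),
# and the map is CAM(t) = relu(sum_k w_k A^k(t)), rescaled to max 1.
# The alpha closed form uses the standard power-of-gradient substitution
# for the second and third partial derivatives. Because every block is
# length-preserving, the feature maps already live on the 300-sample axis
# and no upsampling is needed.

cam_from_maps <- function(A, G, normalize = TRUE) {
  g2 <- G^2
  g3 <- g2 * G
  denom <- 2 * g2 + matrix(colSums(A * g3), nrow(A), ncol(A), byrow = TRUE)
  alpha <- ifelse(denom != 0, g2 / denom, 0)
  w <- colSums(alpha * pmax(G, 0))
  cam <- pmax(as.vector(A %*% w), 0)
  if (normalize) {
    mx <- max(cam)
    if (mx > 0) cam <- cam / mx
  }
  cam
}

#' Grad-CAM++ relevance for a batch of beats
#'
#' @param model a trained \code{beat_cnn} (must contain at least one
#'   convolutional block).
#' @param x beats matrix (n x input_length) or a single beat vector.
#' @param class_index 1 = normal, 2 = obese.
#' @param batch_size evaluation batch size.
#' @param normalize rescale each vector to maximum 1 (all-zero rows stay
#'   all-zero); \code{FALSE} returns raw rectified maps.
#' @param feature_maps which tensor of the last block counts as its
#'   feature maps: \code{"activation"} (the block output, the standard
#'   Grad-CAM reading) or \code{"preactivation"} (the convolution/batch
#'   norm output before the nonlinearity). With a sigmoid final block the
#'   activation maps carry a positive pedestal that flattens the CAM;
#'   the pre-activation variant is sparser (see the methods vignette).
#' @return n x input_length matrix of nonnegative relevance vectors.
#' @export
gradcampp_1d <- function(model, x, class_index, batch_size = 200,
                         normalize = TRUE,
                         feature_maps = c("activation", "preactivation")) {
  feature_maps <- match.arg(feature_maps)
  stopifnot(inherits(model, "beat_cnn"))
  abort_if(length(model$spec$blocks) == 0,
           "model has no convolutional layers; Grad-CAM++ is unsupported")
  abort_if(!class_index %in% seq_len(model$spec$output_classes),
           "class_index out of range")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- scale_input(model, x)
  L <- model$spec$input_length
  n <- nrow(x)
  out <- matrix(NA_real_, n, L)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1, n)
    xb <- x[s:e, , drop = FALSE]
    nb <- nrow(xb)
    fwd <- nn_forward(model, xb, training = FALSE, keep_cache = TRUE)
    dLogits <- matrix(0, nb, model$spec$output_classes)
    dLogits[, class_index] <- 1
    G <- nn_backward(model, fwd, dLogits, stop_at_conv = TRUE)$d_feature_maps
    A <- fwd$feature_maps
    if (feature_maps == "preactivation") {
      last <- length(model$spec$blocks)
      cache <- fwd$caches[[last]]
      if (model$spec$blocks[[last]]$activation == "relu") {
        Z <- cache$pre_act
        G <- G * (Z > 0)
      } else {
        S <- cache$post_act
        Z <- log(S / (1 - S)) # invert the sigmoid to recover the input
        G <- G * S * (1 - S)
      }
      A <- Z
    }
    for (i in seq_len(nb)) {
      rows <- ((i - 1) * L + 1):(i * L)
      out[s + i - 1, ] <- cam_from_maps(A[rows, , drop = FALSE],
                                        G[rows, , drop = FALSE], normalize)
    }
  }
  out
}

#' Class-level CAM profile over correctly classified beats
#'
#' Per-beat Grad-CAM++ vectors (each normalised to max 1, so
#' high-amplitude beats do not dominate; set \code{normalize = FALSE} for
#' raw maps) are averaged over exactly those beats of \code{class_label}
#' that the model classifies correctly.
#'
#' @param model trained model.
#' @param split list with \code{x}, \code{y} (e.g. [dataset_split()]).
#' @param class_label "normal" or "obese".
#' @param normalize average normalised (default) or raw CAM vectors.
#' @param feature_maps passed to [gradcampp_1d()].
#' @return object of class \code{class_cam_profile}: \code{class_label},
#'   \code{mean_cam} (length input_length) and \code{n_beats}.
#' @export
aggregate_class_cam <- function(model, split, class_label = c("normal", "obese"),
                                normalize = TRUE,
                                feature_maps = c("activation", "preactivation")) {
  class_label <- match.arg(class_label)
  feature_maps <- match.arg(feature_maps)
  class_index <- match(class_label, c("normal", "obese"))
  pred <- predict_class(model, split$x)
  sel <- which(as.character(split$y) == class_label & pred == split$y)
  abort_if(length(sel) == 0,
           sprintf("no correctly classified '%s' beats to aggregate", class_label))
  cams <- gradcampp_1d(model, split$x[sel, , drop = FALSE], class_index,
                       normalize = normalize, feature_maps = feature_maps)
  structure(list(class_label = class_label,
                 mean_cam = colMeans(cams),
                 n_beats = length(sel)),
            class = "class_cam_profile")
}

#' Overlap profile of the two class CAMs
#'
#' Pointwise arithmetic mean of the normal and obese class profiles: the
#' regions that matter to both classifications.
#'
#' @param profile_normal,profile_obese [aggregate_class_cam()] results (or
#'   plain numeric vectors of equal length).
#' @return numeric overlap vector.
#' @export
overlap_cam <- function(profile_normal, profile_obese) {
  a <- if (inherits(profile_normal, "class_cam_profile")) {
    profile_normal$mean_cam
  } else {
    profile_normal
  }
  b <- if (inherits(profile_obese, "class_cam_profile")) {
    profile_obese$mean_cam
  } else {
    profile_obese
  }
  abort_if(length(a) != length(b), "profiles differ in length")
  (a + b) / 2
}

#' Fraction of CAM mass inside a region
#'
#' Region bounds are 0-based half-open sample offsets \code{[start, end)}
#' into the beat axis, matching the beat-window convention (the R peak
#' sits at offset 100).
#'
#' @param cam_vector nonnegative relevance vector.
#' @param region_start,region_end 0-based half-open bounds,
#'   \code{0 <= start < end <= length(cam_vector)}.
#' @return mass fraction in [0, 1].
#' @export
localization_score <- function(cam_vector, region_start, region_end) {
  n <- length(cam_vector)
  abort_if(!(region_start >= 0 && region_start < region_end && region_end <= n),
           "region bounds must satisfy 0 <= start < end <= length")
  total <- sum(cam_vector)
  abort_if(total <= 0, "total CAM mass is zero; score undefined")
  sum(cam_vector[(region_start + 1):region_end]) / total
}

#' The T-wave difference window on the beat axis
#'
#' The synthetic generator's default class difference lives +150 to
#' +350 ms after the R peak; with the R peak at 0-based offset 100 and
#' 2 ms per sample this is the half-open sample window [175, 275).
#'
#' @return named vector with \code{start} and \code{end} (0-based).
#' @export
t_wave_window <- function() {
  c(start = 175L, end = 275L)
}
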