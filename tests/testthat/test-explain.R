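test_that("CAM vectors are nonnegative, length 300 and max-normalised", {
  m <- trained_tiny_model()
  ds <- dataset_small()
  te <- dataset_split(ds, "test")
  cams <- gradcampp_1d(m, te$x[1:5, ], class_index = 2)
  expect_equal(dim(cams), c(5, 300))
  expect_true(all(cams >= 0))
  expect_true(all(abs(apply(cams, 1, max) - 1) < 1e-12 |
                    apply(cams, 1, max) == 0))
})

test_that("single-filter toy network reproduces the closed-form CAM", {
  # one conv filter and an identity-like dense head: alpha reduces to
  # 1 / sum(relu-support), w = sum(alpha * relu(g)), cam ∝ relu(w * A)
  spec <- model_spec(list(conv_block_spec(1, activation = "relu",
                                          dropout_rate = 0)),
                     input_length = 8, dense_units = 2, output_classes = 2)
  m <- build_model(spec, train_config(batch_size = 2, early_stop_patience = 1,
                                      max_epochs = 2, seed = 9))
  x <- matrix(rnorm(8), 1, 8)
  fwd <- beatcam:::nn_forward(m, x, keep_cache = TRUE)
  A <- fwd$feature_maps # 8 x 1
  dLog <- matrix(c(0, 1), 1, 2)
  G <- beatcam:::nn_backward(m, fwd, dLog, stop_at_conv = TRUE)$d_feature_maps
  g2 <- G^2
  g3 <- G^3
  denom <- 2 * g2 + sum(A * g3)
  alpha <- ifelse(denom != 0, g2 / denom, 0)
  w <- sum(alpha * pmax(G, 0))
  expected <- pmax(A * w, 0)
  if (max(expected) > 0) expected <- expected / max(expected)
  got <- gradcampp_1d(m, x, 2)
  expect_equal(as.vector(got), as.vector(expected), tolerance = 1e-12)
})

test_that("CAM head gradients match finite differences on the class score", {
  spec <- model_spec(list(
    conv_block_spec(3, activation = "relu", dropout_rate = 0.2),
    conv_block_spec(2, activation = "sigmoid", dropout_rate = 0)
  ), input_length = 10, dense_units = 3, output_classes = 2)
  m <- build_model(spec, train_config(batch_size = 2, early_stop_patience = 1,
                                      max_epochs = 2, seed = 13,
                                      dense_activation = "relu"))
  x <- matrix(rnorm(3 * 10), 3, 10)
  fwd <- beatcam:::nn_forward(m, x, keep_cache = TRUE)
  A <- fwd$feature_maps
  dLog <- matrix(0, 3, 2)
  dLog[, 1] <- 1
  G <- beatcam:::nn_backward(m, fwd, dLog, stop_at_conv = TRUE)$d_feature_maps
  score_of <- function(Amat) {
    Xf <- beatcam:::flatten_nlc(Amat, 3, 10)
    Z1 <- beatcam:::add_rowvec(Xf %*% m$params[["dense.W1"]],
                               m$params[["dense.b1"]])
    H <- pmax(Z1, 0)
    L <- beatcam:::add_rowvec(H %*% m$params[["dense.W2"]],
                              m$params[["dense.b2"]])
    sum(L[, 1])
  }
  eps <- 1e-5
  set.seed(1)
  for (k in sample(length(A), 15)) {
    A2 <- A
    A2[k] <- A[k] + eps
    lp <- score_of(A2)
    A2[k] <- A[k] - eps
    lm <- score_of(A2)
    fd <- (lp - lm) / (2 * eps)
    denom <- max(abs(fd) + abs(G[k]), 1e-6)
    expect_lt(abs(fd - G[k]) / denom, 1e-3)
  }
})

test_that("class aggregation uses only correctly classified beats", {
  m <- trained_tiny_model()
  ds <- dataset_small()
  va <- dataset_split(ds, "val")
  pred <- predict_class(m, va$x)
  n_correct_obese <- sum(pred == va$y & va$y == "obese")
  prof <- aggregate_class_cam(m, va, "obese")
  expect_equal(prof$n_beats, n_correct_obese)
  expect_length(prof$mean_cam, 300)
  # two identical beats aggregate to the single-beat CAM
  i <- which(va$y == "obese" & pred == va$y)[1]
  twin <- list(x = va$x[c(i, i), , drop = FALSE],
               y = va$y[c(i, i)])
  p2 <- aggregate_class_cam(m, twin, "obese")
  expect_equal(p2$mean_cam, as.vector(gradcampp_1d(m, va$x[i, ], 2)),
               tolerance = 1e-12)
  # all-wrong split raises
  flipped <- list(x = va$x, y = factor(ifelse(va$y == "obese", "normal", "obese"),
                                       levels = c("normal", "obese")))
  expect_error(aggregate_class_cam(m, flipped, "obese"), "no correctly classified")
})

test_that("overlap is the pointwise mean of the class profiles", {
  a <- c(1, 0, 0.5, 0)
  b <- c(0, 1, 0.5, 0)
  expect_equal(overlap_cam(a, b), c(0.5, 0.5, 0.5, 0))
  expect_equal(overlap_cam(a, a), a)
  expect_equal(overlap_cam(a, rep(0, 4)), a / 2)
  expect_error(overlap_cam(a, c(1, 2)), "length")
})

test_that("localization score is the regional mass fraction", {
  cam <- rep(1, 300)
  expect_equal(localization_score(cam, 0, 150), 0.5)
  cam2 <- c(rep(0, 100), rep(1, 50), rep(0, 150))
  expect_equal(localization_score(cam2, 100, 150), 1)
  expect_error(localization_score(rep(0, 300), 0, 150), "zero")
  expect_error(localization_score(cam, 200, 100), "bounds")
  w <- t_wave_window()
  expect_equal(unname(w["end"] - w["start"]) / 300, 1 / 3, tolerance = 1e-9)
})
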