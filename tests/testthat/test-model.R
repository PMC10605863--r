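test_that("canonical spec matches the printed architecture", {
  spec <- canonical_spec()
  expect_length(spec$blocks, 4)
  expect_equal(vapply(spec$blocks, `[[`, integer(1), "filters"),
               c(128L, 16L, 8L, 128L))
  expect_equal(vapply(spec$blocks, `[[`, character(1), "activation"),
               c("relu", "sigmoid", "relu", "sigmoid"))
  expect_equal(vapply(spec$blocks, `[[`, numeric(1), "dropout_rate"),
               c(0.45, 0.1, 0.05, 0.4))
  expect_equal(vapply(spec$blocks, `[[`, logical(1), "batch_norm"),
               c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(flatten_width(spec), 38400L)
  expect_equal(spec$output_classes, 2L)
  expect_equal(spec$dense_units, 32L)
})

test_that("forward pass honours the shape and softmax contracts", {
  m <- build_model(tiny_spec(), train_config(seed = 5))
  X <- matrix(rnorm(5 * 300), 5, 300)
  p <- predict_probs(m, X)
  expect_equal(dim(p), c(5, 2))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  p0 <- predict_probs(m, matrix(0, 1, 300))
  expect_equal(sum(p0), 1, tolerance = 1e-12)
  # flatten width by actual shape propagation inside the engine
  fwd <- beatcam:::nn_forward(m, X, keep_cache = TRUE)
  expect_equal(ncol(fwd$Xf), flatten_width(tiny_spec()))
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(31)
  spec <- model_spec(list(
    conv_block_spec(3, activation = "relu", dropout_rate = 0),
    conv_block_spec(2, activation = "sigmoid", batch_norm = TRUE,
                    dropout_rate = 0)
  ), input_length = 12, dense_units = 4, output_classes = 2)
  m <- build_model(spec, train_config(batch_size = 4, early_stop_patience = 2,
                                      max_epochs = 5, seed = 7))
  X <- matrix(rnorm(5 * 12), 5, 12)
  y <- factor(c("normal", "obese", "normal", "obese", "normal"),
              levels = c("normal", "obese"))
  Y <- beatcam:::one_hot(y)
  loss_of <- function(mm) {
    beatcam:::cross_entropy(beatcam:::nn_forward(mm, X, training = TRUE)$probs, Y)
  }
  fwd <- beatcam:::nn_forward(m, X, training = TRUE, keep_cache = TRUE)
  g <- beatcam:::nn_backward(m, fwd, (fwd$probs - Y) / nrow(X))$grads
  eps <- 1e-5
  for (nm in names(g)) {
    for (k in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
      m2 <- m
      m2$params[[nm]][k] <- m$params[[nm]][k] + eps
      lp <- loss_of(m2)
      m2$params[[nm]][k] <- m$params[[nm]][k] - eps
      lm <- loss_of(m2)
      fd <- (lp - lm) / (2 * eps)
      expect_equal(g[[nm]][k], fd, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, k))
    }
  }
})

test_that("training learns a separable synthetic problem and is reproducible", {
  ds <- dataset_small()
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "val")
  cfg <- train_config(batch_size = 50, early_stop_patience = 3,
                      max_epochs = 8, seed = 303)
  m1 <- trained_tiny_model()
  expect_gte(max(m1$history$val_acc), 0.9)
  # early stopping: training stops no later than best_epoch + patience
  expect_lte(nrow(m1$history), m1$best_epoch + cfg$early_stop_patience)
  # reproducibility under identical seed
  m2 <- train(build_model(tiny_spec(), cfg), tr, va)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  expect_equal(m1$params[["dense.W2"]], m2$params[["dense.W2"]],
               tolerance = 1e-12)
  # single-class training split is rejected
  only_norm <- list(x = tr$x[tr$y == "normal", ], y = tr$y[tr$y == "normal"])
  expect_error(train(build_model(tiny_spec(), cfg), only_norm, va),
               "single class")
})

test_that("evaluate and confusion_accuracy agree and follow the matrix orientation", {
  m <- trained_tiny_model()
  ds <- dataset_small()
  te <- dataset_split(ds, "test")
  ev <- evaluate(m, te)
  expect_equal(sum(ev$confusion), length(te$y))
  expect_equal(ev$accuracy, confusion_accuracy(ev$confusion)$fraction)
  # row sums are the true class counts
  expect_equal(as.vector(rowSums(ev$confusion)),
               as.vector(table(te$y)))
})

test_that("confusion-matrix arithmetic reproduces the worked example", {
  m <- matrix(c(2018, 544, 99, 200), 2, 2,
              dimnames = list(true = c("normal", "obese"),
                              predicted = c("normal", "obese")))
  acc <- confusion_accuracy(m)
  expect_equal(acc$correct, 2218)
  expect_equal(acc$percent, 78)
  expect_equal(confusion_accuracy(diag(c(5, 5)))$percent, 100)
  # constant "normal" predictor on 8 normal + 2 obese
  expect_equal(confusion_accuracy(matrix(c(8, 2, 0, 0), 2, 2))$fraction, 0.8)
  expect_error(confusion_accuracy(matrix(0, 2, 2)), "empty")
})
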