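# shared fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a tiny model spec that trains in seconds but exercises every layer type
tiny_spec <- function(input_length = 300) {
  model_spec(list(
    conv_block_spec(8, activation = "relu", dropout_rate = 0.1),
    conv_block_spec(4, activation = "sigmoid", batch_norm = TRUE,
                    dropout_rate = 0)
  ), input_length = input_length, dense_units = 8, output_classes = 2)
}

# small written cohort on disk (4 per class, defaults)
cohort_dir_small <- function() {
  fixture("cohort_dir_small", function() {
    dir <- file.path(tempdir(), "beatcam-cohort-small")
    write_cohort(4, c("normal", "obese"), dir, seed = 101, effect_size = 1)
    dir
  })
}

# a modest two-class dataset for training-related tests
dataset_small <- function() {
  fixture("dataset_small", function() {
    synthetic_beat_dataset(15, effect_size = 1.5, seed = 202,
                           split_level = "beat")
  })
}

# a tiny trained model on the small dataset
trained_tiny_model <- function() {
  fixture("trained_tiny_model", function() {
    ds <- dataset_small()
    cfg <- train_config(batch_size = 50, early_stop_patience = 3,
                        max_epochs = 8, seed = 303)
    m <- build_model(tiny_spec(), cfg)
    train(m, dataset_split(ds, "train"), dataset_split(ds, "val"))
  })
}
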