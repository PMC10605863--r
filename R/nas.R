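# Compact neural-architecture-search harness over the structural and
# training hyperparameters of the 1D CNN: random search and a genetic
# algorithm (tournament selection, blockwise crossover, per-field
# mutation, elitism). Fitness is the early-stopped validation accuracy.

#' Hyperparameter search space
#'
#' Ranges for block count, filters, activation, batch norm, dropout, dense
#' width, learning rate and batch size. The default space contains the
#' canonical architecture. Kernel size and stride are fixed at 3 and 1 (the
#' length-preserving setting the engine supports).
#'
#' @param n_blocks integer vector of admissible block counts.
#' @param filters admissible filter counts.
#' @param activations admissible activation names.
#' @param batch_norm admissible batch-norm flags.
#' @param dropout_range length-2 range for dropout rates.
#' @param dense_units admissible dense widths.
#' @param learning_rates admissible learning rates.
#' @param batch_sizes admissible batch sizes.
#' @return object of class \code{search_space}.
#' @export
search_space <- function(n_blocks = 2:4,
                         filters = c(8, 16, 32, 64, 128),
                         activations = c("relu", "sigmoid"),
                         batch_norm = c(TRUE, FALSE),
                         dropout_range = c(0, 0.5),
                         dense_units = c(16, 32, 64),
                         learning_rates = c(1e-2, 1e-3, 1e-4),
                         batch_sizes = c(100, 200)) {
  abort_if(length(n_blocks) == 0 || length(filters) == 0 ||
             length(activations) == 0 || length(dense_units) == 0 ||
             length(learning_rates) == 0 || length(batch_sizes) == 0,
           "all search-space ranges must be non-empty")
  abort_if(dropout_range[1] < 0 || dropout_range[2] >= 1 ||
             dropout_range[1] > dropout_range[2],
           "dropout_range must lie in [0, 1)")
  structure(list(n_blocks = n_blocks, filters = filters,
                 activations = activations, batch_norm = batch_norm,
                 dropout_range = dropout_range, dense_units = dense_units,
                 learning_rates = learning_rates, batch_sizes = batch_sizes),
            class = "search_space")
}

#' Search budget
#'
#' The desk preset (10 trials of 10 epochs; 3 generations of 4) keeps a
#' search run in the minutes range on one CPU; the full preset (400
#' trials of 200 epochs; 20 generations of 20) is the full-scale setting
#' and is long-running.
#'
#' @param max_trials random-search trial count.
#' @param epochs_per_trial training epochs per evaluated candidate.
#' @param generations,population_size genetic-search shape.
#' @param seed root seed for the search.
#' @return object of class \code{search_budget}.
#' @export
search_budget <- function(max_trials = 10, epochs_per_trial = 10,
                          generations = 3, population_size = 4, seed = 1) {
  abort_if(any(c(max_trials, epochs_per_trial, generations,
                 population_size) < 1), "all budget fields must be >= 1")
  structure(list(max_trials = as.integer(max_trials),
                 epochs_per_trial = as.integer(epochs_per_trial),
                 generations = as.integer(generations),
                 population_size = as.integer(population_size),
                 seed = as.integer(seed)),
            class = "search_budget")
}

#' @rdname search_budget
#' @param preset "desk" or "full".
#' @export
budget_preset <- function(preset = c("desk", "full"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    search_budget(10, 10, 3, 4, seed)
  } else {
    search_budget(400, 200, 20, 20, seed)
  }
}

# a genome is the raw sampled hyperparameter list; specs/configs are
# derived views of it
sample_genome <- function(space) {
  nb <- if (length(space$n_blocks) == 1) space$n_blocks else sample(space$n_blocks, 1)
  blocks <- lapply(seq_len(nb), function(j) {
    list(filters = sample(space$filters, 1),
         activation = sample(space$activations, 1),
         batch_norm = sample(space$batch_norm, 1),
         dropout_rate = round(stats::runif(1, space$dropout_range[1],
                                           space$dropout_range[2]), 2))
  })
  list(blocks = blocks,
       dense_units = sample(space$dense_units, 1),
       learning_rate = sample(space$learning_rates, 1),
       batch_size = sample(space$batch_sizes, 1))
}

genome_to_spec <- function(genome) {
  model_spec(lapply(genome$blocks, function(b) {
    conv_block_spec(b$filters, activation = b$activation,
                    batch_norm = b$batch_norm, dropout_rate = b$dropout_rate)
  }), dense_units = genome$dense_units)
}

genome_key <- function(genome) {
  paste(utils::capture.output(utils::str(genome, digits.d = 6)), collapse = "|")
}

#' Sample a candidate from the search space
#'
#' @param space a [search_space()].
#' @param seed integer seed.
#' @return list with \code{spec} ([model_spec()]) and \code{config}
#'   ([train_config()]).
#' @export
sample_spec <- function(space, seed = 1) {
  g <- with_seed(seed, sample_genome(space))
  list(spec = genome_to_spec(g),
       config = train_config(learning_rate = g$learning_rate,
                             batch_size = g$batch_size, seed = seed))
}

#' Is a spec/config pair inside a search space?
#'
#' @param spec a [model_spec()].
#' @param config a [train_config()].
#' @param space a [search_space()].
#' @return TRUE if every field lies within the space's ranges.
#' @export
spec_in_space <- function(spec, config, space) {
  ok_blocks <- length(spec$blocks) %in% space$n_blocks &&
    all(vapply(spec$blocks, function(b) {
      b$filters %in% space$filters &&
        b$activation %in% space$activations &&
        b$batch_norm %in% space$batch_norm &&
        b$dropout_rate >= space$dropout_range[1] &&
        b$dropout_rate <= space$dropout_range[2]
    }, logical(1)))
  ok_blocks && spec$dense_units %in% space$dense_units &&
    config$learning_rate %in% space$learning_rates &&
    config$batch_size %in% space$batch_sizes
}

# default fitness: build, train with the trial budget, return the best
# validation accuracy; failures yield NA so the search continues
default_nas_fitness <- function(budget) {
  function(spec, config, data_splits) {
    cfg <- train_config(learning_rate = config$learning_rate,
                        batch_size = config$batch_size,
                        early_stop_patience = max(1, budget$epochs_per_trial - 1),
                        max_epochs = budget$epochs_per_trial,
                        seed = config$seed)
    fit <- try({
      m <- build_model(spec, cfg)
      m <- train(m, data_splits$train, data_splits$val)
      max(m$history$val_acc)
    }, silent = TRUE)
    if (inherits(fit, "try-error")) NA_real_ else fit
  }
}

#' Random architecture search
#'
#' Samples \code{max_trials} candidates, evaluates each by training, and
#' returns the best by validation accuracy together with the full trial
#' log. A failing trial is logged with NA fitness and the search continues.
#'
#' @param space a [search_space()].
#' @param budget a [search_budget()].
#' @param data_splits list with \code{train} and \code{val} split lists
#'   (each \code{x}/\code{y}).
#' @param fitness_fn optional \code{function(spec, config, data_splits)}
#'   returning a scalar fitness; defaults to training-based validation
#'   accuracy under the trial budget.
#' @return list with \code{best} (spec, config, fitness) and \code{log}
#'   (data.frame trial/fitness/spec description).
#' @export
random_search <- function(space, budget, data_splits, fitness_fn = NULL) {
  fitness_fn <- fitness_fn %||% default_nas_fitness(budget)
  rows <- list()
  best <- NULL
  for (trial in seq_len(budget$max_trials)) {
    cand <- sample_spec(space, derive_seed(budget$seed, trial))
    fit <- fitness_fn(cand$spec, cand$config, data_splits)
    rows[[trial]] <- data.frame(trial = trial, fitness = fit,
                                n_blocks = length(cand$spec$blocks),
                                spec = describe_spec(cand$spec, cand$config),
                                stringsAsFactors = FALSE)
    if (!is.na(fit) && (is.null(best) || fit > best$fitness)) {
      best <- list(spec = cand$spec, config = cand$config, fitness = fit)
    }
  }
  abort_if(is.null(best), "every trial failed")
  list(best = best, log = do.call(rbind, rows))
}

mutate_genome <- function(genome, space, rate) {
  maybe <- function(cur, resample) if (stats::runif(1) < rate) resample() else cur
  genome$blocks <- lapply(genome$blocks, function(b) {
    b$filters <- maybe(b$filters, function() sample(space$filters, 1))
    b$activation <- maybe(b$activation, function() sample(space$activations, 1))
    b$batch_norm <- maybe(b$batch_norm, function() sample(space$batch_norm, 1))
    b$dropout_rate <- maybe(b$dropout_rate, function() {
      round(stats::runif(1, space$dropout_range[1], space$dropout_range[2]), 2)
    })
    b
  })
  genome$dense_units <- maybe(genome$dense_units,
                              function() sample(space$dense_units, 1))
  genome$learning_rate <- maybe(genome$learning_rate,
                                function() sample(space$learning_rates, 1))
  genome$batch_size <- maybe(genome$batch_size,
                             function() sample(space$batch_sizes, 1))
  genome
}

crossover_genomes <- function(a, b) {
  # blockwise: the child inherits the block count of one parent and each
  # block (position-wise) from a random parent; scalar fields coin-flipped
  child <- if (stats::runif(1) < 0.5) a else b
  for (j in seq_along(child$blocks)) {
    donor <- if (stats::runif(1) < 0.5) a else b
    if (j <= length(donor$blocks)) child$blocks[[j]] <- donor$blocks[[j]]
  }
  for (f in c("dense_units", "learning_rate", "batch_size")) {
    child[[f]] <- if (stats::runif(1) < 0.5) a[[f]] else b[[f]]
  }
  child
}

#' Genetic architecture search
#'
#' Generational GA with tournament selection (size 2), blockwise
#' crossover, per-field mutation and single-individual elitism, so the
#' best fitness is non-decreasing across generations. Fitness values are
#' memoised by genome, so unchanged individuals are not retrained.
#'
#' @inheritParams random_search
#' @param mutation_rate per-field mutation probability.
#' @param crossover logical; disable to copy parents unchanged.
#' @return list with \code{best} (spec, config, fitness) and \code{log}
#'   (data.frame generation/individual/fitness/spec description).
#' @export
genetic_search <- function(space, budget, data_splits, fitness_fn = NULL,
                           mutation_rate = 0.1, crossover = TRUE) {
  abort_if(budget$population_size < 2, "population_size must be >= 2")
  fitness_fn <- fitness_fn %||% default_nas_fitness(budget)
  cache <- new.env(parent = emptyenv())
  eval_genome <- function(g, seed) {
    key <- genome_key(g)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cand_cfg <- train_config(learning_rate = g$learning_rate,
                             batch_size = g$batch_size, seed = seed)
    fit <- fitness_fn(genome_to_spec(g), cand_cfg, data_splits)
    cache[[key]] <- fit
    fit
  }
  rows <- list()
  best_genome <- NULL
  best_fit <- -Inf
  with_seed(derive_seed(budget$seed, 101L), {
    pop <- lapply(seq_len(budget$population_size),
                  function(i) sample_genome(space))
    for (gen in seq_len(budget$generations)) {
      fits <- vapply(seq_along(pop), function(i) {
        eval_genome(pop[[i]], derive_seed(budget$seed, gen * 1000L + i))
      }, numeric(1))
      for (i in seq_along(pop)) {
        rows[[length(rows) + 1L]] <- data.frame(
          generation = gen, individual = i, fitness = fits[i],
          spec = describe_spec(genome_to_spec(pop[[i]])),
          stringsAsFactors = FALSE)
        if (!is.na(fits[i]) && fits[i] > best_fit) {
          best_fit <- fits[i]
          best_genome <- pop[[i]]
        }
      }
      if (gen == budget$generations) break
      ranked <- order(fits, decreasing = TRUE, na.last = TRUE)
      elite <- pop[[ranked[1]]]
      tournament <- function() {
        pair <- sample.int(length(pop), 2)
        f1 <- fits[pair[1]]
        f2 <- fits[pair[2]]
        if (is.na(f2) || (!is.na(f1) && f1 >= f2)) pop[[pair[1]]] else pop[[pair[2]]]
      }
      offspring <- list(elite)
      while (length(offspring) < budget$population_size) {
        child <- if (crossover) {
          crossover_genomes(tournament(), tournament())
        } else {
          tournament()
        }
        child <- mutate_genome(child, space, mutation_rate)
        offspring[[length(offspring) + 1L]] <- child
      }
      pop <- offspring
    }
  })
  log <- do.call(rbind, rows)
  abort_if(is.null(best_genome), "every individual failed")
  list(best = list(spec = genome_to_spec(best_genome),
                   config = train_config(learning_rate = best_genome$learning_rate,
                                         batch_size = best_genome$batch_size,
                                         seed = budget$seed),
                   fitness = best_fit),
       log = log)
}

#' One-line description of a spec
#' @param spec a [model_spec()].
#' @param config optional [train_config()].
#' @return character scalar.
#' @export
describe_spec <- function(spec, config = NULL) {
  blocks <- vapply(spec$blocks, function(b) {
    sprintf("%d%s%s/do%.2f", b$filters, substr(b$activation, 1, 3),
            if (b$batch_norm) "+bn" else "", b$dropout_rate)
  }, character(1))
  s <- sprintf("[%s] dense%d", paste(blocks, collapse = " "), spec$dense_units)
  if (!is.null(config)) {
    s <- sprintf("%s lr%g bs%d", s, config$learning_rate, config$batch_size)
  }
  s
}
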