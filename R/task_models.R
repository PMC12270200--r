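# Task-specific shallow classifiers with Monte-Carlo-dropout uncertainty.

#' Specification of a task-specific shallow classifier
#'
#' Dense layers with ReLU activations, dropout after each hidden layer, and a
#' sigmoid output, trained with binary cross-entropy.
#'
#' @param input_dim Feature count after preprocessing.
#' @param hidden_dims Hidden layer widths (at most two layers; default one).
#' @param dropout_p Dropout probability in `[0.05, 0.50]` (0 allowed for
#'   deterministic ablations).
#' @param learning_rate,batch_size,epochs,optimizer,momentum Training
#'   hyperparameters; `optimizer` one of `"sgd"`, `"adamw"`, `"rmsprop"`.
#' @param scheduler Optional learning-rate schedule: `"none"`, `"step"`, or
#'   `"reduce_on_plateau"`, with `step_size` / `patience` / `gamma`.
#' @param weight_decay Decoupled L2 strength (AdamW only; default 0.01).
#'   High-dimensional blocks with linear signal benefit from larger values.
#' @param mc_rounds Default number of Monte-Carlo dropout forward passes.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout during training.
#' @return A validated list of class `task_model_spec`.
#' @export
task_model_spec <- function(input_dim, hidden_dims = 32L, dropout_p = 0.25,
                            learning_rate = 0.01, batch_size = 256L,
                            epochs = 100L, optimizer = c("adamw", "sgd", "rmsprop"),
                            momentum = 0.9, scheduler = c("none", "step", "reduce_on_plateau"),
                            step_size = 10L, patience = 5L, gamma = 0.5,
                            weight_decay = 0.01, mc_rounds = 30L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  scheduler <- match.arg(scheduler)
  input_dim <- check_count(input_dim, "input_dim")
  if (length(hidden_dims) < 1L || length(hidden_dims) > 2L || any(hidden_dims < 1)) {
    stopf("`hidden_dims` must list one or two positive layer widths (shallow network)")
  }
  if (dropout_p < 0 || dropout_p >= 1) stopf("`dropout_p` must be in [0, 1)")
  if (learning_rate <= 0) stopf("`learning_rate` must be positive")
  epochs <- check_count(epochs, "epochs")
  structure(list(input_dim = input_dim, hidden_dims = as.integer(hidden_dims),
                 dropout_p = dropout_p, learning_rate = learning_rate,
                 batch_size = check_count(batch_size, "batch_size"),
                 epochs = epochs, optimizer = optimizer, momentum = momentum,
                 scheduler = scheduler, step_size = as.integer(step_size),
                 patience = as.integer(patience), gamma = gamma,
                 weight_decay = weight_decay,
                 mc_rounds = check_count(mc_rounds, "mc_rounds"),
                 seed = as.integer(seed)),
            class = "task_model_spec")
}

#' Train a task-specific classifier
#'
#' Dropout is active during training (and later during Monte-Carlo
#' inference). Reproducible: the same spec and data give identical final
#' weights.
#'
#' @param x Scaled feature matrix (rows = sessions).
#' @param y Binary labels.
#' @param spec A [task_model_spec()].
#' @return A `park_task_model`: parameters, spec, per-epoch training losses,
#'   and a format version field.
#' @export
train_task_model <- function(x, y, spec) {
  stopifnot(inherits(spec, "task_model_spec"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (anyNA(x) || any(!is.finite(x))) stopf("features contain NA or non-finite values")
  if (length(unique(y)) < 2L) stopf("labels are single-class; need both classes to train")
  if (!all(y %in% c(0, 1))) stopf("labels must be binary 0/1")
  if (ncol(x) != spec$input_dim) {
    stopf("spec$input_dim is %d but x has %d columns", spec$input_dim, ncol(x))
  }
  fit <- with_seed(spec$seed, {
    params <- mlp_init(spec$input_dim, spec$hidden_dims)
    grad_fn <- function(params, idx) {
      cache <- mlp_forward(params, x[idx, , drop = FALSE],
                           dropout_p = spec$dropout_p, training = TRUE)
      list(loss = bce_loss(cache$prob, y[idx]),
           grads = mlp_backward(params, cache, y[idx]))
    }
    nn_train(params, grad_fn, nrow(x), spec)
  })
  structure(list(params = fit$params, spec = spec,
                 epoch_losses = fit$epoch_losses,
                 format_version = 1L),
            class = "park_task_model")
}

summarize_mc_samples <- function(samples, level) {
  alpha <- (1 - level) / 2
  qs <- t(apply(samples, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  out <- data.frame(
    mean_p = rowMeans(samples),
    sd_p = if (ncol(samples) > 1L) apply(samples, 1, stats::sd) else
      rep(0, nrow(samples)),
    ci_low = qs[, 1], ci_high = qs[, 2],
    T = ncol(samples))
  attr(out, "samples") <- samples
  attr(out, "level") <- level
  class(out) <- c("mc_prediction", "data.frame")
  out
}

#' Monte-Carlo dropout prediction
#'
#' Runs `T` stochastic forward passes with dropout active and summarizes the
#' per-row sigmoid outputs: sample mean, sample SD (n-1), and the empirical
#' percentile interval at `level`. The per-pass samples are retained in the
#' `"samples"` attribute so any interval convention can be recomputed.
#'
#' @param model A `park_task_model`.
#' @param x Feature matrix (same preprocessing as training).
#' @param T Number of forward passes (>= 1).
#' @param level Interval level (default 0.95).
#' @param seed Optional seed; if `NULL` the caller's RNG stream is used.
#' @return An `mc_prediction` data frame: `mean_p`, `sd_p`, `ci_low`,
#'   `ci_high`, `T`, one row per input row.
#' @export
mc_predict <- function(model, x, T = model$spec$mc_rounds, level = 0.95,
                       seed = NULL) {
  stopifnot(inherits(model, "park_task_model"))
  T <- check_count(T, "T")
  x <- as.matrix(x)
  run <- function() {
    vapply(seq_len(T), function(t) {
      mlp_forward(model$params, x, dropout_p = model$spec$dropout_p,
                  training = TRUE)$prob
    }, numeric(nrow(x)))
  }
  samples <- if (is.null(seed)) run() else with_seed(seed, run())
  samples <- matrix(samples, nrow = nrow(x), ncol = T)
  summarize_mc_samples(samples, level)
}

#' Hyperparameter search space for task models
#'
#' Mirrors the published search table: categorical batch sizes, uniform
#' learning rate on `[5e-5, 1]`, dropout uniform on `[0.05, 0.5]`, epochs
#' uniform integer on `[1, 300]`, the three optimizers, momentum uniform on
#' `[0.1, 1]`, and optional step / reduce-on-plateau schedules. Each
#' dimension is either `list(values = ...)` (categorical) or
#' `list(min =, max =, integer =)` (uniform).
#'
#' @param input_dim Feature count (fixed, not searched).
#' @return Named list of dimension specifications.
#' @export
task_search_space <- function(input_dim) {
  list(
    input_dim = list(values = input_dim),
    hidden_dims = list(values = c(16L, 32L, 64L)),
    batch_size = list(values = c(256L, 512L, 1024L)),
    learning_rate = list(min = 5e-5, max = 1),
    dropout_p = list(min = 0.05, max = 0.50),
    epochs = list(min = 1L, max = 300L, integer = TRUE),
    optimizer = list(values = c("sgd", "adamw", "rmsprop")),
    momentum = list(min = 0.1, max = 1.0),
    scheduler = list(values = c("none", "step", "reduce_on_plateau")),
    step_size = list(min = 1L, max = 30L, integer = TRUE),
    patience = list(min = 1L, max = 20L, integer = TRUE),
    gamma = list(min = 0.5, max = 0.95),
    mc_rounds = list(values = 30L))
}

sample_space <- function(space) {
  out <- lapply(space, function(dim) {
    if (!is.null(dim$values)) {
      if (length(dim$values) == 1L) dim$values else
        dim$values[[sample.int(length(dim$values), 1)]]
    } else if (isTRUE(dim$integer)) {
      sample(seq(dim$min, dim$max), 1)
    } else {
      stats::runif(1, dim$min, dim$max)
    }
  })
  out
}

#' Random hyperparameter search maximizing development-set AUROC
#'
#' Samples `budget` configurations from `space` (uniform over categorical
#' values, uniform or uniform-integer over ranges), trains each on the
#' training data, scores the Monte-Carlo mean probability on the development
#' set by AUROC, and returns the best spec (ties broken by earlier draw).
#' Trials whose training diverges (non-finite loss) are logged with `NA`
#' AUROC and skipped.
#'
#' @param space A search space as from [task_search_space()].
#' @param budget Number of configurations to try (>= 1).
#' @param x_train,y_train,x_dev,y_dev Training and development data.
#' @param seed Integer seed for sampling, training and scoring.
#' @return List with `best_spec`, `best_model`, `best_auroc`, and a `trials`
#'   data frame logging every configuration and its score.
#' @export
search_hyperparameters <- function(space, budget, x_train, y_train,
                                   x_dev, y_dev, seed = 1L) {
  budget <- check_count(budget, "budget")
  if (length(y_dev) == 0L) stopf("development set is empty")
  draws <- with_seed(seed, lapply(seq_len(budget), function(i) sample_space(space)))
  trials <- vector("list", budget)
  best <- list(auroc = -Inf, spec = NULL, model = NULL)
  for (i in seq_len(budget)) {
    d <- draws[[i]]
    spec <- task_model_spec(
      input_dim = d$input_dim, hidden_dims = d$hidden_dims,
      dropout_p = d$dropout_p, learning_rate = d$learning_rate,
      batch_size = d$batch_size, epochs = d$epochs, optimizer = d$optimizer,
      momentum = d$momentum, scheduler = d$scheduler, step_size = d$step_size,
      patience = d$patience, gamma = d$gamma, mc_rounds = d$mc_rounds,
      seed = child_seed(seed, sprintf("trial%d", i)))
    auroc <- NA_real_
    model <- NULL
    res <- tryCatch({
      model <- train_task_model(x_train, y_train, spec)
      mc <- mc_predict(model, x_dev, T = spec$mc_rounds,
                       seed = child_seed(seed, sprintf("score%d", i)))
      auroc <- roc_auc(y_dev, mc$mean_p)
      TRUE
    }, error = function(e) FALSE)
    trials[[i]] <- data.frame(
      trial = i, dev_auroc = auroc, learning_rate = d$learning_rate,
      dropout_p = d$dropout_p, epochs = d$epochs, optimizer = d$optimizer,
      batch_size = d$batch_size, hidden_dims = paste(d$hidden_dims, collapse = "+"),
      scheduler = d$scheduler, failed = !res)
    if (res && is.finite(auroc) && auroc > best$auroc) {
      best <- list(auroc = auroc, spec = spec, model = model)
    }
  }
  if (is.null(best$spec)) stopf("every trial failed; widen the budget or the space")
  list(best_spec = best$spec, best_model = best$model, best_auroc = best$auroc,
       trials = do.call(rbind, trials))
}
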