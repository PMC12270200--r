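# Minimal dense-network engine: He-initialized linear layers, ReLU, inverted
# dropout, sigmoid output, binary cross-entropy, analytic backprop, and the
# three optimizers used by the screening models (SGD with momentum, AdamW,
# RMSprop) with optional step / reduce-on-plateau learning-rate schedules.
# Written against base R matrix ops; parameters are plain lists of matrices
# so trained models serialize deterministically.

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

relu <- function(x) (x > 0) * x

sigmoid <- function(x) 1 / (1 + exp(-x))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Inverted dropout mask drawn from the current RNG stream.
dropout_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(n * m) >= p) / (1 - p), n, m)
}

mlp_init <- function(input_dim, hidden_dims) {
  sizes <- c(input_dim, hidden_dims, 1L)
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", l)]] <- he_init(sizes[l], sizes[l + 1])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1])
  }
  params
}

# Forward pass. `training = TRUE` draws fresh dropout masks from the current
# RNG stream (used both for SGD and for Monte-Carlo dropout at inference).
mlp_forward <- function(params, x, dropout_p = 0, training = FALSE) {
  n_layers <- length(params) / 2L
  a <- x
  cache <- list(a = list(a), mask = list())
  for (l in seq_len(n_layers - 1L)) {
    z <- a %*% params[[paste0("W", l)]]
    z <- sweep(z, 2, params[[paste0("b", l)]], "+")
    a <- relu(z)
    mask <- if (training) dropout_mask(nrow(a), ncol(a), dropout_p) else NULL
    if (!is.null(mask)) a <- a * mask
    cache$a[[l + 1L]] <- a
    cache$mask[l] <- list(mask)
  }
  z_out <- a %*% params[[paste0("W", n_layers)]]
  z_out <- sweep(z_out, 2, params[[paste0("b", n_layers)]], "+")
  cache$prob <- sigmoid(z_out)[, 1]
  cache
}

# Backprop of mean BCE through the cached forward pass.
mlp_backward <- function(params, cache, y) {
  n_layers <- length(params) / 2L
  n <- length(y)
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  delta <- matrix((cache$prob - y) / n, n, 1)
  for (l in seq(n_layers, 1L)) {
    a_prev <- cache$a[[l]]
    grads[[paste0("W", l)]] <- crossprod(a_prev, delta)
    grads[[paste0("b", l)]] <- colSums(delta)
    if (l > 1L) {
      da <- delta %*% t(params[[paste0("W", l)]])
      mask <- cache$mask[[l - 1L]]
      if (!is.null(mask)) da <- da * mask
      delta <- da * (cache$a[[l]] > 0)
    }
  }
  grads
}

# ---- optimizers ------------------------------------------------------------

opt_init <- function(optimizer, params, momentum = 0.9, weight_decay = 0.01) {
  e <- new.env(parent = emptyenv())
  e$kind <- optimizer
  e$momentum <- momentum
  e$weight_decay <- weight_decay
  e$t <- 0
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  e$m <- zeros
  e$v <- zeros
  e
}

opt_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (opt$kind == "sgd") {
      opt$v[[i]] <- opt$momentum * opt$v[[i]] + g
      params[[i]] <- params[[i]] - lr * opt$v[[i]]
    } else if (opt$kind == "adamw") {
      b1 <- 0.9; b2 <- 0.999
      opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
      opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g^2
      mhat <- opt$m[[i]] / (1 - b1^opt$t)
      vhat <- opt$v[[i]] / (1 - b2^opt$t)
      params[[i]] <- params[[i]] -
        lr * (mhat / (sqrt(vhat) + 1e-8) + opt$weight_decay * params[[i]])
    } else if (opt$kind == "rmsprop") {
      opt$v[[i]] <- 0.99 * opt$v[[i]] + 0.01 * g^2
      params[[i]] <- params[[i]] - lr * g / (sqrt(opt$v[[i]]) + 1e-8)
    } else {
      stopf("unknown optimizer '%s'", opt$kind)
    }
  }
  params
}

# ---- generic minibatch training loop ---------------------------------------
#
# `grad_fn(params, idx)` must return list(loss =, grads =) for the minibatch
# rows `idx`, drawing any dropout masks from the current RNG stream. Returns
# the trained parameters plus the per-epoch mean training loss.
nn_train <- function(params, grad_fn, n_obs, spec) {
  opt <- opt_init(spec$optimizer, params, momentum = spec$momentum %||% 0.9,
                  weight_decay = spec$weight_decay %||% 0.01)
  lr <- spec$learning_rate
  scheduler <- spec$scheduler %||% "none"
  gamma <- spec$gamma %||% 0.5
  best_loss <- Inf
  stale <- 0L
  epoch_losses <- numeric(spec$epochs)
  batch <- max(1L, min(spec$batch_size, n_obs))
  for (e in seq_len(spec$epochs)) {
    idx <- sample.int(n_obs)
    starts <- seq(1L, n_obs, by = batch)
    tot <- 0
    for (s in starts) {
      rows <- idx[s:min(s + batch - 1L, n_obs)]
      g <- grad_fn(params, rows)
      if (!is.finite(g$loss)) {
        stopf("non-finite training loss at epoch %d (learning rate too high?)", e)
      }
      params <- opt_step(opt, params, g$grads, lr)
      tot <- tot + g$loss * length(rows)
    }
    epoch_losses[e] <- tot / n_obs
    if (scheduler == "step") {
      if (e %% (spec$step_size %||% 10L) == 0L) lr <- lr * gamma
    } else if (scheduler == "reduce_on_plateau") {
      if (epoch_losses[e] < best_loss - 1e-8) {
        best_loss <- epoch_losses[e]
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= (spec$patience %||% 5L)) {
          lr <- lr * gamma
          stale <- 0L
        }
      }
    }
  }
  list(params = params, epoch_losses = epoch_losses)
}
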