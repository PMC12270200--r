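# Uncertainty-calibrated fusion network.
#
# Architecture: each modality's preprocessed feature vector is projected
# (linear -> ReLU -> MC dropout -> layer normalization) to a shared space;
# the three modality tokens are combined by scaled dot-product self-attention
# whose post-softmax weights toward key j are multiplied by exp(-eta * sigma_j)
# (sigma_j = the task model's MC-dropout predictive SD) and renormalized, so
# unreliable modalities are down-weighted; the contextualized vectors are
# concatenated with the three task-model mean probabilities and passed
# through a shallow head (hidden layer, ReLU, dropout, sigmoid). Trained with
# binary cross-entropy via analytic backprop. Prediction uses MC dropout with
# a percentile interval, and verdicts are withheld when the interval contains
# the decision threshold.

LN_EPS <- 1e-6

#' Fusion network hyperparameters
#'
#' @param projection_dim Shared projection width, one of 128/256/512 (any
#'   positive value accepted for toy configurations).
#' @param query_dim Query/key width for the attention, one of 32/64/128/256.
#' @param hidden_dim Fusion head hidden width, 4..128.
#' @param dropout_p Dropout probability.
#' @param eta Uncertainty-calibration strength in `[0.1, 100]` (0 allowed:
#'   calibration off).
#' @param mc_rounds Monte-Carlo dropout rounds `T` (default 30).
#' @param learning_rate,batch_size,epochs,optimizer,momentum,scheduler,step_size,patience,gamma,weight_decay
#'   Training settings as in [task_model_spec()].
#' @param decision_threshold Probability threshold for the screening verdict.
#' @param ci_level Level of the withholding interval (default 0.95).
#' @param seed Integer seed.
#' @return A validated list of class `fusion_spec`.
#' @export
fusion_spec <- function(projection_dim = 128L, query_dim = 64L, hidden_dim = 32L,
                        dropout_p = 0.25, eta = 1, mc_rounds = 30L,
                        learning_rate = 0.005, batch_size = 256L, epochs = 100L,
                        optimizer = c("adamw", "sgd", "rmsprop"), momentum = 0.9,
                        scheduler = c("none", "step", "reduce_on_plateau"),
                        step_size = 10L, patience = 5L, gamma = 0.5,
                        weight_decay = 0.01,
                        decision_threshold = 0.5, ci_level = 0.95, seed = 1L) {
  optimizer <- match.arg(optimizer)
  scheduler <- match.arg(scheduler)
  if (eta < 0) stopf("`eta` must be >= 0")
  if (dropout_p < 0 || dropout_p >= 1) stopf("`dropout_p` must be in [0, 1)")
  check_proportion(decision_threshold, "decision_threshold")
  if (ci_level <= 0 || ci_level >= 1) stopf("`ci_level` must be in (0, 1)")
  structure(list(
    projection_dim = check_count(projection_dim, "projection_dim"),
    query_dim = check_count(query_dim, "query_dim"),
    hidden_dim = check_count(hidden_dim, "hidden_dim"),
    dropout_p = dropout_p, eta = eta,
    mc_rounds = check_count(mc_rounds, "mc_rounds"),
    learning_rate = learning_rate,
    batch_size = check_count(batch_size, "batch_size"),
    epochs = check_count(epochs, "epochs"), optimizer = optimizer,
    momentum = momentum, scheduler = scheduler,
    step_size = as.integer(step_size), patience = as.integer(patience),
    gamma = gamma, weight_decay = weight_decay,
    decision_threshold = decision_threshold,
    ci_level = ci_level, seed = as.integer(seed)),
    class = "fusion_spec")
}

#' Initialize fusion network parameters
#'
#' @param input_dims Named integer vector of per-modality input widths
#'   (after preprocessing), in the order finger_tapping, smile, speech.
#' @param spec A [fusion_spec()].
#' @return Named list of parameter matrices/vectors.
#' @export
ufnet_init <- function(input_dims, spec) {
  stopifnot(length(input_dims) == 3L)
  P <- spec$projection_dim
  q <- spec$query_dim
  H <- spec$hidden_dim
  params <- list()
  for (m in 1:3) {
    params[[paste0("proj", m, "_W")]] <- he_init(input_dims[[m]], P)
    params[[paste0("proj", m, "_b")]] <- numeric(P)
  }
  params$Wq <- he_init(P, q); params$bq <- numeric(q)
  params$Wk <- he_init(P, q); params$bk <- numeric(q)
  params$Wv <- he_init(P, P); params$bv <- numeric(P)
  params$head_W1 <- he_init(3L * P + 3L, H); params$head_b1 <- numeric(H)
  params$head_W2 <- he_init(H, 1L); params$head_b2 <- numeric(1L)
  params
}

row_layernorm <- function(a) {
  mu <- rowMeans(a)
  c0 <- a - mu
  v <- rowMeans(c0^2)
  inv <- 1 / sqrt(v + LN_EPS)
  list(h = c0 * inv, inv = inv)
}

#' Project one modality into the shared fusion space
#'
#' Linear map, ReLU, (optional) MC dropout, then layer normalization: each
#' output row has mean 0 and variance 1 up to the normalizer's epsilon;
#' all-zero pre-normalization rows map to the zero vector.
#'
#' @param x Numeric vector or matrix (rows = sessions) of the modality's
#'   trained input width.
#' @param proj List with `W` (input x projection_dim) and `b`.
#' @param dropout_p Dropout probability (0 disables).
#' @param training Draw a dropout mask from the current RNG stream.
#' @return Matrix of projected rows (projection_dim columns).
#' @export
project_modality <- function(x, proj, dropout_p = 0, training = FALSE) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != nrow(proj$W)) {
    stopf("input width %d does not match trained width %d", ncol(x), nrow(proj$W))
  }
  z <- sweep(x %*% proj$W, 2, proj$b, "+")
  a <- relu(z)
  if (training && dropout_p > 0) {
    a <- a * dropout_mask(nrow(a), ncol(a), dropout_p)
  }
  row_layernorm(a)$h
}

#' Uncertainty-calibrated self-attention over the three modality tokens
#'
#' Scaled dot-product self-attention in which the post-softmax weight toward
#' key `j` is multiplied by `exp(-eta * sigma_j)` and each row renormalized
#' to sum 1. With `eta = 0` or equal sigmas this reduces exactly to standard
#' softmax attention.
#'
#' @param projections List of three projected vectors (or matrices with one
#'   row per session) of equal width.
#' @param sigmas Three nonnegative task-model uncertainties (or a matrix with
#'   3 columns, one row per session).
#' @param params Attention parameters `Wq, bq, Wk, bk, Wv, bv` (e.g. from
#'   [ufnet_init()]).
#' @param eta Calibration strength.
#' @return List with `contexts` (list of three contextualized matrices) and
#'   `weights` (a 3x3 matrix for single vectors, else a B x 3 x 3 array;
#'   rows sum to 1).
#' @export
calibrated_attention <- function(projections, sigmas, params, eta) {
  single <- is.null(dim(projections[[1]]))
  H <- lapply(projections, function(h) if (is.null(dim(h))) matrix(h, 1) else as.matrix(h))
  B <- nrow(H[[1]])
  sig <- if (is.null(dim(sigmas))) matrix(sigmas, B, 3, byrow = TRUE) else as.matrix(sigmas)
  if (any(sig < 0)) stopf("sigmas must be nonnegative")
  fwd <- attention_forward(H, sig, params, eta)
  weights <- if (single) {
    w <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) w[i, j] <- fwd$w[[i]][[j]][1]
    w
  } else {
    arr <- array(0, c(B, 3, 3))
    for (i in 1:3) for (j in 1:3) arr[, i, j] <- fwd$w[[i]][[j]]
    arr
  }
  contexts <- if (single) lapply(fwd$ctx, function(m) m[1, ]) else fwd$ctx
  list(contexts = contexts, weights = weights)
}

# Attention forward over three tokens; H = list of B x P matrices,
# sig = B x 3 matrix of uncertainties. Returns Q, K, V, softmax weights a,
# calibrated weights w, normalizers, contexts.
attention_forward <- function(H, sig, params, eta) {
  q <- ncol(params$Wq)
  Q <- lapply(H, function(h) sweep(h %*% params$Wq, 2, params$bq, "+"))
  K <- lapply(H, function(h) sweep(h %*% params$Wk, 2, params$bk, "+"))
  V <- lapply(H, function(h) sweep(h %*% params$Wv, 2, params$bv, "+"))
  cfac <- exp(-eta * sig)  # B x 3
  S <- a <- u <- w <- vector("list", 3)
  Tn <- vector("list", 3)
  for (i in 1:3) {
    S[[i]] <- lapply(1:3, function(j) rowSums(Q[[i]] * K[[j]]) / sqrt(q))
    smax <- pmax(S[[i]][[1]], S[[i]][[2]], S[[i]][[3]])
    e <- lapply(1:3, function(j) exp(S[[i]][[j]] - smax))
    esum <- e[[1]] + e[[2]] + e[[3]]
    a[[i]] <- lapply(1:3, function(j) e[[j]] / esum)
    u[[i]] <- lapply(1:3, function(j) a[[i]][[j]] * cfac[, j])
    Tn[[i]] <- u[[i]][[1]] + u[[i]][[2]] + u[[i]][[3]]
    w[[i]] <- lapply(1:3, function(j) u[[i]][[j]] / Tn[[i]])
  }
  ctx <- lapply(1:3, function(i) {
    w[[i]][[1]] * V[[1]] + w[[i]][[2]] * V[[2]] + w[[i]][[3]] * V[[3]]
  })
  list(Q = Q, K = K, V = V, a = a, w = w, Tn = Tn, ctx = ctx, cfac = cfac)
}

# Full forward pass. Xs: list of 3 B x d_m matrices; pbar, sig: B x 3.
ufnet_forward <- function(params, Xs, pbar, sig, spec, training = FALSE) {
  P <- spec$projection_dim
  cache <- list(Xs = Xs)
  H <- Z <- Mk <- Inv <- vector("list", 3)
  for (m in 1:3) {
    z <- sweep(Xs[[m]] %*% params[[paste0("proj", m, "_W")]], 2,
               params[[paste0("proj", m, "_b")]], "+")
    r <- relu(z)
    mask <- if (training) dropout_mask(nrow(r), ncol(r), spec$dropout_p) else NULL
    a <- if (is.null(mask)) r else r * mask
    ln <- row_layernorm(a)
    Z[[m]] <- z; Mk[m] <- list(mask); H[[m]] <- ln$h; Inv[[m]] <- ln$inv
  }
  att <- attention_forward(H, sig, params, spec$eta)
  U <- cbind(att$ctx[[1]], att$ctx[[2]], att$ctx[[3]], pbar)
  z1 <- sweep(U %*% params$head_W1, 2, params$head_b1, "+")
  r1 <- relu(z1)
  mask_h <- if (training) dropout_mask(nrow(r1), ncol(r1), spec$dropout_p) else NULL
  a1 <- if (is.null(mask_h)) r1 else r1 * mask_h
  z2 <- sweep(a1 %*% params$head_W2, 2, params$head_b2, "+")
  cache$Z <- Z; cache$Mk <- Mk; cache$H <- H; cache$Inv <- Inv
  cache$att <- att; cache$U <- U; cache$z1 <- z1; cache$a1 <- a1
  cache$mask_h <- mask_h
  cache$prob <- sigmoid(z2)[, 1]
  cache
}

# Analytic gradients of mean BCE wrt every parameter.
ufnet_backward <- function(params, cache, y, spec) {
  B <- length(y)
  P <- spec$projection_dim
  q <- ncol(params$Wq)
  att <- cache$att
  g <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))

  delta2 <- matrix((cache$prob - y) / B, B, 1)
  g$head_W2 <- crossprod(cache$a1, delta2)
  g$head_b2 <- colSums(delta2)
  da1 <- delta2 %*% t(params$head_W2)
  if (!is.null(cache$mask_h)) da1 <- da1 * cache$mask_h
  dz1 <- da1 * (cache$z1 > 0)
  g$head_W1 <- crossprod(cache$U, dz1)
  g$head_b1 <- colSums(dz1)
  dU <- dz1 %*% t(params$head_W1)

  dctx <- lapply(1:3, function(i) dU[, ((i - 1) * P + 1):(i * P), drop = FALSE])
  # (gradient wrt pbar columns is not needed: task models are locked inputs)

  dV <- lapply(1:3, function(j) {
    att$w[[1]][[j]] * dctx[[1]] + att$w[[2]][[j]] * dctx[[2]] +
      att$w[[3]][[j]] * dctx[[3]]
  })
  dS <- vector("list", 3)
  for (i in 1:3) {
    dw <- lapply(1:3, function(j) rowSums(dctx[[i]] * att$V[[j]]))
    wdot <- dw[[1]] * att$w[[i]][[1]] + dw[[2]] * att$w[[i]][[2]] +
      dw[[3]] * att$w[[i]][[3]]
    du <- lapply(1:3, function(j) (dw[[j]] - wdot) / att$Tn[[i]])
    da <- lapply(1:3, function(j) du[[j]] * att$cfac[, j])
    adot <- da[[1]] * att$a[[i]][[1]] + da[[2]] * att$a[[i]][[2]] +
      da[[3]] * att$a[[i]][[3]]
    dS[[i]] <- lapply(1:3, function(j) att$a[[i]][[j]] * (da[[j]] - adot))
  }
  dQ <- lapply(1:3, function(i) {
    (dS[[i]][[1]] * att$K[[1]] + dS[[i]][[2]] * att$K[[2]] +
       dS[[i]][[3]] * att$K[[3]]) / sqrt(q)
  })
  dK <- lapply(1:3, function(j) {
    (dS[[1]][[j]] * att$Q[[1]] + dS[[2]][[j]] * att$Q[[2]] +
       dS[[3]][[j]] * att$Q[[3]]) / sqrt(q)
  })
  dH <- vector("list", 3)
  for (m in 1:3) {
    g$Wq <- g$Wq + crossprod(cache$H[[m]], dQ[[m]])
    g$bq <- g$bq + colSums(dQ[[m]])
    g$Wk <- g$Wk + crossprod(cache$H[[m]], dK[[m]])
    g$bk <- g$bk + colSums(dK[[m]])
    g$Wv <- g$Wv + crossprod(cache$H[[m]], dV[[m]])
    g$bv <- g$bv + colSums(dV[[m]])
    dH[[m]] <- dQ[[m]] %*% t(params$Wq) + dK[[m]] %*% t(params$Wk) +
      dV[[m]] %*% t(params$Wv)
  }
  for (m in 1:3) {
    h <- cache$H[[m]]
    dh <- dH[[m]]
    da <- cache$Inv[[m]] * (dh - rowMeans(dh) - h * rowMeans(dh * h))
    if (!is.null(cache$Mk[[m]])) da <- da * cache$Mk[[m]]
    dz <- da * (cache$Z[[m]] > 0)
    g[[paste0("proj", m, "_W")]] <- crossprod(cache$Xs[[m]], dz)
    g[[paste0("proj", m, "_b")]] <- colSums(dz)
  }
  g
}

prepare_modality_matrix <- function(sessions, pipeline) {
  x <- get_modality_matrix(sessions, pipeline$modality)
  apply_scaler(pipeline$scaler, x)[, pipeline$keep, drop = FALSE]
}

#' Fit a per-modality preprocessing + classifier pipeline
#'
#' Fits the scaler and correlation-based feature selection on the training
#' sessions of one modality (sessions with that block missing are dropped),
#' optionally SMOTE-oversamples the minority class, and trains the task
#' classifier.
#'
#' @param sessions Wide session table (training split).
#' @param modality Modality name.
#' @param spec A [task_model_spec()] whose `input_dim` may be `NULL`; it is
#'   set to the post-selection width.
#' @param scaler_kind `"standardize"` or `"minmax"`.
#' @param corr_threshold Absolute-correlation cutoff, or `NULL` to keep all.
#' @param smote_ratio Minority:majority target ratio, or `NULL` to disable.
#' @param smote_k SMOTE neighbor count.
#' @return A `park_task_pipeline`: modality, scaler, kept indices, model.
#' @export
fit_task_pipeline <- function(sessions, modality, spec = NULL,
                              scaler_kind = "standardize",
                              corr_threshold = NULL, smote_ratio = NULL,
                              smote_k = 5L) {
  x <- get_modality_matrix(sessions, modality)
  present <- !is.na(x[, 1])
  x <- x[present, , drop = FALSE]
  y <- sessions$label_at_session[present]
  scaler <- fit_scaler(x, scaler_kind)
  xs <- apply_scaler(scaler, x)
  keep <- if (is.null(corr_threshold)) seq_len(ncol(xs)) else
    select_features_by_correlation(xs, corr_threshold)
  xs <- xs[, keep, drop = FALSE]
  if (is.null(spec)) spec <- task_model_spec(input_dim = length(keep))
  spec$input_dim <- length(keep)
  if (!is.null(smote_ratio)) {
    aug <- smote_oversample(xs, y, k = smote_k, target_ratio = smote_ratio,
                            seed = child_seed(spec$seed, paste0("smote-", modality)))
    xs <- aug$x
    y <- aug$y
  }
  model <- train_task_model(xs, y, spec)
  structure(list(modality = modality, scaler = scaler, keep = keep,
                 model = model, format_version = 1L),
            class = "park_task_pipeline")
}

#' @rdname fit_task_pipeline
#' @param pipeline A fitted `park_task_pipeline`.
#' @param T,level,seed Passed to [mc_predict()].
#' @export
predict_task <- function(pipeline, sessions, T = pipeline$model$spec$mc_rounds,
                         level = 0.95, seed = NULL) {
  x <- prepare_modality_matrix(sessions, pipeline)
  mc_predict(pipeline$model, x, T = T, level = level, seed = seed)
}

check_complete <- function(sessions) {
  complete <- is_complete_session(sessions)
  if (!all(complete)) {
    bad <- session_ids(sessions)[!complete]
    stopf("fusion requires complete sessions; missing a modality block: %s%s",
          paste(utils::head(bad, 3), collapse = ", "),
          if (length(bad) > 3) sprintf(" (+%d more)", length(bad) - 3) else "")
  }
  invisible(TRUE)
}

#' Train the uncertainty-calibrated fusion network
#'
#' Task models are locked: their mean probabilities and MC-dropout SDs are
#' computed once per training session (T task-level passes) and enter the
#' fusion network as fixed inputs; only the fusion parameters are updated.
#' All training sessions must be complete (all three blocks present).
#'
#' With `cross_fit_folds > 1` the probabilities and SDs used *during fusion
#' training* come from out-of-fold task models (same specs, retrained on the
#' fold complements, folds assigned by participant): shallow task networks
#' typically separate their own training set perfectly, so their in-sample
#' probabilities are degenerate and would teach the fusion head to
#' over-trust them. Inference always uses the locked full task models.
#'
#' @param sessions Wide session table of complete sessions (training split).
#' @param pipelines Named list of three `park_task_pipeline`s
#'   (`finger_tapping`, `smile`, `speech`).
#' @param spec A [fusion_spec()].
#' @param cross_fit_folds Folds for out-of-fold task probabilities during
#'   fusion training (1 = use the locked models' in-sample outputs).
#' @return A `park_ufnet`: parameters, spec, pipelines, input dims, task
#'   model content hashes, training losses, and a format version field.
#' @export
train_ufnet <- function(sessions, pipelines, spec, cross_fit_folds = 2L) {
  stopifnot(inherits(spec, "fusion_spec"))
  if (!all(MODALITIES %in% names(pipelines))) {
    stopf("`pipelines` must name all of: %s", paste(MODALITIES, collapse = ", "))
  }
  check_complete(sessions)
  cross_fit_folds <- check_count(cross_fit_folds, "cross_fit_folds")
  Xs <- lapply(MODALITIES, function(m) prepare_modality_matrix(sessions, pipelines[[m]]))
  y_all <- as.numeric(sessions$label_at_session)
  if (cross_fit_folds > 1L) {
    fold <- (match(sessions$participant_id, unique(sessions$participant_id)) - 1L) %%
      cross_fit_folds
    pbar <- sig <- matrix(0, nrow(sessions), 3)
    for (j in seq_along(MODALITIES)) {
      m <- MODALITIES[j]
      for (k in seq_len(cross_fit_folds) - 1L) {
        sub <- fold != k
        fold_spec <- pipelines[[m]]$model$spec
        fold_spec$seed <- child_seed(spec$seed, sprintf("cf-%s-%d", m, k))
        fm <- train_task_model(Xs[[j]][sub, , drop = FALSE], y_all[sub],
                               fold_spec)
        mk <- mc_predict(fm, Xs[[j]][!sub, , drop = FALSE], T = spec$mc_rounds,
                         seed = child_seed(spec$seed, sprintf("cfmc-%s-%d", m, k)))
        pbar[!sub, j] <- mk$mean_p
        sig[!sub, j] <- mk$sd_p
      }
    }
  } else {
    task_mc <- lapply(MODALITIES, function(m) {
      predict_task(pipelines[[m]], sessions, T = spec$mc_rounds,
                   seed = child_seed(spec$seed, paste0("taskmc-", m)))
    })
    pbar <- do.call(cbind, lapply(task_mc, function(p) p$mean_p))
    sig <- do.call(cbind, lapply(task_mc, function(p) p$sd_p))
  }
  y <- as.numeric(sessions$label_at_session)
  dims <- vapply(Xs, ncol, integer(1))
  names(dims) <- MODALITIES
  fit <- with_seed(spec$seed, {
    params <- ufnet_init(dims, spec)
    grad_fn <- function(params, idx) {
      cache <- ufnet_forward(params,
                             lapply(Xs, function(x) x[idx, , drop = FALSE]),
                             pbar[idx, , drop = FALSE], sig[idx, , drop = FALSE],
                             spec, training = TRUE)
      list(loss = bce_loss(cache$prob, y[idx]),
           grads = ufnet_backward(params, cache, y[idx], spec))
    }
    nn_train(params, grad_fn, nrow(sessions), spec)
  })
  task_hashes <- vapply(MODALITIES, function(m) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    saveRDS(pipelines[[m]]$model$params, f)
    unname(tools::md5sum(f))
  }, character(1))
  structure(list(params = fit$params, spec = spec, pipelines = pipelines,
                 input_dims = dims, task_hashes = task_hashes,
                 epoch_losses = fit$epoch_losses, format_version = 1L),
            class = "park_ufnet")
}

#' Fused Monte-Carlo prediction for complete sessions
#'
#' The task-model uncertainties are recomputed once per session from
#' task-level MC dropout and held fixed; then `T` stochastic passes run
#' through the fusion stack. Incomplete sessions are an error (the fusion
#' model does not handle missing blocks).
#'
#' @param ufnet A trained `park_ufnet`.
#' @param sessions Wide session table.
#' @param T Fusion-level MC rounds.
#' @param level Interval level (defaults to the spec's `ci_level`).
#' @param seed Optional seed.
#' @return An `mc_prediction` data frame (see [mc_predict()]).
#' @export
fuse_predict <- function(ufnet, sessions, T = ufnet$spec$mc_rounds,
                         level = ufnet$spec$ci_level, seed = NULL) {
  stopifnot(inherits(ufnet, "park_ufnet"))
  T <- check_count(T, "T")
  check_complete(sessions)
  run <- function() {
    task_mc <- lapply(MODALITIES, function(m) {
      predict_task(ufnet$pipelines[[m]], sessions, T = ufnet$spec$mc_rounds)
    })
    pbar <- do.call(cbind, lapply(task_mc, function(p) p$mean_p))
    sig <- do.call(cbind, lapply(task_mc, function(p) p$sd_p))
    Xs <- lapply(MODALITIES, function(m) {
      prepare_modality_matrix(sessions, ufnet$pipelines[[m]])
    })
    vapply(seq_len(T), function(t) {
      ufnet_forward(ufnet$params, Xs, pbar, sig, ufnet$spec,
                    training = TRUE)$prob
    }, numeric(nrow(sessions)))
  }
  samples <- if (is.null(seed)) run() else with_seed(seed, run())
  samples <- matrix(samples, nrow = nrow(sessions), ncol = T)
  summarize_mc_samples(samples, level)
}

#' Screening decision with withholding
#'
#' A verdict is withheld iff the Monte-Carlo percentile interval contains the
#' decision threshold (the interval spans both classes); otherwise the
#' verdict is positive iff the mean probability exceeds the threshold.
#'
#' @param mc An `mc_prediction`.
#' @param threshold Decision threshold (default 0.5).
#' @param level Optional interval level; when it differs from the level the
#'   prediction was summarized at, the interval is recomputed from the logged
#'   per-pass samples.
#' @return Data frame with `verdict` (`"positive"`, `"negative"`,
#'   `"withheld"`) plus the interval columns used.
#' @export
decide <- function(mc, threshold = 0.5, level = NULL) {
  stopifnot(inherits(mc, "mc_prediction"))
  check_proportion(threshold, "threshold")
  if (!is.null(level) && !isTRUE(all.equal(level, attr(mc, "level")))) {
    mc <- summarize_mc_samples(attr(mc, "samples"), level)
  }
  withheld <- mc$ci_low <= threshold & threshold <= mc$ci_high
  verdict <- ifelse(withheld, "withheld",
                    ifelse(mc$mean_p > threshold, "positive", "negative"))
  data.frame(verdict = verdict, mean_p = mc$mean_p, sd_p = mc$sd_p,
             ci_low = mc$ci_low, ci_high = mc$ci_high)
}

#' Hyperparameter search space for the fusion network
#'
#' Mirrors the published table: projection dimension {128, 256, 512},
#' query/key/value dimension {32, 64, 128, 256}, hidden dimension
#' {4, 8, 16, 32, 64, 128}, dropout uniform on [0.05, 0.5], eta uniform on
#' [0.1, 100], 30 MC rounds, learning rate uniform on [5e-5, 1], epochs
#' uniform integer on [1, 300], the three optimizers, and optional schedules.
#'
#' @return Named list of dimension specifications (see [task_search_space()]).
#' @export
fusion_search_space <- function() {
  list(
    projection_dim = list(values = c(128L, 256L, 512L)),
    query_dim = list(values = c(32L, 64L, 128L, 256L)),
    hidden_dim = list(values = c(4L, 8L, 16L, 32L, 64L, 128L)),
    dropout_p = list(min = 0.05, max = 0.50),
    eta = list(min = 0.1, max = 100),
    mc_rounds = list(values = 30L),
    learning_rate = list(min = 5e-5, max = 1),
    batch_size = list(values = c(256L, 512L, 1024L)),
    epochs = list(min = 1L, max = 300L, integer = TRUE),
    optimizer = list(values = c("sgd", "adamw", "rmsprop")),
    momentum = list(min = 0.1, max = 1.0),
    scheduler = list(values = c("none", "step", "reduce_on_plateau")),
    step_size = list(min = 1L, max = 30L, integer = TRUE),
    patience = list(min = 1L, max = 20L, integer = TRUE),
    gamma = list(min = 0.5, max = 0.95))
}

#' Random search over fusion hyperparameters
#'
#' Samples `budget` fusion configurations, trains each on the complete
#' training sessions against the locked task pipelines, and keeps the spec
#' with the highest development-set AUROC of the fused Monte-Carlo mean
#' probability (ties to the earlier draw; diverged trials logged as `NA`).
#'
#' @param space A space as from [fusion_search_space()].
#' @param budget Number of configurations (>= 1).
#' @param train_sessions,dev_sessions Complete session tables.
#' @param pipelines Named list of locked `park_task_pipeline`s.
#' @param decision_threshold,ci_level Carried into each candidate spec.
#' @param seed Integer seed.
#' @return List with `best_spec`, `best_model`, `best_auroc`, `trials`.
#' @export
search_fusion_hyperparameters <- function(space, budget, train_sessions,
                                          dev_sessions, pipelines,
                                          decision_threshold = 0.5,
                                          ci_level = 0.95, seed = 1L) {
  budget <- check_count(budget, "budget")
  if (nrow(dev_sessions) == 0L) stopf("development set is empty")
  draws <- with_seed(seed, lapply(seq_len(budget), function(i) sample_space(space)))
  trials <- vector("list", budget)
  best <- list(auroc = -Inf, spec = NULL, model = NULL)
  y_dev <- dev_sessions$label_at_session
  for (i in seq_len(budget)) {
    d <- draws[[i]]
    spec <- fusion_spec(
      projection_dim = d$projection_dim, query_dim = d$query_dim,
      hidden_dim = d$hidden_dim, dropout_p = d$dropout_p, eta = d$eta,
      mc_rounds = d$mc_rounds, learning_rate = d$learning_rate,
      batch_size = d$batch_size, epochs = d$epochs, optimizer = d$optimizer,
      momentum = d$momentum, scheduler = d$scheduler, step_size = d$step_size,
      patience = d$patience, gamma = d$gamma,
      decision_threshold = decision_threshold, ci_level = ci_level,
      seed = child_seed(seed, sprintf("ftrial%d", i)))
    auroc <- NA_real_
    model <- NULL
    ok <- tryCatch({
      model <- train_ufnet(train_sessions, pipelines, spec)
      mc <- fuse_predict(model, dev_sessions,
                         seed = child_seed(seed, sprintf("fscore%d", i)))
      auroc <- roc_auc(y_dev, mc$mean_p)
      TRUE
    }, error = function(e) FALSE)
    trials[[i]] <- data.frame(
      trial = i, dev_auroc = auroc, projection_dim = d$projection_dim,
      query_dim = d$query_dim, hidden_dim = d$hidden_dim,
      dropout_p = d$dropout_p, eta = d$eta, learning_rate = d$learning_rate,
      epochs = d$epochs, optimizer = d$optimizer, failed = !ok)
    if (ok && is.finite(auroc) && auroc > best$auroc) {
      best <- list(auroc = auroc, spec = spec, model = model)
    }
  }
  if (is.null(best$spec)) stopf("every fusion trial failed; widen the budget or the space")
  list(best_spec = best$spec, best_model = best$model,
       best_auroc = best$auroc, trials = do.call(rbind, trials))
}

#' Count trainable fusion parameters
#'
#' @param ufnet A `park_ufnet`, or a raw parameter list from [ufnet_init()].
#' @return List with `total` and a named per-layer `by_layer` breakdown.
#' @export
count_parameters <- function(ufnet) {
  params <- if (inherits(ufnet, "park_ufnet")) ufnet$params else ufnet
  by_layer <- vapply(params, function(p) length(p), integer(1))
  list(total = sum(by_layer), by_layer = by_layer)
}
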