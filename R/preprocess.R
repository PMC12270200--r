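# Data hygiene and feature conditioning: duration-based session filtering,
# feature scaling, correlation-based feature selection, minority oversampling.

#' Flag sessions with abnormal task durations
#'
#' A session's task is flagged when its recorded duration lies more than
#' three standard deviations below or above the average duration of that
#' task, with mean and sample SD (n-1) computed over all non-missing
#' durations of the task in the incoming table. Flagged tasks are treated as
#' missing downstream. Tasks whose duration is absent are tagged
#' `missing_block` for information; they do not count against the session.
#'
#' @param sessions Wide session table with `dur_tap_s`, `dur_smile_s`,
#'   `dur_speech_s` columns.
#' @param n_sd Exclusion threshold in standard deviations (default 3).
#' @return A `filter_report`: `kept` (session IDs with no duration flag),
#'   `excluded` (session IDs with at least one flag), `detail` (data frame of
#'   session_id, task, reason in duration_low / duration_high /
#'   missing_block), and `warnings` (tasks skipped because every duration was
#'   missing).
#' @export
filter_sessions_by_duration <- function(sessions, n_sd = 3) {
  ids <- session_ids(sessions)
  detail <- list()
  warnings <- character()
  for (m in MODALITIES) {
    d <- sessions[[DURATION_COLS[[m]]]]
    miss <- is.na(d)
    if (any(miss)) {
      detail[[length(detail) + 1L]] <- data.frame(
        session_id = ids[miss], task = m, reason = "missing_block")
    }
    obs <- d[!miss]
    if (length(obs) == 0L) {
      warnings <- c(warnings, sprintf("task '%s': all durations missing; skipped", m))
      next
    }
    if (length(obs) < 2L || stats::sd(obs) == 0) next  # degenerate: nothing flagged
    mu <- mean(obs)
    sdv <- stats::sd(obs)
    low <- !miss & (d < mu - n_sd * sdv)
    high <- !miss & (d > mu + n_sd * sdv)
    if (any(low)) {
      detail[[length(detail) + 1L]] <- data.frame(
        session_id = ids[low], task = m, reason = "duration_low")
    }
    if (any(high)) {
      detail[[length(detail) + 1L]] <- data.frame(
        session_id = ids[high], task = m, reason = "duration_high")
    }
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(session_id = character(), task = character(), reason = character())
  flagged <- unique(detail$session_id[detail$reason != "missing_block"])
  structure(list(kept = setdiff(ids, flagged), excluded = flagged,
                 detail = detail, warnings = warnings),
            class = "filter_report")
}

#' Apply a duration filter report to a session table
#'
#' Sets every duration-flagged task block (features and duration) to `NA`.
#'
#' @param sessions Wide session table.
#' @param report A `filter_report` from [filter_sessions_by_duration()].
#' @return The session table with flagged blocks removed.
#' @export
apply_duration_filter <- function(sessions, report) {
  ids <- session_ids(sessions)
  det <- report$detail[report$detail$reason != "missing_block", , drop = FALSE]
  for (m in unique(det$task)) {
    rows <- ids %in% det$session_id[det$task == m]
    sessions[rows, modality_columns(m)] <- NA_real_
    sessions[rows, DURATION_COLS[[m]]] <- NA_real_
  }
  sessions
}

#' Fit and apply feature scaling
#'
#' `standardize` centers to mean 0 / sample SD 1; `minmax` maps the training
#' range to `[0, 1]`. Constant training columns map to 0 under either kind
#' (zero scale is guarded by replacing it with 1 after centering).
#'
#' @param x Numeric training matrix (rows = sessions).
#' @param kind `"standardize"` or `"minmax"`.
#' @return `fit_scaler()` returns a `park_scaler` with per-column location
#'   and scale; `apply_scaler()` / `invert_scaler()` transform a matrix of
#'   matching width.
#' @export
fit_scaler <- function(x, kind = c("standardize", "minmax")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (kind == "standardize") {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
  } else {
    center <- apply(x, 2, min)
    scale <- apply(x, 2, max) - center
  }
  constant <- scale <= 0 | !is.finite(scale)
  scale[constant] <- 1
  structure(list(kind = kind, center = center, scale = scale,
                 constant = constant, p = ncol(x)),
            class = "park_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `park_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "park_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != scaler$p) {
    stopf("scaler fitted on %d columns; got %d", scaler$p, ncol(x))
  }
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "park_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != scaler$p) {
    stopf("scaler fitted on %d columns; got %d", scaler$p, ncol(x))
  }
  sweep(sweep(x, 2, scaler$scale, "*"), 2, scaler$center, "+")
}

#' Greedy correlation-based feature selection
#'
#' Scans columns in order; a column is dropped iff its absolute Pearson
#' correlation with an already-kept column exceeds `threshold`. Zero-variance
#' columns correlate 0 with everything except an identical constant column
#' already kept (a duplicated constant is dropped). Deterministic for a fixed
#' column order.
#'
#' @param x Numeric training matrix.
#' @param threshold Absolute correlation cutoff in (0, 1].
#' @return Integer vector of kept column indices.
#' @export
select_features_by_correlation <- function(x, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stopf("`threshold` must be in (0, 1]")
  }
  x <- as.matrix(x)
  p <- ncol(x)
  if (p == 0L) return(integer())
  sds <- apply(x, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(x))
  cm[!is.finite(cm)] <- 0
  kept <- integer()
  for (j in seq_len(p)) {
    drop <- FALSE
    for (k in kept) {
      r <- if (sds[j] == 0 && sds[k] == 0) {
        if (isTRUE(all(x[, j] == x[, k]))) 1 else 0
      } else cm[j, k]
      if (abs(r) > threshold) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, j)
  }
  kept
}

#' SMOTE minority oversampling
#'
#' Synthesizes minority-class rows as convex combinations
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and `x_nn` one of the `k`
#' nearest minority neighbors (Euclidean). Majority rows are untouched; the
#' output minority:majority ratio equals `target_ratio` within one sample.
#'
#' @param x Numeric training matrix.
#' @param y Binary labels (0/1), one per row.
#' @param k Neighbor count; the minority class must have at least `k + 1`
#'   members.
#' @param target_ratio Desired minority / majority count ratio (default 1).
#' @param seed Integer seed.
#' @return List with augmented `x`, `y`, and `n_synthetic`.
#' @export
smote_oversample <- function(x, y, k = 5, target_ratio = 1, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  tab <- table(factor(y, levels = c(0L, 1L)))
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  n_min <- sum(y == minority)
  n_maj <- length(y) - n_min
  if (n_min < k + 1) {
    stopf("minority class has %d members but k = %d requires at least %d; lower k",
          n_min, k, k + 1)
  }
  n_new <- round(n_maj * target_ratio) - n_min
  if (n_new <= 0) return(list(x = x, y = y, n_synthetic = 0L))
  xm <- x[y == minority, , drop = FALSE]
  dmat <- as.matrix(stats::dist(xm))
  diag(dmat) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i) {
    order(dmat[i, ])[seq_len(k)]
  }))
  synth <- with_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    xm[base, , drop = FALSE] + u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  })
  list(x = rbind(x, synth), y = c(y, rep(minority, n_new)),
       n_synthetic = as.integer(n_new))
}
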