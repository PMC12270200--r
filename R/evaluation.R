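# Diagnostic performance, calibration, agreement, and subgroup statistics.

#' Confusion-matrix metrics
#'
#' Standard definitions from the 2x2 table. Ratios with a zero denominator
#' are reported as `NA` (not available), never 0. Withheld sessions must be
#' removed by the caller before evaluation.
#'
#' @param truth,predictions Binary 0/1 vectors of equal length.
#' @return Named list: accuracy, sensitivity, specificity, ppv, npv, f1.
#' @export
confusion_metrics <- function(truth, predictions) {
  truth <- as.integer(truth)
  predictions <- as.integer(predictions)
  if (length(truth) == 0L) stopf("empty input")
  stopifnot(length(truth) == length(predictions),
            all(truth %in% 0:1), all(predictions %in% 0:1))
  tp <- sum(truth == 1 & predictions == 1)
  tn <- sum(truth == 0 & predictions == 0)
  fp <- sum(truth == 0 & predictions == 1)
  fn <- sum(truth == 1 & predictions == 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  ppv <- ratio(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_ else
    2 * sens * ppv / (sens + ppv)
  list(accuracy = (tp + tn) / length(truth), sensitivity = sens,
       specificity = ratio(tn, tn + fp), ppv = ppv,
       npv = ratio(tn, tn + fn), f1 = f1)
}

#' Area under the ROC curve (rank / Mann--Whitney identity)
#'
#' `AUROC = (sum of positive-class midranks - n_pos(n_pos+1)/2) /
#' (n_pos * n_neg)`; ties count one half.
#'
#' @param truth Binary 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0L || n_neg == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision--recall curve (step integration)
#'
#' Descends the score-sorted list (tied scores grouped) and integrates
#' precision over recall increments.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `[0, 1]`.
#' @export
pr_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1)
  if (n_pos == 0L || sum(truth == 0) == 0L) stopf("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  t_sorted <- truth[ord]
  s_sorted <- scores[ord]
  grp <- cumsum(!duplicated(s_sorted))
  tp <- tapply(t_sorted, grp, sum)
  n <- tapply(t_sorted, grp, length)
  tp_cum <- cumsum(tp)
  n_cum <- cumsum(n)
  precision <- tp_cum / n_cum
  recall <- tp_cum / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Brier score, expected calibration error, calibration curve
#'
#' Brier = mean squared error of predicted probabilities against outcomes.
#' ECE = `sum_b (n_b / n) * |mean prob_b - observed rate_b|` over `bins`
#' equal-width probability bins; empty bins are skipped.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param truth Binary 0/1 outcomes.
#' @param bins Number of equal-width bins (>= 1).
#' @return `brier()` and `ece()` return a scalar; `calibration_curve()` a
#'   data frame with per-bin mean probability, observed rate, and count.
#' @export
brier <- function(probs, truth) {
  check_proportion(probs, "probs")
  mean((probs - as.numeric(truth))^2)
}

bin_probs <- function(probs, bins) {
  pmin(pmax(ceiling(probs * bins), 1L), bins)
}

#' @rdname brier
#' @export
ece <- function(probs, truth, bins = 10L) {
  bins <- check_count(bins, "bins")
  check_proportion(probs, "probs")
  truth <- as.numeric(truth)
  b <- bin_probs(probs, bins)
  n <- length(probs)
  conf <- tapply(probs, b, mean)
  rate <- tapply(truth, b, mean)
  nb <- tapply(truth, b, length)
  sum(nb / n * abs(conf - rate))
}

#' @rdname brier
#' @export
calibration_curve <- function(probs, truth, bins = 10L) {
  bins <- check_count(bins, "bins")
  check_proportion(probs, "probs")
  truth <- as.numeric(truth)
  b <- factor(bin_probs(probs, bins), levels = seq_len(bins))
  data.frame(bin = seq_len(bins),
             lower = (seq_len(bins) - 1) / bins, upper = seq_len(bins) / bins,
             mean_prob = as.numeric(tapply(probs, b, mean)),
             observed_rate = as.numeric(tapply(truth, b, mean)),
             n = as.integer(table(b)))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows with replacement `B` times and returns the percentile
#' interval of the statistic at `level`, together with the full resample
#' distribution (used downstream for Mann--Whitney comparisons between
#' models). Resamples on which the statistic is undefined (error or `NA`)
#' are redrawn and counted in `redraws`.
#'
#' @param statistic Function of the resampled data.
#' @param data Vector, matrix, or data frame (rows are resampled).
#' @param B Number of resamples (default 1000).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return List: `estimate` (statistic on the full data), `ci_low`,
#'   `ci_high`, `distribution`, `B`, `level`, `redraws`.
#' @export
bootstrap_ci <- function(statistic, data, B = 1000L, level = 0.95, seed = 1L) {
  B <- check_count(B, "B")
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  take <- function(idx) {
    if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
  }
  estimate <- statistic(data)
  redraws <- 0L
  dist <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        val <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                        error = function(e) NA_real_)
        if (length(val) == 1L && is.finite(val)) return(val)
        redraws <<- redraws + 1L
        if (redraws > 100L * B) stopf("statistic undefined on virtually every resample")
      }
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(dist, c(alpha, 1 - alpha), names = FALSE)
  list(estimate = estimate, ci_low = qs[1], ci_high = qs[2],
       distribution = dist, B = B, level = level, redraws = redraws)
}

#' Mann--Whitney U comparison of two bootstrap distributions
#'
#' Two-sided Mann--Whitney U test with the tie-corrected normal
#' approximation (via [stats::wilcox.test()]).
#'
#' @param dist_a,dist_b Nonempty numeric vectors.
#' @return List with `U` (statistic for the first sample) and `p`.
#' @export
compare_bootstrap_distributions <- function(dist_a, dist_b) {
  if (length(dist_a) == 0L || length(dist_b) == 0L) {
    stopf("both distributions must be nonempty")
  }
  wt <- suppressWarnings(stats::wilcox.test(dist_a, dist_b, exact = FALSE,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Two-proportion pooled z-test
#'
#' Two-sided z test with pooled variance. Refuses (with an assumption error)
#' when the standard applicability rule fails: using the pooled proportion,
#' `n*p` and `n*(1-p)` must both be at least 5 in each group.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two groups.
#' @return List with `z` and `p`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, n1 >= 1, n2 >= 1, x1 <= n1, x2 <= n2)
  p_pool <- (x1 + x2) / (n1 + n2)
  checks <- c(n1 * p_pool, n1 * (1 - p_pool), n2 * p_pool, n2 * (1 - p_pool))
  if (any(checks < 5)) {
    stopf(paste("sample-size assumption violated (np >= 5 and n(1-p) >= 5",
                "required in both groups); use an exact or Monte-Carlo test"))
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Monte-Carlo chi-square test of independence
#'
#' Pearson chi-square statistic with the p-value estimated from `reps`
#' random tables drawn with fixed margins:
#' `p = (1 + #(chi2_sim >= chi2_obs)) / (reps + 1)` (the add-one estimator,
#' so `p` is never 0). Implemented via [stats::chisq.test()] simulation.
#'
#' @param tab Contingency table of nonnegative integer counts.
#' @param reps Number of simulated tables (default 10000).
#' @param seed Integer seed.
#' @return List with `chi2` and `p`.
#' @export
mc_chisquare <- function(tab, reps = 10000L, seed = 1L) {
  reps <- check_count(reps, "reps")
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stopf("table must contain nonnegative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stopf("zero marginal row or column")
  }
  ct <- with_seed(seed, stats::chisq.test(tab, simulate.p.value = TRUE,
                                          B = reps))
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1; input order is
#' preserved.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stopf("p-values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Cohen's kappa and raw agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement from the marginal
#' products. When both raters are constant and equal (`p_e = 1`) kappa is
#' reported as `NA`. Agreement is the fraction of identical verdicts.
#'
#' @param labels_a,labels_b Equal-length categorical vectors.
#' @return A scalar.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  levels_all <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = levels_all)
  b <- factor(labels_b, levels = levels_all)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e == 0) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' @rdname cohens_kappa
#' @export
agreement_rate <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b), length(labels_a) > 0)
  mean(labels_a == labels_b)
}

#' Majority vote over an odd number of raters
#'
#' @param ratings Data frame or matrix of binary verdicts, one column per
#'   rater, one row per subject.
#' @return Integer vector of per-subject modal verdicts.
#' @export
majority_vote <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) %% 2 == 0) {
    stopf("an odd number of raters is required (no tie rule is defined)")
  }
  as.integer(rowMeans(ratings) > 0.5)
}

#' Multivariable logistic regression of misclassification on demographics
#'
#' Fits `error ~ covariates` by maximum likelihood (IRLS via
#' [stats::glm()]), reports Wald p-values, and adjusts them across
#' covariate terms by Benjamini--Hochberg. Refuses on (quasi-)separation or
#' rank deficiency.
#'
#' @param error Binary misclassification indicator (1 = model was wrong).
#' @param covariates Data frame of demographic covariates (e.g. sex,
#'   ethnicity, age).
#' @return Data frame with term, coefficient, p, bh_adjusted_p (intercept
#'   excluded from the adjustment set but reported).
#' @export
misclassification_regression <- function(error, covariates) {
  stopifnot(length(error) == nrow(covariates))
  df <- cbind(data.frame(.error = as.integer(error)), covariates)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.error ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  coefs <- summary(fit)$coefficients
  if (separation || any(!is.finite(coefs[, 1])) || any(abs(coefs[, 1]) > 15)) {
    stopf("separation or near-separation detected; coefficients are not identifiable")
  }
  if (fit$rank < length(stats::coef(fit))) {
    stopf("rank-deficient design; drop collinear covariates")
  }
  terms <- rownames(coefs)
  is_cov <- terms != "(Intercept)"
  adj <- rep(NA_real_, length(terms))
  adj[is_cov] <- bh_adjust(coefs[is_cov, 4])
  data.frame(term = terms, coefficient = coefs[, 1], p = coefs[, 4],
             bh_adjusted_p = adj, row.names = NULL)
}

#' Fused accuracy partitioned by task-model agreement
#'
#' Partitions sessions into the eight regions of which task models were
#' correct and reports the fused model's accuracy and count per region
#' (the Venn-diagram decomposition of fusion behavior).
#'
#' @param tap_correct,smile_correct,speech_correct Logical vectors: was each
#'   task model correct on the session.
#' @param fused_correct Logical vector: was the fused verdict correct.
#' @return Data frame with one row per region (tap/smile/speech flags, n,
#'   fused accuracy; `NA` accuracy for empty regions).
#' @export
accuracy_by_agreement <- function(tap_correct, smile_correct, speech_correct,
                                  fused_correct) {
  n <- length(fused_correct)
  stopifnot(length(tap_correct) == n, length(smile_correct) == n,
            length(speech_correct) == n)
  regions <- expand.grid(tap = c(TRUE, FALSE), smile = c(TRUE, FALSE),
                         speech = c(TRUE, FALSE))
  res <- lapply(seq_len(nrow(regions)), function(i) {
    in_region <- tap_correct == regions$tap[i] &
      smile_correct == regions$smile[i] &
      speech_correct == regions$speech[i]
    data.frame(tap = regions$tap[i], smile = regions$smile[i],
               speech = regions$speech[i], n = sum(in_region),
               fused_accuracy = if (any(in_region))
                 mean(fused_correct[in_region]) else NA_real_)
  })
  do.call(rbind, res)
}

#' Full diagnostic metric report with bootstrap intervals
#'
#' Computes accuracy, sensitivity, specificity, PPV, NPV, F1, AUROC, AUPRC,
#' Brier and ECE with percentile-bootstrap confidence intervals, on the
#' retained (non-withheld) sessions; coverage (fraction not withheld) is
#' reported alongside.
#'
#' @param truth Binary 0/1 labels.
#' @param probs Predicted probabilities.
#' @param verdicts Optional verdict vector from [decide()]; `"withheld"`
#'   rows are excluded from the metrics.
#' @param threshold Classification threshold for the confusion metrics.
#' @param B,level,seed Bootstrap settings.
#' @param ece_bins Bins for the calibration error.
#' @return A `metric_report`: per-metric estimate and CI, plus `coverage`,
#'   `n_total`, `n_retained`.
#' @export
metric_report <- function(truth, probs, verdicts = NULL, threshold = 0.5,
                          B = 1000L, level = 0.95, seed = 1L, ece_bins = 10L) {
  truth <- as.integer(truth)
  retained <- if (is.null(verdicts)) rep(TRUE, length(truth)) else
    verdicts != "withheld"
  n_total <- length(truth)
  t_r <- truth[retained]
  p_r <- probs[retained]
  if (length(t_r) == 0L) stopf("no retained sessions to evaluate")
  data <- cbind(t_r, p_r)
  metric_fns <- list(
    accuracy = function(d) confusion_metrics(d[, 1], as.integer(d[, 2] > threshold))$accuracy,
    sensitivity = function(d) confusion_metrics(d[, 1], as.integer(d[, 2] > threshold))$sensitivity,
    specificity = function(d) confusion_metrics(d[, 1], as.integer(d[, 2] > threshold))$specificity,
    ppv = function(d) confusion_metrics(d[, 1], as.integer(d[, 2] > threshold))$ppv,
    npv = function(d) confusion_metrics(d[, 1], as.integer(d[, 2] > threshold))$npv,
    f1 = function(d) confusion_metrics(d[, 1], as.integer(d[, 2] > threshold))$f1,
    auroc = function(d) roc_auc(d[, 1], d[, 2]),
    auprc = function(d) pr_auc(d[, 1], d[, 2]),
    brier = function(d) brier(d[, 2], d[, 1]),
    ece = function(d) ece(d[, 2], d[, 1], bins = ece_bins))
  metrics <- lapply(names(metric_fns), function(nm) {
    bs <- bootstrap_ci(metric_fns[[nm]], data, B = B, level = level,
                       seed = child_seed(seed, nm))
    list(metric = nm, estimate = bs$estimate, ci_low = bs$ci_low,
         ci_high = bs$ci_high, distribution = bs$distribution)
  })
  names(metrics) <- names(metric_fns)
  structure(list(metrics = metrics, coverage = mean(retained),
                 n_total = n_total, n_retained = sum(retained),
                 B = B, level = level, threshold = threshold),
            class = "metric_report")
}

#' @rdname metric_report
#' @param report A `metric_report`.
#' @param path Output path for the JSON serialization.
#' @export
write_metric_report <- function(report, path) {
  out <- list(
    coverage = report$coverage, n_total = report$n_total,
    n_retained = report$n_retained, B = report$B, level = report$level,
    threshold = report$threshold,
    metrics = lapply(report$metrics, function(m) {
      list(estimate = m$estimate, ci_low = m$ci_low, ci_high = m$ci_high)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
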