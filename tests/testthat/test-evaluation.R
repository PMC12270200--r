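# Diagnostic metrics, calibration, bootstrap, agreement, subgroup statistics.

test_that("confusion metrics match hand arithmetic and guard zero denominators", {
  # TP=9, FN=1, TN=7, FP=3
  truth <- rep(c(1, 0), c(10, 10))
  pred <- c(rep(1, 9), 0, rep(0, 7), rep(1, 3))
  m <- confusion_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 0.875)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 2 * 0.9 * 0.75 / (0.9 + 0.75))
  # perfect predictions
  p <- confusion_metrics(truth, truth)
  expect_true(all(unlist(p) == 1))
  # all-positive predictions: specificity 0, npv unavailable
  ap <- confusion_metrics(truth, rep(1, 20))
  expect_equal(ap$specificity, 0)
  expect_true(is.na(ap$npv))
  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
})

test_that("AUROC matches the rank identity, an enumeration oracle, and pROC", {
  truth <- c(1, 1, 1, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2, 0.1)
  # brute-force pair enumeration oracle (ties = 1/2)
  pairs <- expand.grid(p = which(truth == 1), n = which(truth == 0))
  orc <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                     ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(truth, scores), orc)
  expect_equal(roc_auc(truth, scores),
               as.numeric(suppressMessages(pROC::auc(truth, scores))))
  # tied scores
  st <- c(0.5, 0.5, 0.5, 0.5, 0.2, 0.9, 0.5)
  pairs_t <- expand.grid(p = which(truth == 1), n = which(truth == 0))
  orc_t <- mean(ifelse(st[pairs_t$p] > st[pairs_t$n], 1,
                       ifelse(st[pairs_t$p] == st[pairs_t$n], 0.5, 0)))
  expect_equal(roc_auc(truth, st), orc_t)
  # perfect / inverted / random scores
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  set.seed(1)
  big_t <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(big_t, runif(10000)) - 0.5), 0.01)
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("AUPRC step integration matches a small hand-checked fixture", {
  truth <- c(1, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.7, 0.1)
  # descending: (1@.9) p=1 r=.5 ; (0@.8) ; (1@.7) p=2/3 r=1 ; (0@.1)
  expect_equal(pr_auc(truth, scores), 0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(pr_auc(c(0, 1), c(0.1, 0.9)), 1)
})

test_that("Brier and ECE match closed forms and hand fixtures", {
  # perfectly confident correct predictions
  expect_equal(brier(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  # bin {1,1}: gap 0; bin {0.001, 0.001}: gap 0.001, weight 1/2
  expect_equal(ece(c(1, 1, 0.001, 0.001), c(1, 1, 0, 0)), 0.0005)
  # constant 0.5 on balanced labels: Brier exactly 0.25
  y <- rep(c(0, 1), 500)
  expect_identical(brier(rep(0.5, 1000), y), 0.25)
  expect_lt(ece(rep(0.5, 1000), y), 0.01)
  # hand fixture of 6 (prob, label) pairs
  pr <- c(0.1, 0.3, 0.35, 0.6, 0.8, 0.95)
  yy <- c(0, 0, 1, 1, 1, 0)
  expect_equal(brier(pr, yy), mean((pr - yy)^2))
  # hand ECE, 10 equal-width bins; every prob lands in its own bin
  hand <- (abs(0.1 - 0) + abs(0.3 - 0) + abs(0.35 - 1) + abs(0.6 - 1) +
             abs(0.8 - 1) + abs(0.95 - 0)) / 6
  expect_equal(ece(pr, yy, bins = 10), hand)
  cal <- calibration_curve(pr, yy, bins = 10)
  expect_identical(nrow(cal), 10L)
  expect_identical(sum(cal$n), 6L)
  expect_equal(cal$mean_prob[4], 0.35)  # (0.3, 0.4] bin holds 0.35 only
  expect_error(ece(pr, yy, bins = 0), "bins")
})

test_that("bootstrap percentile intervals behave on degenerate inputs", {
  # B = 1: degenerate CI at the single resample's value
  b1 <- bootstrap_ci(mean, c(1, 2, 3, 4), B = 1, seed = 1)
  expect_identical(b1$ci_low, b1$ci_high)
  expect_identical(b1$ci_low, b1$distribution[1])
  # constant data collapse the CI to the constant
  bc <- bootstrap_ci(mean, rep(7, 20), B = 50, seed = 2)
  expect_identical(bc$ci_low, 7)
  expect_identical(bc$ci_high, 7)
  # endpoints inside the observed resample range; reproducible by seed
  bx <- bootstrap_ci(mean, rnorm(50), B = 200, seed = 3)
  expect_gte(bx$ci_low, min(bx$distribution))
  expect_lte(bx$ci_high, max(bx$distribution))
  by <- bootstrap_ci(mean, bx$distribution, B = 200, seed = 4)
  bz <- bootstrap_ci(mean, bx$distribution, B = 200, seed = 4)
  expect_identical(by$distribution, bz$distribution)
  # undefined resamples are redrawn and logged
  dat <- c(rep(NA_real_, 2), 1:8)
  br <- bootstrap_ci(function(d) mean(d), dat, B = 50, seed = 5)
  expect_gt(br$redraws, 0)
  expect_true(all(is.finite(br$distribution)))
})

test_that("Mann-Whitney comparison agrees with exact enumeration on a small fixture", {
  a <- c(1.1, 2.3, 3.7, 4.2, 5.9)
  b <- c(0.8, 2.0, 3.1, 4.0)
  # brute-force U: count pairs where a > b (no ties here)
  U_orc <- sum(outer(a, b, ">"))
  res <- compare_bootstrap_distributions(a, b)
  expect_equal(unname(res$U), U_orc)
  # identical distributions -> p near 1; disjoint -> U maximal, p small
  same <- compare_bootstrap_distributions(1:20, 1:20)
  expect_gt(same$p, 0.9)
  apart <- compare_bootstrap_distributions(101:120, 1:20)
  expect_identical(unname(apart$U), 400)
  expect_lt(apart$p, 1e-6)
  expect_error(compare_bootstrap_distributions(numeric(0), 1:3), "nonempty")
})

test_that("two-proportion z-test matches the pooled formula and refuses tiny samples", {
  res <- two_proportion_z(30, 100, 15, 100)
  p_pool <- 45 / 200
  z_hand <- (0.30 - 0.15) / sqrt(p_pool * (1 - p_pool) * (1 / 100 + 1 / 100))
  expect_equal(res$z, z_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-10)
  # equal proportions -> z = 0, p = 1
  eq <- two_proportion_z(20, 50, 20, 50)
  expect_identical(eq$z, 0)
  expect_identical(eq$p, 1)
  # n * p_pool < 5 -> assumption error, not a silent fallback
  expect_error(two_proportion_z(3, 100, 2, 100), "assumption")
})

test_that("Monte-Carlo chi-square approximates the asymptotic p on large tables", {
  tab <- matrix(c(50, 30, 20, 30, 50, 20), nrow = 2, byrow = TRUE)
  mc <- mc_chisquare(tab, reps = 4000, seed = 1)
  asym <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(mc$chi2, unname(asym$statistic))
  expect_lt(abs(mc$p - asym$p.value), 0.02)
  # independent table (outer product of margins) -> p near 1
  ind <- outer(c(40, 60), c(30, 70)) / 100
  expect_gt(mc_chisquare(round(ind * 10), reps = 500, seed = 2)$p, 0.5)
  # p floor: never below 1 / (reps + 1)
  far <- matrix(c(50, 0, 0, 50), 2)
  pf <- mc_chisquare(far, reps = 200, seed = 3)$p
  expect_gte(pf, 1 / 201)
  expect_error(mc_chisquare(matrix(c(0, 0, 3, 4), 2), reps = 10), "marginal")
  expect_error(mc_chisquare(matrix(c(1.5, 2, 3, 4), 2), reps = 10), "integer")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.3), 0.3)
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  # hand-computed mixed case: p * m / rank with step-up monotonicity
  p <- c(0.005, 0.04, 0.03, 0.8)
  hand <- c(0.02, 0.053333333333333337, 0.053333333333333337, 0.8)
  expect_equal(bh_adjust(p), hand, tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's kappa matches hand computation, is symmetric, guards p_e = 1", {
  expect_identical(cohens_kappa(c(1, 0, 1), c(1, 0, 1)), 1)
  # independence table [[25,25],[25,25]] -> kappa 0
  a <- rep(c(1, 1, 0, 0), each = 25)
  b <- rep(c(1, 0, 1, 0), each = 25)
  expect_identical(cohens_kappa(a, b), 0)
  # hand table [[20,5],[3,12]]
  aa <- rep(c(1, 1, 0, 0), c(20, 5, 3, 12))
  bb <- rep(c(1, 0, 1, 0), c(20, 5, 3, 12))
  n <- 40
  p_o <- 32 / 40
  p_e <- (25 / 40) * (23 / 40) + (15 / 40) * (17 / 40)
  expect_equal(cohens_kappa(aa, bb), (p_o - p_e) / (1 - p_e))
  expect_identical(cohens_kappa(aa, bb), cohens_kappa(bb, aa))
  # both raters constant and equal
  expect_true(is.na(cohens_kappa(rep(1, 10), rep(1, 10))))
  expect_equal(agreement_rate(aa, bb), 0.8)
})

test_that("majority vote requires an odd panel and returns the modal verdict", {
  r <- cbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  expect_identical(majority_vote(r), c(1L, 1L, 0L))
  expect_identical(majority_vote(r[, 1, drop = FALSE]), c(1L, 1L, 0L))
  expect_error(majority_vote(r[, 1:2]), "odd")
})

test_that("misclassification regression recovers closed forms and refuses separation", {
  # intercept-only behavior: error rate 0.25 -> intercept ~ log(1/3)
  set.seed(4)
  n <- 4000
  err <- rbinom(n, 1, 0.25)
  cov <- data.frame(sex = sample(c("m", "f"), n, replace = TRUE))
  res <- misclassification_regression(err, cov)
  expect_lt(abs(res$coefficient[res$term == "(Intercept)"] - log(1 / 3)), 0.15)
  # independent covariate: small coefficient, non-significant after BH
  expect_lt(abs(res$coefficient[2]), 0.15)
  expect_gt(res$bh_adjusted_p[2], 0.05)
  # separable fixture -> refusal
  sep <- data.frame(x = c(rep(0, 20), rep(1, 20)))
  expect_error(misclassification_regression(c(rep(0, 20), rep(1, 20)), sep),
               "separation")
})

test_that("accuracy-by-agreement partitions sessions into the eight regions", {
  set.seed(5)
  n <- 10
  tap <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE)
  smi <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  spe <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  fus <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)
  tab <- accuracy_by_agreement(tap, smi, spe, fus)
  expect_identical(sum(tab$n), 10L)
  # enumeration oracle for one region: all three correct
  region <- tap & smi & spe
  row <- tab[tab$tap & tab$smile & tab$speech, ]
  expect_identical(row$n, sum(region))
  expect_equal(row$fused_accuracy, mean(fus[region]))
  # all models always correct -> a single populated region
  tab2 <- accuracy_by_agreement(rep(TRUE, 4), rep(TRUE, 4), rep(TRUE, 4),
                                c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(sum(tab2$n > 0), 1L)
  expect_equal(tab2$fused_accuracy[tab2$tap & tab2$smile & tab2$speech], 0.75)
})

test_that("metric_report assembles estimates, intervals, and coverage", {
  set.seed(6)
  n <- 150
  truth <- rbinom(n, 1, 0.5)
  probs <- plogis(qlogis(0.5) + (truth - 0.5) * 3 + rnorm(n))
  verdicts <- ifelse(runif(n) < 0.1, "withheld",
                     ifelse(probs > 0.5, "positive", "negative"))
  rep <- metric_report(truth, probs, verdicts = verdicts, B = 100, seed = 7)
  expect_equal(rep$coverage, mean(verdicts != "withheld"))
  expect_identical(rep$n_retained, sum(verdicts != "withheld"))
  for (m in rep$metrics) {
    expect_true(m$ci_low <= m$estimate + 1e-12)
    expect_true(m$estimate <= m$ci_high + 1e-12)
  }
  retained <- verdicts != "withheld"
  expect_identical(rep$metrics$auroc$estimate,
                   roc_auc(truth[retained], probs[retained]))
  f <- tempfile(fileext = ".json")
  write_metric_report(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$metrics$auroc$estimate, rep$metrics$auroc$estimate)
  unlink(f)
})
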