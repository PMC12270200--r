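# Synthetic cohort generator: dimensions, determinism, class balance,
# missingness mechanics, and signal structure.

test_that("config validation rejects bad proportions and empty cohorts", {
  expect_error(cohort_config(subgroup_targets = list(
    sex = c(male = 0.6, female = 0.6), ethnicity = c(white = 1),
    age = c(under50 = 1))), "sum to 1")
  expect_error(cohort_config(pd_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(n_informative = c(finger_tapping = 200L, smile = 10L,
                                               speech = 64L)), "must be in")
  cc <- cohort_config(n_participants = 0)
  expect_error(generate_cohort(cc), "empty cohort")
})

test_that("PD count follows the rounding rule exactly", {
  for (frac in c(0.5, 0.359, 0.25)) {
    co <- small_cohort(n = 40, pd_fraction = frac, seed = 9)
    expect_identical(sum(co$participants$pd_status), as.integer(round(40 * frac)))
  }
  co <- small_cohort(n = 200, pd_fraction = 0.5, seed = 1)
  expect_identical(sum(co$participants$pd_status), 100L)
})

test_that("identical config and seed reproduce byte-identical cohorts", {
  cc <- cohort_config(n_participants = 30, seed = 123)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(a$sessions, f1, config = cc)
  write_cohort(b$sessions, f2, config = cc)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_cohort(f1)
  expect_equal(nrow(back), nrow(a$sessions))
  expect_true(file.exists(paste0(f1, ".meta")))
  unlink(c(f1, f2, paste0(f1, ".meta"), paste0(f2, ".meta")))
})

test_that("modality vectors have the declared widths and signal structure", {
  cc <- cohort_config(seed = 1)
  expect_length(modality_columns("smile"), 42)
  expect_length(modality_columns("finger_tapping"), 130)
  expect_length(modality_columns("speech"), 1024)
  set.seed(1)
  expect_length(simulate_modality_vector(0.7, "smile", cc), 42)
  expect_error(simulate_modality_vector(0, "gait", cc))
  # zero severity, zero noise -> all-zero vector
  cc0 <- cohort_config(noise_sd = 0, seed = 1)
  expect_identical(simulate_modality_vector(0, "speech", cc0), rep(0, 1024))
  # empirical class mean difference of an informative coordinate matches the
  # closed-form expectation 2 * effect_size within 5%
  cc2 <- cohort_config(n_participants = 700, pd_fraction = 0.5,
                       sessions_per_participant = c(2L, 2L),
                       modality_signal = c(finger_tapping = 2.0, smile = 0.5,
                                           speech = 1.5),
                       missing_rate = c(finger_tapping = 0, smile = 0, speech = 0),
                       seed = 77)
  co <- generate_cohort(cc2)
  x <- co$sessions$tap_000
  pd <- co$sessions$pd_status == 1
  diff <- mean(x[pd]) - mean(x[!pd])
  # closed-form expectation given the realized latent severities: delta * s
  s <- co$sessions$severity_session
  expected <- 2.0 * (mean(s[pd]) - mean(s[!pd]))
  expect_lt(abs(diff - expected) / expected, 0.05)
  # and the unconditional expectation 2 * delta holds more loosely
  expect_lt(abs(diff - 2 * 2.0) / (2 * 2.0), 0.15)
})

test_that("with zero modality signal held-out discrimination is chance", {
  # oracle: logistic fit on pooled sessions across seeds; AUROC ~ 0.5
  aucs <- sapply(1:3, function(s) {
    cc <- cohort_config(n_participants = 250, pd_fraction = 0.5,
                        sessions_per_participant = c(2L, 2L),
                        modality_signal = c(finger_tapping = 0, smile = 0, speech = 0),
                        missing_rate = c(finger_tapping = 0, smile = 0, speech = 0),
                        seed = 100 + s)
    co <- generate_cohort(cc)
    sess <- co$sessions
    half <- sess$participant_id %in% unique(sess$participant_id)[1:125]
    x <- as.matrix(sess[, modality_columns("smile")])
    fit <- suppressWarnings(glm.fit(cbind(1, x[half, ]), sess$pd_status[half],
                                    family = binomial()))
    scores <- cbind(1, x[!half, ]) %*% fit$coefficients
    roc_auc(sess$pd_status[!half], scores)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("missingness hits the configured rates and spares one block", {
  co <- small_cohort(n = 80, seed = 5)
  cc <- cohort_config(n_participants = 80, seed = 5,
                      missing_rate = c(finger_tapping = 0, smile = 0, speech = 0))
  # all rates zero -> identity
  expect_identical(inject_missingness(co$sessions, cc, seed = 1), co$sessions)
  # rate 1 for smile only -> smile always absent, others always present
  cc1 <- cohort_config(n_participants = 80, seed = 5,
                       missing_rate = c(finger_tapping = 0, smile = 1, speech = 0))
  out <- inject_missingness(co$sessions, cc1, seed = 1)
  expect_true(all(is.na(out$smile_000)))
  expect_true(all(!is.na(out$tap_000)))
  expect_true(all(!is.na(out$speech_0000)))
  # binomial concentration at rate 0.3 over many sessions
  co2 <- small_cohort(n = 1200, seed = 6, sessions = c(2L, 2L))
  cc3 <- cohort_config(n_participants = 1200, seed = 6,
                       missing_rate = c(finger_tapping = 0, smile = 0, speech = 0.3))
  out2 <- inject_missingness(co2$sessions, cc3, seed = 2)
  frac <- mean(is.na(out2$speech_0000))
  expect_gt(frac, 0.27)
  expect_lt(frac, 0.33)
  # no session ever loses all three blocks
  cc4 <- cohort_config(n_participants = 80, seed = 5,
                       missing_rate = c(finger_tapping = 0.9, smile = 0.9,
                                        speech = 0.9))
  out3 <- inject_missingness(co$sessions, cc4, seed = 3)
  n_blocks <- (!is.na(out3$tap_000)) + (!is.na(out3$smile_000)) +
    (!is.na(out3$speech_0000))
  expect_true(all(n_blocks >= 1))
})

test_that("participant records respect their invariants", {
  co <- small_cohort(n = 120, pd_fraction = 0.4, seed = 13)
  p <- co$participants
  # stage only for PD participants, in 1..3
  expect_true(all(is.na(p$hy_stage[p$pd_status == 0])))
  expect_true(all(p$hy_stage[!is.na(p$hy_stage)] %in% 1:3))
  # known ages within bounds
  ages <- p$age_years[!is.na(p$age_years)]
  expect_true(all(ages >= 18 & ages <= 100))
  expect_false(any(duplicated(p$participant_id)))
  # sessions reference known participants and have contiguous indices
  s <- co$sessions
  expect_true(all(s$participant_id %in% p$participant_id))
  first <- tapply(s$session_index, s$participant_id, min)
  expect_true(all(first == 0))
})

test_that("raising one modality's effect size never hurts its discriminability", {
  # Bayes-proxy oracle: AUROC of the mean of informative coordinates,
  # checked across three effect-size levels and averaged over seeds.
  levels_auc <- sapply(c(0.3, 0.8, 1.5), function(es) {
    mean(sapply(1:3, function(s) {
      cc <- cohort_config(n_participants = 200, pd_fraction = 0.5,
                          modality_signal = c(finger_tapping = es, smile = 0.5,
                                              speech = 0.5),
                          missing_rate = c(finger_tapping = 0, smile = 0,
                                           speech = 0),
                          seed = 500 + s)
      co <- generate_cohort(cc)
      k <- cc$n_informative[["finger_tapping"]]
      score <- rowMeans(as.matrix(
        co$sessions[, modality_columns("finger_tapping")[seq_len(k)]]))
      roc_auc(co$sessions$pd_status, score)
    }))
  })
  expect_true(all(diff(levels_auc) > -0.02))
})
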