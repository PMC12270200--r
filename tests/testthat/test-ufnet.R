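# Fusion network: projection contract, calibrated attention, training,
# fused MC prediction, withholding, parameter counting.

toy_spec <- function(...) {
  fusion_spec(projection_dim = 4L, query_dim = 2L, hidden_dim = 2L,
              dropout_p = 0, eta = 1, mc_rounds = 5L, epochs = 5L,
              batch_size = 8L, seed = 1L, ...)
}

toy_params <- function(spec = toy_spec(), dims = c(3L, 3L, 3L), seed = 1) {
  set.seed(seed)
  ufnet_init(dims, spec)
}

test_that("projection output is layer-normalized with a degenerate-input guard", {
  set.seed(1)
  proj <- list(W = matrix(rnorm(20), 5, 4), b = rnorm(4))
  out <- project_modality(matrix(rnorm(40), 8, 5), proj)
  expect_identical(dim(out), c(8L, 4L))
  expect_true(all(abs(rowMeans(out)) < 1e-6))
  expect_true(all(abs(rowMeans(out^2) - 1) < 1e-4))
  # zero weights and bias -> all-zero pre-normalization -> zero output
  proj0 <- list(W = matrix(0, 5, 4), b = rep(0, 4))
  expect_identical(project_modality(rnorm(5), proj0), matrix(0, 1, 4))
  # deterministic with dropout disabled
  x <- rnorm(5)
  expect_identical(project_modality(x, proj), project_modality(x, proj))
  expect_error(project_modality(rnorm(3), proj), "width")
})

test_that("calibrated attention reduces to softmax attention under symmetry", {
  spec <- toy_spec()
  params <- toy_params(spec)
  attn <- params[c("Wq", "bq", "Wk", "bk", "Wv", "bv")]
  set.seed(2)
  H <- lapply(1:3, function(i) rnorm(4))
  # equal sigmas: exp factors cancel under renormalization
  eq <- calibrated_attention(H, c(0.2, 0.2, 0.2), attn, eta = 5)
  un <- calibrated_attention(H, c(0, 0, 0), attn, eta = 5)
  expect_equal(eq$weights, un$weights, tolerance = 1e-12)
  expect_equal(eq$contexts, un$contexts, tolerance = 1e-12)
  # eta = 0 makes calibration a no-op for any sigmas
  a0 <- calibrated_attention(H, c(0.5, 0.01, 0.3), attn, eta = 0)
  expect_equal(a0$weights, un$weights, tolerance = 1e-12)
  # rows always sum to 1
  big <- calibrated_attention(H, c(0.5, 0.01, 0.3), attn, eta = 10)
  expect_equal(rowSums(big$weights), rep(1, 3), tolerance = 1e-9)
  expect_error(calibrated_attention(H, c(-0.1, 0, 0), attn, eta = 1),
               "nonnegative")
})

test_that("a very uncertain modality loses essentially all attention mass", {
  spec <- toy_spec()
  params <- toy_params(spec, seed = 3)
  attn <- params[c("Wq", "bq", "Wk", "bk", "Wv", "bv")]
  set.seed(3)
  H <- lapply(1:3, function(i) rnorm(4))
  # smile is token 2; sigma_smile = 10 with eta = 10 -> exp(-100) factor
  res <- calibrated_attention(H, c(0, 10, 0), attn, eta = 10)
  expect_true(all(res$weights[, 2] < 1e-6))
  # weights nonincreasing in the token's own sigma, all else fixed
  w_seq <- sapply(c(0, 0.2, 0.5, 1, 2), function(sg) {
    calibrated_attention(H, c(0, sg, 0), attn, eta = 2)$weights[1, 2]
  })
  expect_true(all(diff(w_seq) <= 1e-12))
})

test_that("analytic fusion gradients match finite differences", {
  spec <- toy_spec()
  dims <- c(3L, 3L, 3L)
  params <- toy_params(spec, dims = dims, seed = 4)
  set.seed(5)
  B <- 6
  Xs <- lapply(dims, function(d) matrix(rnorm(B * d), B, d))
  pbar <- matrix(runif(B * 3), B, 3)
  sig <- matrix(runif(B * 3, 0, 0.3), B, 3)
  y <- rep(c(0, 1), 3)
  loss_at <- function(p) {
    bce_loss(parkscreen:::ufnet_forward(p, Xs, pbar, sig, spec)$prob, y)
  }
  cache <- parkscreen:::ufnet_forward(params, Xs, pbar, sig, spec)
  grads <- parkscreen:::ufnet_backward(params, cache, y, spec)
  eps <- 1e-6
  for (nm in c("proj1_W", "proj2_b", "Wq", "Wk", "Wv", "bv",
               "head_W1", "head_W2", "head_b2")) {
    p <- params[[nm]]
    picks <- if (length(p) > 4) sample(length(p), 4) else seq_along(p)
    for (i in picks) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params
      pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]][i]), num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("fusion training requires complete sessions and learns signal", {
  co <- small_cohort(n = 160, pd_fraction = 0.5, seed = 21, sessions = c(2L, 2L))
  sess <- co$sessions
  tr <- sess$participant_id %in% unique(sess$participant_id)[1:110]
  stack <- fit_full_stack(sess[tr, ], epochs = 50)
  # head input width = 3 * projection_dim + 3
  expect_identical(nrow(stack$ufnet$params$head_W1),
                   3L * stack$ufnet$spec$projection_dim + 3L)
  mc <- fuse_predict(stack$ufnet, sess[!tr, ], seed = 2)
  expect_gt(roc_auc(sess[!tr, ]$label_at_session, mc$mean_p), 0.8)
  # logged per-pass samples reproduce the summary exactly
  s <- attr(mc, "samples")
  expect_equal(mc$mean_p, rowMeans(s))
  expect_equal(mc$sd_p, apply(s, 1, sd))
  # missing block -> completeness error naming the session
  broken <- sess[!tr, ]
  broken[1, modality_columns("smile")] <- NA_real_
  expect_error(train_ufnet(broken, stack$pipes, stack$ufnet$spec),
               "missing a modality block")
  expect_error(fuse_predict(stack$ufnet, broken), "missing a modality block")
})

test_that("fusion training and prediction are reproducible by seed", {
  co <- small_cohort(n = 60, pd_fraction = 0.5, seed = 22)
  sess <- co$sessions
  a <- fit_full_stack(sess, epochs = 10, seed = 5)
  b <- fit_full_stack(sess, epochs = 10, seed = 5)
  expect_identical(a$ufnet$params, b$ufnet$params)
  expect_identical(a$ufnet$task_hashes, b$ufnet$task_hashes)
  mc1 <- fuse_predict(a$ufnet, sess[1:10, ], seed = 9)
  mc2 <- fuse_predict(b$ufnet, sess[1:10, ], seed = 9)
  expect_identical(mc1$mean_p, mc2$mean_p)
})

test_that("zero dropout everywhere gives zero fused spread", {
  co <- small_cohort(n = 50, pd_fraction = 0.5, seed = 23)
  sess <- co$sessions
  stack <- fit_full_stack(sess, epochs = 10, dropout_p = 0, seed = 6)
  mc <- fuse_predict(stack$ufnet, sess[1:8, ], seed = 3)
  expect_identical(mc$sd_p, rep(0, 8))
})

test_that("decide maps intervals to verdicts per the withholding rule", {
  mk <- function(vals) {
    parkscreen:::summarize_mc_samples(matrix(vals, nrow = 1), 0.95)
  }
  expect_identical(decide(mk(rep(0.9, 30)))$verdict, "positive")
  expect_identical(decide(mk(rep(0.2, 30)))$verdict, "negative")
  expect_identical(decide(mk(seq(0.3, 0.7, length.out = 30)))$verdict, "withheld")
  # threshold inside the degenerate interval -> withheld
  expect_identical(decide(mk(rep(0.5, 30)))$verdict, "withheld")
  # recomputation at another level from logged samples
  spread <- mk(c(rep(0.52, 28), 0.45, 0.44))
  expect_identical(decide(spread, level = 0.95)$verdict, "withheld")
  expect_identical(decide(spread, level = 0.5)$verdict, "positive")
})

test_that("parameter count matches hand arithmetic and is architecture-only", {
  spec <- toy_spec()
  dims <- c(3L, 4L, 5L)
  params <- toy_params(spec, dims = dims)
  ct <- count_parameters(params)
  P <- 4; q <- 2; H <- 2
  hand <- (3 * P + P) + (4 * P + P) + (5 * P + P) +  # projections + biases
    2 * (P * q + q) +                                # query, key
    (P * P + P) +                                    # value
    ((3 * P + 3) * H + H) +                          # head hidden
    (H * 1 + 1)                                      # head output
  expect_identical(ct$total, as.integer(hand))
  # doubling hidden_dim strictly increases the count
  spec2 <- fusion_spec(projection_dim = 4L, query_dim = 2L, hidden_dim = 4L,
                       dropout_p = 0, epochs = 5L, seed = 1L)
  ct2 <- count_parameters(ufnet_init(dims, spec2))
  expect_gt(ct2$total, ct$total)
  # count is invariant to training (architecture-only)
  co <- small_cohort(n = 40, pd_fraction = 0.5, seed = 24)
  stack <- fit_full_stack(co$sessions, epochs = 5, seed = 2)
  before <- count_parameters(parkscreen:::with_seed(1, {
    ufnet_init(stack$ufnet$input_dims, stack$ufnet$spec)
  }))
  expect_identical(count_parameters(stack$ufnet)$total, before$total)
})
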