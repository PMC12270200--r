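# Shared fixtures, built in code at test time.

MODS <- c("finger_tapping", "smile", "speech")

# A small cohort with all three blocks present (no missingness) unless asked.
small_cohort <- function(n = 60, pd_fraction = 0.5, seed = 42,
                         missing = 0, sessions = c(1L, 2L), ...) {
  cc <- cohort_config(
    n_participants = n, pd_fraction = pd_fraction,
    sessions_per_participant = sessions,
    missing_rate = c(finger_tapping = missing, smile = missing, speech = missing),
    seed = seed, ...)
  generate_cohort(cc)
}

# Two well-separated Gaussian blobs in 2-D (linearly separable).
blob_data <- function(n_per_class = 100, separation = 6, seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
               matrix(rnorm(2 * n_per_class, mean = separation), ncol = 2))
    y <- rep(c(0, 1), each = n_per_class)
    list(x = scale(x), y = y)
  })
}

# A participant pool with controllable demographics for sampler tests.
demo_pool <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("D%04d", seq_len(n)),
    pd_status = rep_len(c(1L, 0L), n),
    sex = sample(c("male", "female", "unknown"), n, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10)),
    ethnicity = sample(c("white", "non_white", "unknown"), n, replace = TRUE,
                       prob = c(0.6, 0.3, 0.1)),
    age_years = ifelse(runif(n) < 0.1, NA_real_, runif(n, 25, 85)),
    stringsAsFactors = FALSE)
}

# Exhaustive minimum of the diversity loss over all class-respecting subsets.
brute_force_balance <- function(pool, n_select, pd_fraction = 0.5,
                                targets = diversity_targets()) {
  n_pd <- round(n_select * pd_fraction)
  pd_idx <- which(pool$pd_status == 1)
  non_idx <- which(pool$pd_status == 0)
  pd_sets <- utils::combn(pd_idx, n_pd, simplify = FALSE)
  non_sets <- utils::combn(non_idx, n_select - n_pd, simplify = FALSE)
  best <- Inf
  for (a in pd_sets) {
    for (b in non_sets) {
      l <- diversity_loss(pool[c(a, b), , drop = FALSE], targets)
      if (l < best) best <- l
    }
  }
  best
}

# Train the three task pipelines plus a fusion model on a complete-session
# table; returns everything needed for fused prediction.
fit_full_stack <- function(train, epochs = 60, dropout_p = 0.25, seed = 3,
                           fusion_epochs = epochs, eta = 1) {
  pipes <- lapply(stats::setNames(MODS, MODS), function(m) {
    fit_task_pipeline(train, m,
                      spec = task_model_spec(input_dim = 1, epochs = epochs,
                                             dropout_p = dropout_p, seed = seed),
                      corr_threshold = 0.98)
  })
  fs <- fusion_spec(projection_dim = 128L, query_dim = 32L, hidden_dim = 16L,
                    dropout_p = dropout_p, eta = eta, epochs = fusion_epochs,
                    seed = seed + 1L)
  list(pipes = pipes, ufnet = train_ufnet(train, pipes, fs))
}
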