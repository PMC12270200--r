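# Synthetic multimodal cohort generator.
#
# Emulates the statistical structure of a remote PD screening study: a latent
# per-participant severity factor drives modality-specific signal in three
# fixed-width feature blocks (finger tapping 130, smile 42, speech 1024),
# with demographic subgroups, multi-session participants, per-task
# missingness, and recording-duration outliers.

MODALITIES <- c("finger_tapping", "smile", "speech")

MODALITY_DIMS <- c(finger_tapping = 130L, smile = 42L, speech = 1024L)

DURATION_COLS <- c(finger_tapping = "dur_tap_s", smile = "dur_smile_s",
                   speech = "dur_speech_s")

#' Feature column names for one modality
#'
#' @param modality One of `"finger_tapping"`, `"smile"`, `"speech"`.
#' @return Character vector of column names (`tap_000`..`tap_129`,
#'   `smile_000`..`smile_041`, `speech_0000`..`speech_1023`).
#' @export
modality_columns <- function(modality) {
  modality <- match.arg(modality, MODALITIES)
  switch(modality,
    finger_tapping = sprintf("tap_%03d", 0:129),
    smile          = sprintf("smile_%03d", 0:41),
    speech         = sprintf("speech_%04d", 0:1023))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reflect the composition of the study population the generator
#' emulates: 35.9% PD prevalence, 52% female, ~11% non-white, mostly older
#' adults, 31% of PD participants with a documented Hoehn--Yahr stage, and a
#' modality signal ordering speech > finger tapping > smile.
#'
#' @param n_participants Number of enrollees.
#' @param pd_fraction Proportion with PD; the PD count is
#'   `round(n_participants * pd_fraction)` exactly.
#' @param subgroup_targets Named list (`sex`, `ethnicity`, `age`) of named
#'   proportion vectors, each summing to 1. The `age` entry uses bins
#'   `under50` / `over50` / `unknown`.
#' @param sessions_per_participant Integer range `c(min, max)`.
#' @param modality_signal Named effect sizes (standardized mean separation
#'   contributed by each modality's informative subspace).
#' @param n_informative Named counts of signal-carrying coordinates per
#'   modality; must not exceed the block widths 130/42/1024.
#' @param noise_sd Standard deviation of per-coordinate Gaussian noise.
#' @param missing_rate Named per-modality probability that a session's block
#'   is missing (task skipped or failed quality checks).
#' @param duration_outlier_rate Probability that a task duration is drawn at
#'   mean +/- 5 SD instead of the nominal Normal(30 s, 5 s).
#' @param stage_thresholds Two increasing quantile levels in (0,1) cutting
#'   PD severity into Hoehn--Yahr stages 1--3.
#' @param stage_fraction Fraction of PD participants with a recorded stage.
#' @param confirmed_fraction Fraction of PD labels that are clinically
#'   confirmed (the rest are self-reported).
#' @param seed Integer root seed; all draws derive from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 400,
                          pd_fraction = 0.359,
                          subgroup_targets = list(
                            sex = c(male = 0.46, female = 0.52, unknown = 0.02),
                            ethnicity = c(white = 0.792, non_white = 0.108, unknown = 0.10),
                            age = c(under50 = 0.20, over50 = 0.75, unknown = 0.05)),
                          sessions_per_participant = c(1L, 3L),
                          modality_signal = c(finger_tapping = 1.0, smile = 0.5, speech = 1.5),
                          n_informative = c(finger_tapping = 20L, smile = 10L, speech = 64L),
                          noise_sd = 1,
                          missing_rate = c(finger_tapping = 0.15, smile = 0.15, speech = 0.15),
                          duration_outlier_rate = 0.01,
                          stage_thresholds = c(1 / 3, 2 / 3),
                          stage_fraction = 0.31,
                          confirmed_fraction = 0.567,
                          seed = 1L) {
  n_participants <- check_count(n_participants, "n_participants", min = 0L)
  check_proportion(pd_fraction, "pd_fraction")
  if (!is.list(subgroup_targets) ||
      !all(c("sex", "ethnicity", "age") %in% names(subgroup_targets))) {
    stopf("`subgroup_targets` must be a named list with sex, ethnicity and age entries")
  }
  for (a in names(subgroup_targets)) {
    p <- subgroup_targets[[a]]
    check_proportion(p, paste0("subgroup_targets$", a))
    if (abs(sum(p) - 1) > 1e-9) {
      stopf("proportions for attribute '%s' must sum to 1 (got %.12f)", a, sum(p))
    }
  }
  if (length(sessions_per_participant) != 2L ||
      any(sessions_per_participant < 1L) ||
      sessions_per_participant[1] > sessions_per_participant[2]) {
    stopf("`sessions_per_participant` must be an increasing integer range c(min, max)")
  }
  for (m in MODALITIES) {
    if (is.na(modality_signal[m]) || modality_signal[m] < 0) {
      stopf("`modality_signal` must name all modalities with effect sizes >= 0")
    }
    if (is.na(n_informative[m]) || n_informative[m] < 1 ||
        n_informative[m] > MODALITY_DIMS[m]) {
      stopf("`n_informative[%s]` must be in [1, %d]", m, MODALITY_DIMS[m])
    }
    if (is.na(missing_rate[m])) stopf("`missing_rate` must name all modalities")
  }
  check_proportion(missing_rate, "missing_rate")
  if (all(missing_rate >= 1)) stopf("at least one modality must have missing_rate < 1")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  check_proportion(duration_outlier_rate, "duration_outlier_rate")
  check_proportion(stage_fraction, "stage_fraction")
  check_proportion(confirmed_fraction, "confirmed_fraction")
  if (length(stage_thresholds) != 2L || any(diff(stage_thresholds) <= 0) ||
      any(stage_thresholds <= 0) || any(stage_thresholds >= 1)) {
    stopf("`stage_thresholds` must be two increasing quantile levels in (0, 1)")
  }
  structure(list(
    n_participants = n_participants, pd_fraction = pd_fraction,
    subgroup_targets = subgroup_targets,
    sessions_per_participant = as.integer(sessions_per_participant),
    modality_signal = modality_signal[MODALITIES],
    n_informative = as.integer(n_informative[MODALITIES]) |>
      stats::setNames(MODALITIES),
    noise_sd = noise_sd, missing_rate = missing_rate[MODALITIES],
    duration_outlier_rate = duration_outlier_rate,
    stage_thresholds = stage_thresholds, stage_fraction = stage_fraction,
    confirmed_fraction = confirmed_fraction, seed = as.integer(seed)),
    class = "cohort_config")
}

#' Simulate one modality feature vector
#'
#' The first `n_informative[m]` coordinates have mean
#' `severity * effect_size` (each informative coordinate separates the class
#' severity means, +1 vs -1, by twice the configured effect size); the
#' remaining coordinates are pure Gaussian noise with sd `noise_sd`.
#'
#' @param severity Latent severity scalar for the session.
#' @param modality Modality name.
#' @param config A [cohort_config()].
#' @return Numeric vector of length 130/42/1024 by modality.
#' @export
simulate_modality_vector <- function(severity, modality, config) {
  modality <- match.arg(modality, MODALITIES)
  d <- MODALITY_DIMS[[modality]]
  k <- config$n_informative[[modality]]
  loading <- config$modality_signal[[modality]]
  x <- stats::rnorm(d, mean = 0, sd = config$noise_sd)
  x[seq_len(k)] <- x[seq_len(k)] + severity * loading
  x
}

simulate_duration <- function(config) {
  d <- stats::rnorm(1, 30, 5)
  if (stats::runif(1) < config$duration_outlier_rate) {
    d <- 30 + sample(c(-5, 5), 1) * 5
  }
  max(d, 0.1)
}

#' Generate a synthetic multimodal cohort
#'
#' Participants get a latent severity `s ~ Normal(+1, 1)` (PD) or
#' `Normal(-1, 1)` (non-PD); sessions of one participant share `s` plus
#' `Normal(0, sd = 0.25)` session jitter, giving the within-participant
#' correlation longitudinal collection implies. Every
#' random draw for a participant comes from a child stream keyed by the
#' participant ID, so identical config + seed reproduces identical output
#' regardless of construction order.
#'
#' @param config A [cohort_config()].
#' @param apply_missingness Apply [inject_missingness()] with the configured
#'   rates before returning (default `TRUE`).
#' @return List with `participants` (one row per enrollee: demographics, PD
#'   status and provenance, optional stage, latent severity) and `sessions`
#'   (the wide per-session table: IDs, demographics, durations, and the three
#'   feature blocks; missing blocks are `NA`).
#' @export
generate_cohort <- function(config, apply_missingness = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  if (n < 1) stopf("empty cohort: n_participants must be >= 1")
  n_pd <- round(n * config$pd_fraction)
  ids <- sprintf("P%05d", seq_len(n))
  pd_ids <- with_seed(config$seed, sample(ids, n_pd))
  pd_status <- as.integer(ids %in% pd_ids)

  draw_cat <- function(p) names(p)[sample.int(length(p), 1, prob = p)]
  tg <- config$subgroup_targets

  participants <- vector("list", n)
  session_rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- ids[i]
    with_seed(child_seed(config$seed, id), {
      sex <- draw_cat(tg$sex)
      ethnicity <- draw_cat(tg$ethnicity)
      age_bin <- draw_cat(tg$age)
      age <- switch(age_bin,
        under50 = stats::runif(1, 18, 49.99),
        over50  = stats::runif(1, 50, 93),
        unknown = NA_real_)
      s <- stats::rnorm(1, mean = if (pd_status[i] == 1) 1 else -1, sd = 1)
      provenance <- if (pd_status[i] == 1) {
        if (stats::runif(1) < config$confirmed_fraction) "clinically_confirmed"
        else "self_reported"
      } else "self_reported"
      stage_recorded <- pd_status[i] == 1 && stats::runif(1) < config$stage_fraction
      n_sess <- sample(seq(config$sessions_per_participant[1],
                           config$sessions_per_participant[2]), 1)
      sess <- vector("list", n_sess)
      for (j in seq_len(n_sess)) {
        s_j <- s + stats::rnorm(1, 0, 0.25)
        feats <- unlist(lapply(MODALITIES, function(m) {
          simulate_modality_vector(s_j, m, config)
        }))
        durs <- vapply(MODALITIES, function(m) simulate_duration(config), numeric(1))
        sess[[j]] <- c(session_index = j - 1L, severity_session = s_j,
                       stats::setNames(durs, DURATION_COLS), feats)
      }
      participants[[i]] <- list(participant_id = id, pd_status = pd_status[i],
                                label_provenance = provenance, sex = sex,
                                ethnicity = ethnicity, age_years = age,
                                stage_recorded = stage_recorded, severity = s)
      session_rows[[i]] <- sess
    })
  }

  pdf <- as.data.frame(data.table::rbindlist(lapply(participants, as.data.frame)))
  # H&Y stage: quantile bins of severity among PD participants.
  pdf$hy_stage <- NA_integer_
  if (n_pd > 0) {
    s_pd <- pdf$severity[pdf$pd_status == 1]
    cuts <- stats::quantile(s_pd, probs = config$stage_thresholds, names = FALSE)
    stage_all <- 1L + findInterval(pdf$severity, cuts)
    pdf$hy_stage <- ifelse(pdf$pd_status == 1 & pdf$stage_recorded,
                           stage_all, NA_integer_)
  }
  pdf$stage_recorded <- NULL

  feat_names <- unlist(lapply(MODALITIES, modality_columns))
  sessions <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    rows <- session_rows[[i]]
    m <- do.call(rbind, rows)
    dt <- data.table::as.data.table(m)
    data.table::setnames(dt, c("session_index", "severity_session",
                               unname(DURATION_COLS), feat_names))
    data.table::set(dt, j = "participant_id", value = ids[i])
    dt
  }))
  meta <- pdf[, c("participant_id", "pd_status", "label_provenance", "sex",
                  "ethnicity", "age_years", "hy_stage")]
  sessions <- data.table::as.data.table(
    merge(meta, as.data.frame(sessions), by = "participant_id", sort = FALSE))
  sessions$label_at_session <- sessions$pd_status
  front <- c("participant_id", "session_index", "pd_status", "label_at_session",
             "label_provenance", "sex", "ethnicity", "age_years", "hy_stage",
             "severity_session", unname(DURATION_COLS))
  data.table::setcolorder(sessions, c(front, feat_names))
  data.table::setorder(sessions, participant_id, session_index)
  sessions <- as.data.frame(sessions)
  pdf <- as.data.frame(pdf)

  if (apply_missingness) {
    sessions <- inject_missingness(sessions, config,
                                   seed = child_seed(config$seed, "missingness"))
  }
  list(participants = pdf, sessions = sessions)
}

#' Delete modality blocks at the configured missingness rates
#'
#' Each modality block of each session is independently deleted with its
#' per-modality rate (the block's features and its duration become `NA`),
#' emulating skipped tasks and failed automated quality checks. A session
#' never loses all three blocks: the three deletion draws are redrawn until
#' at least one block survives.
#'
#' @param sessions Wide session table.
#' @param config A [cohort_config()] supplying `missing_rate`.
#' @param seed Integer seed for the deletion draws.
#' @return The session table with deleted blocks set to `NA`.
#' @export
inject_missingness <- function(sessions, config, seed = config$seed) {
  rates <- config$missing_rate[MODALITIES]
  if (all(rates >= 1)) stopf("cannot delete all three blocks from every session")
  if (all(rates == 0)) return(sessions)
  n <- nrow(sessions)
  drop <- with_seed(seed, {
    d <- matrix(stats::runif(n * 3), n, 3) <
      matrix(rates, n, 3, byrow = TRUE)
    # Redraw sessions that would lose all three blocks until one survives.
    bad <- which(rowSums(d) == 3L)
    while (length(bad)) {
      d[bad, ] <- matrix(stats::runif(length(bad) * 3), length(bad), 3) <
        matrix(rates, length(bad), 3, byrow = TRUE)
      bad <- bad[rowSums(d[bad, , drop = FALSE]) == 3L]
    }
    d
  })
  for (k in seq_along(MODALITIES)) {
    m <- MODALITIES[k]
    rows <- drop[, k]
    if (any(rows)) {
      sessions[rows, modality_columns(m)] <- NA_real_
      sessions[rows, DURATION_COLS[[m]]] <- NA_real_
    }
  }
  sessions
}

#' Session identifiers, block extraction, completeness
#'
#' `session_ids()` builds the canonical `participant:index` key;
#' `get_modality_matrix()` extracts one block as a numeric matrix (rows with
#' missing blocks are all-`NA`); `is_complete_session()` flags sessions with
#' all three blocks present.
#'
#' @param sessions Wide session table.
#' @param modality Modality name.
#' @return A character vector, a numeric matrix, or a logical vector.
#' @export
session_ids <- function(sessions) {
  paste(sessions$participant_id, sessions$session_index, sep = ":")
}

#' @rdname session_ids
#' @export
get_modality_matrix <- function(sessions, modality) {
  cols <- modality_columns(modality)
  as.matrix(sessions[, cols, drop = FALSE])
}

#' @rdname session_ids
#' @export
is_complete_session <- function(sessions) {
  Reduce(`&`, lapply(MODALITIES, function(m) {
    !is.na(sessions[[modality_columns(m)[1]]])
  }))
}

#' Write / read the cohort CSV dialect
#'
#' One CSV with identifier, demographic, duration and feature columns; empty
#' cells encode missing blocks. A sidecar `<path>.meta` key-value text file
#' records the generating configuration and seed.
#'
#' @param sessions Wide session table.
#' @param path Output CSV path.
#' @param config Optional [cohort_config()] recorded in the sidecar.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the table.
#' @export
write_cohort <- function(sessions, path, config = NULL) {
  out <- sessions
  out$severity_session <- NULL  # latent; not part of the on-disk dialect
  data.table::fwrite(out, path, na = "")
  if (!is.null(config)) {
    flat <- unlist(config[setdiff(names(config), "subgroup_targets")])
    tg <- unlist(config$subgroup_targets)
    lines <- c(paste(names(flat), flat, sep = "="),
               paste(paste0("subgroup_targets.", names(tg)), tg, sep = "="))
    writeLines(sort(lines), paste0(path, ".meta"))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  dt <- data.table::fread(path, na.strings = "", data.table = FALSE)
  dt$participant_id <- as.character(dt$participant_id)
  dt
}
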