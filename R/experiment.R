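# Experiment configuration, orchestration, and reproducible manifests.

#' Default experiment configuration
#'
#' A nested list mirroring each stage of the pipeline: synthetic cohort,
#' duration filter, GA splits, preprocessing, task-model search, fusion
#' search, and evaluation. Sizes default to a small cohort so the full
#' pipeline runs quickly on one CPU; the search spaces default to narrow,
#' well-behaved ranges (the full published search space is available via
#' [task_search_space()]).
#'
#' @return Nested configuration list.
#' @export
default_experiment_config <- function() {
  list(
    seed = 1L,
    cohort = list(
      n_participants = 300L, pd_fraction = 0.45,
      sessions_min = 1L, sessions_max = 3L,
      signal_finger_tapping = 1.0, signal_smile = 0.5, signal_speech = 1.5,
      noise_sd = 1, missing_rate = 0.15, duration_outlier_rate = 0.01),
    filter = list(n_sd = 3),
    split = list(test_size = 60L, dev_size = 40L, pd_fraction = 0.5,
                 restarts = 50L, max_stale = 500L),
    preprocess = list(scaler = "standardize", corr_threshold = 0.98,
                      smote_ratio = NULL, smote_k = 5L),
    task = list(
      budget = 2L,
      space = list(
        hidden_dims = list(values = c(16L, 32L)),
        batch_size = list(values = 256L),
        learning_rate = list(min = 0.002, max = 0.02),
        dropout_p = list(min = 0.1, max = 0.3),
        epochs = list(min = 40L, max = 80L, integer = TRUE),
        optimizer = list(values = "adamw"),
        momentum = list(min = 0.9, max = 0.9),
        scheduler = list(values = "none"),
        step_size = list(values = 10L),
        patience = list(values = 5L),
        gamma = list(min = 0.5, max = 0.95),
        mc_rounds = list(values = 30L))),
    fusion = list(
      budget = 2L,
      space = list(
        projection_dim = list(values = 128L),
        query_dim = list(values = c(32L, 64L)),
        hidden_dim = list(values = c(16L, 32L)),
        dropout_p = list(min = 0.1, max = 0.3),
        eta = list(min = 0.1, max = 10),
        mc_rounds = list(values = 30L),
        learning_rate = list(min = 0.002, max = 0.02),
        batch_size = list(values = 256L),
        epochs = list(min = 40L, max = 80L, integer = TRUE),
        optimizer = list(values = "adamw"),
        momentum = list(min = 0.9, max = 0.9),
        scheduler = list(values = "none"),
        step_size = list(values = 10L),
        patience = list(values = 5L),
        gamma = list(min = 0.5, max = 0.95)),
      decision_threshold = 0.5, ci_level = 0.95),
    evaluation = list(bootstrap = 1000L, level = 0.95, ece_bins = 10L))
}

validate_against <- function(value, template, path, problems) {
  if (is.list(template) && !is.null(names(template))) {
    if (!is.list(value)) {
      return(c(problems, sprintf("%s: expected a section, got %s", path,
                                 class(value)[1])))
    }
    unknown <- setdiff(names(value), names(template))
    for (u in unknown) {
      problems <- c(problems, sprintf("%s.%s: unknown key", path, u))
    }
    for (k in intersect(names(value), names(template))) {
      problems <- validate_against(value[[k]], template[[k]],
                                   paste(path, k, sep = "."), problems)
    }
    problems
  } else {
    if (!is.null(template) && !is.null(value) &&
        is.numeric(template) && !is.numeric(value)) {
      c(problems, sprintf("%s: expected numeric, got %s", path,
                          class(value)[1]))
    } else if (!is.null(template) && !is.null(value) &&
               is.character(template) && !is.character(value)) {
      c(problems, sprintf("%s: expected character, got %s", path,
                          class(value)[1]))
    } else {
      problems
    }
  }
}

merge_config <- function(defaults, user) {
  if (!is.list(user)) return(user)
  out <- defaults
  for (k in names(user)) {
    replace_leaf <- is.list(user[[k]]) &&
      any(c("values", "min", "max") %in% names(user[[k]]))
    val <- if (!replace_leaf && is.list(defaults[[k]]) &&
               !is.null(names(defaults[[k]])) && is.list(user[[k]])) {
      merge_config(defaults[[k]], user[[k]])
    } else {
      user[[k]]
    }
    out[k] <- list(val)  # preserves explicit NULLs (disabled settings)
  }
  out
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML document, rejects unknown keys and type mismatches (all
#' problems listed at once), and fills every omitted setting from
#' [default_experiment_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated configuration list of class `experiment_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- default_experiment_config()
  # search-space dimensions are free-form below the dimension name
  template <- defaults
  problems <- character()
  shallow_check <- function(user, template, path) {
    for (k in names(user)) {
      if (!k %in% names(template)) {
        problems <<- c(problems, sprintf("%s%s: unknown key", path, k))
      }
    }
  }
  shallow_check(user, template, "")
  for (sec in intersect(names(user), names(template))) {
    if (sec %in% c("seed")) next
    if (is.list(user[[sec]])) {
      shallow_check(user[[sec]], template[[sec]], paste0(sec, "."))
    }
  }
  probs2 <- validate_against(user[setdiff(names(user), "task")],
                             template[setdiff(names(template), "task")],
                             "config", character())
  probs2 <- probs2[!grepl("space", probs2)]  # space dims validated at sampling
  problems <- unique(c(problems, probs2))
  if (length(problems)) {
    stopf("invalid configuration:\n  %s", paste(problems, collapse = "\n  "))
  }
  cfg <- merge_config(defaults, user)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "experiment_config"
  cfg
}

#' @rdname load_config
#' @param config An `experiment_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

cohort_config_from <- function(cfg) {
  co <- cfg$cohort
  cohort_config(
    n_participants = co$n_participants, pd_fraction = co$pd_fraction,
    sessions_per_participant = c(co$sessions_min, co$sessions_max),
    modality_signal = c(finger_tapping = co$signal_finger_tapping,
                        smile = co$signal_smile, speech = co$signal_speech),
    noise_sd = co$noise_sd,
    missing_rate = c(finger_tapping = co$missing_rate, smile = co$missing_rate,
                     speech = co$missing_rate),
    duration_outlier_rate = co$duration_outlier_rate,
    seed = cfg$seed)
}

#' Run the full screening experiment
#'
#' Executes the pipeline end to end: simulate a cohort, apply the duration
#' filter, build GA-balanced splits, fit per-modality preprocessing and
#' task-model search, search and train the fusion network, predict the test
#' sessions with withholding, and evaluate. Every artifact is written to
#' `out_dir` and a manifest of content hashes makes the run replayable;
#' identical config + seed reproduces identical artifacts.
#'
#' @param config An `experiment_config` from [load_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the manifest path, the metric report, and
#'   the trained fusion model.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(path) files <<- c(files, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(config, cfg_path)
  emit(cfg_path)

  cohort <- stage("simulate", {
    cc <- cohort_config_from(config)
    generate_cohort(cc)
  })
  cohort_path <- file.path(out_dir, "cohort.csv")
  stage("simulate", write_cohort(cohort$sessions, cohort_path,
                                 config = cohort_config_from(config)))
  emit(cohort_path)
  emit(paste0(cohort_path, ".meta"))

  sessions <- stage("duration_filter", {
    rep <- filter_sessions_by_duration(cohort$sessions, n_sd = config$filter$n_sd)
    det_path <- file.path(out_dir, "filter_report.csv")
    data.table::fwrite(rep$detail, det_path)
    emit(det_path)
    apply_duration_filter(cohort$sessions, rep)
  })

  splits <- stage("split", {
    sp <- make_splits(cohort$participants, config$split$test_size,
                      config$split$dev_size, config$split$pd_fraction,
                      restarts = config$split$restarts,
                      max_stale = config$split$max_stale,
                      seed = child_seed(config$seed, "split"))
    sp_path <- file.path(out_dir, "splits.csv")
    data.table::fwrite(sp$assignment, sp_path)
    emit(sp_path)
    log_path <- file.path(out_dir, "ga_log.csv")
    data.table::fwrite(rbind(cbind(stage = "test", sp$test_run$log),
                             cbind(stage = "dev", sp$dev_run$log)), log_path)
    emit(log_path)
    sp
  })
  split_of <- stats::setNames(splits$assignment$split,
                              splits$assignment$participant_id)
  sess_split <- split_of[sessions$participant_id]

  pipelines <- stage("train_task", {
    pp <- config$preprocess
    res <- list()
    trial_logs <- list()
    for (m in MODALITIES) {
      train_s <- sessions[sess_split == "train", , drop = FALSE]
      dev_s <- sessions[sess_split == "dev", , drop = FALSE]
      x_tr_raw <- get_modality_matrix(train_s, m)
      pres_tr <- !is.na(x_tr_raw[, 1])
      x_tr_raw <- x_tr_raw[pres_tr, , drop = FALSE]
      y_tr <- train_s$label_at_session[pres_tr]
      x_dv_raw <- get_modality_matrix(dev_s, m)
      pres_dv <- !is.na(x_dv_raw[, 1])
      x_dv_raw <- x_dv_raw[pres_dv, , drop = FALSE]
      y_dv <- dev_s$label_at_session[pres_dv]
      scaler <- fit_scaler(x_tr_raw, pp$scaler)
      x_tr <- apply_scaler(scaler, x_tr_raw)
      keep <- if (is.null(pp$corr_threshold)) seq_len(ncol(x_tr)) else
        select_features_by_correlation(x_tr, pp$corr_threshold)
      x_tr <- x_tr[, keep, drop = FALSE]
      x_dv <- apply_scaler(scaler, x_dv_raw)[, keep, drop = FALSE]
      if (!is.null(pp$smote_ratio)) {
        aug <- smote_oversample(x_tr, y_tr, k = pp$smote_k,
                                target_ratio = pp$smote_ratio,
                                seed = child_seed(config$seed, paste0("smote-", m)))
        x_tr <- aug$x
        y_tr <- aug$y
      }
      space <- c(list(input_dim = list(values = length(keep))),
                 config$task$space)
      sr <- search_hyperparameters(space, config$task$budget, x_tr, y_tr,
                                   x_dv, y_dv,
                                   seed = child_seed(config$seed, paste0("search-", m)))
      res[[m]] <- structure(list(modality = m, scaler = scaler, keep = keep,
                                 model = sr$best_model, format_version = 1L),
                            class = "park_task_pipeline")
      trial_logs[[m]] <- cbind(modality = m, sr$trials)
    }
    tl_path <- file.path(out_dir, "task_trials.csv")
    data.table::fwrite(do.call(rbind, trial_logs), tl_path)
    emit(tl_path)
    for (m in MODALITIES) {
      mp <- file.path(out_dir, paste0("task_model_", m, ".rds"))
      saveRDS(res[[m]], mp)
      emit(mp)
    }
    res
  })

  ufnet <- stage("train_fusion", {
    complete <- is_complete_session(sessions)
    train_c <- sessions[sess_split == "train" & complete, , drop = FALSE]
    dev_c <- sessions[sess_split == "dev" & complete, , drop = FALSE]
    fr <- search_fusion_hyperparameters(
      config$fusion$space, config$fusion$budget, train_c, dev_c, pipelines,
      decision_threshold = config$fusion$decision_threshold,
      ci_level = config$fusion$ci_level,
      seed = child_seed(config$seed, "fusion-search"))
    ft_path <- file.path(out_dir, "fusion_trials.csv")
    data.table::fwrite(fr$trials, ft_path)
    emit(ft_path)
    fp <- file.path(out_dir, "fusion_model.rds")
    saveRDS(fr$best_model, fp)
    emit(fp)
    fr$best_model
  })

  predictions <- stage("predict", {
    complete <- is_complete_session(sessions)
    test_c <- sessions[sess_split == "test" & complete, , drop = FALSE]
    mc <- fuse_predict(ufnet, test_c, seed = child_seed(config$seed, "predict"))
    dec <- decide(mc, threshold = ufnet$spec$decision_threshold,
                  level = ufnet$spec$ci_level)
    out <- cbind(data.frame(session_id = session_ids(test_c),
                            truth = test_c$label_at_session), dec)
    pr_path <- file.path(out_dir, "predictions.csv")
    data.table::fwrite(out, pr_path)
    emit(pr_path)
    out
  })

  report <- stage("evaluate", {
    rep <- metric_report(predictions$truth, predictions$mean_p,
                         verdicts = predictions$verdict,
                         threshold = ufnet$spec$decision_threshold,
                         B = config$evaluation$bootstrap,
                         level = config$evaluation$level,
                         seed = child_seed(config$seed, "evaluate"),
                         ece_bins = config$evaluation$ece_bins)
    mr_path <- file.path(out_dir, "metrics.json")
    write_metric_report(rep, mr_path)
    emit(mr_path)
    retained <- predictions$verdict != "withheld"
    cal <- calibration_curve(predictions$mean_p[retained],
                             predictions$truth[retained],
                             bins = config$evaluation$ece_bins)
    cal_path <- file.path(out_dir, "calibration.csv")
    data.table::fwrite(cal, cal_path)
    emit(cal_path)
    rep
  })

  manifest <- stage("manifest", {
    files <- sort(unique(files))
    hashes <- tools::md5sum(files)
    man <- list(package_version = as.character(utils::packageVersion("parkscreen")),
                format_version = 1L, seed = config$seed,
                files = stats::setNames(as.list(unname(hashes)),
                                        basename(files)))
    man_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    man_path
  })

  invisible(list(manifest = manifest, report = report, ufnet = ufnet,
                 predictions = predictions, out_dir = out_dir))
}
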