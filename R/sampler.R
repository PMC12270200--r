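# Genetic-algorithm demographic balancer and leak-free split construction.
#
# A candidate selection is scored by the chi-square-style diversity loss
# sum_a sum_i (E_i - O_i)^2 / E_i over demographic attributes (sex,
# ethnicity, age bin); the GA proposes one same-class swap per iteration,
# accepts it iff the loss strictly decreases, stops a restart after a run of
# consecutive rejections, and keeps the best restart.

#' Expected demographic distribution for cohort balancing
#'
#' Defaults are the balanced targets used for cohort selection: sex 50/50,
#' ethnicity 45% white / 45% non-white / 10% unknown, age 45% below 50 /
#' 45% at-or-above 50 / 10% unknown. "unknown" is a scored subgroup like any
#' other.
#'
#' @param sex,ethnicity,age Named proportion vectors, each summing to 1.
#' @param age_cutoff Age (years) splitting the two known age bins.
#' @return A `diversity_targets` list.
#' @export
diversity_targets <- function(sex = c(male = 0.5, female = 0.5),
                              ethnicity = c(white = 0.45, non_white = 0.45,
                                            unknown = 0.10),
                              age = c(under50 = 0.45, over50 = 0.45,
                                      unknown = 0.10),
                              age_cutoff = 50) {
  targets <- list(sex = sex, ethnicity = ethnicity, age = age)
  for (a in names(targets)) {
    p <- targets[[a]]
    check_proportion(p, a)
    if (abs(sum(p) - 1) > 1e-9) stopf("proportions for '%s' must sum to 1", a)
  }
  structure(c(targets, list(age_cutoff = age_cutoff)),
            class = "diversity_targets")
}

# Map participants to subgroup labels per scored attribute.
participant_subgroups <- function(participants, targets) {
  age_bin <- ifelse(is.na(participants$age_years), "unknown",
                    ifelse(participants$age_years < targets$age_cutoff,
                           "under50", "over50"))
  sex <- ifelse(is.na(participants$sex), "unknown", participants$sex)
  eth <- ifelse(is.na(participants$ethnicity), "unknown", participants$ethnicity)
  data.frame(sex = sex, ethnicity = eth, age = age_bin,
             stringsAsFactors = FALSE)
}

# Flatten targets into one subgroup vector with attribute bookkeeping, and
# index each participant's subgroup memberships into it. Subgroup levels not
# named in the targets fall into an unscored sink bin per attribute
# (proportion NA): they contribute nothing to the loss. A level that IS
# listed with proportion 0 stays scored (and errors when populated).
subgroup_index <- function(participants, targets) {
  attrs <- c("sex", "ethnicity", "age")
  groups <- participant_subgroups(participants, targets)
  props <- unlist(lapply(attrs, function(a) {
    p <- c(targets[[a]], NA_real_)
    stats::setNames(p, paste(a, c(names(targets[[a]]), "(other)"), sep = "."))
  }))
  idx <- matrix(0L, nrow(participants), length(attrs))
  offset <- 0L
  for (k in seq_along(attrs)) {
    a <- attrs[k]
    levels_a <- names(targets[[a]])
    pos <- match(groups[[a]], levels_a)
    pos[is.na(pos)] <- length(levels_a) + 1L
    idx[, k] <- offset + pos
    offset <- offset + length(levels_a) + 1L
  }
  list(props = props, idx = idx)
}

#' Demographic diversity loss
#'
#' `sum_a sum_i (E_i - O_i)^2 / E_i` where, for each demographic attribute
#' `a` and subgroup `i`, `E_i` is the expected count (target proportion times
#' selection size) and `O_i` the observed count in the selection. Zero means
#' the selection matches the expected distribution exactly; larger deviations
#' are penalized quadratically.
#'
#' @param selection Data frame of selected participants with `sex`,
#'   `ethnicity`, `age_years` columns.
#' @param targets A [diversity_targets()].
#' @return Nonnegative loss value.
#' @export
diversity_loss <- function(selection, targets) {
  stopifnot(inherits(targets, "diversity_targets"))
  n <- nrow(selection)
  si <- subgroup_index(selection, targets)
  E <- si$props * n
  O <- tabulate(si$idx, nbins = length(E))
  bad <- O > 0 & !is.na(E) & E == 0
  if (any(bad)) {
    stopf("expected count is zero for populated subgroup(s): %s",
          paste(names(E)[bad], collapse = ", "))
  }
  loss_from_counts(E, O)
}

loss_from_counts <- function(E, O) {
  scored <- !is.na(E) & E > 0
  sum((E[scored] - O[scored])^2 / E[scored])
}

#' Genetic-algorithm cohort balancing
#'
#' Selects `n_select` participants from `pool` with an exact PD / non-PD
#' split (`round(n_select * pd_fraction)` PD). Each restart starts from a
#' random class-respecting selection and repeatedly proposes replacing a
#' random selected participant with a random unselected participant of the
#' same PD class; a proposal is accepted iff the diversity loss strictly
#' decreases. A restart stops after `max_stale` consecutive rejections, and
#' the best of `restarts` restarts is returned.
#'
#' @param pool Data frame with `participant_id`, `pd_status`, `sex`,
#'   `ethnicity`, `age_years`.
#' @param n_select Selection size.
#' @param pd_fraction PD proportion of the selection (default 0.5).
#' @param targets A [diversity_targets()].
#' @param restarts Number of independent GA restarts (default 500).
#' @param max_stale Consecutive rejections ending a restart (default 2000).
#' @param seed Integer seed.
#' @return List with `selected` (participant IDs), `loss`, `log` (one row per
#'   restart: iterations, accepted steps, initial and final loss), and
#'   `trace` (loss after each accepted step of the best restart, starting at
#'   the initial loss).
#' @export
genetic_balance <- function(pool, n_select, pd_fraction = 0.5,
                            targets = diversity_targets(), restarts = 500L,
                            max_stale = 2000L, seed = 1L) {
  restarts <- check_count(restarts, "restarts")
  max_stale <- check_count(max_stale, "max_stale")
  n_select <- check_count(n_select, "n_select")
  n_pd <- round(n_select * pd_fraction)
  n_non <- n_select - n_pd
  pd_pool <- which(pool$pd_status == 1)
  non_pool <- which(pool$pd_status == 0)
  if (length(pd_pool) < n_pd || length(non_pool) < n_non) {
    stopf("infeasible: need %d PD and %d non-PD but pool has %d and %d",
          n_pd, n_non, length(pd_pool), length(non_pool))
  }
  si <- subgroup_index(pool, targets)
  E <- si$props * n_select
  idx <- si$idx  # n_pool x 3 subgroup positions

  best <- list(loss = Inf, sel = NULL, trace = NULL)
  log <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    res <- with_seed(child_seed(seed, sprintf("restart%d", r)), {
      sel_pd <- sample(pd_pool, n_pd)
      sel_non <- sample(non_pool, n_non)
      out_pd <- setdiff(pd_pool, sel_pd)
      out_non <- setdiff(non_pool, sel_non)
      O <- tabulate(idx[c(sel_pd, sel_non), , drop = FALSE], nbins = length(E))
      loss <- loss_from_counts(E, O)
      trace <- loss
      stale <- 0L
      iters <- 0L
      accepted <- 0L
      while (stale < max_stale) {
        iters <- iters + 1L
        pd_class <- stats::runif(1) < 0.5
        n_in <- if (pd_class) length(sel_pd) else length(sel_non)
        n_out <- if (pd_class) length(out_pd) else length(out_non)
        if (n_out == 0L || n_in == 0L) { stale <- stale + 1L; next }
        a <- sample.int(n_in, 1)
        b <- sample.int(n_out, 1)
        out_i <- if (pd_class) sel_pd[a] else sel_non[a]
        in_i <- if (pd_class) out_pd[b] else out_non[b]
        O2 <- O
        O2[idx[out_i, ]] <- O2[idx[out_i, ]] - 1L
        O2[idx[in_i, ]] <- O2[idx[in_i, ]] + 1L
        loss2 <- loss_from_counts(E, O2)
        if (loss2 < loss - 1e-12) {
          O <- O2
          loss <- loss2
          accepted <- accepted + 1L
          trace <- c(trace, loss)
          stale <- 0L
          if (pd_class) {
            sel_pd[a] <- in_i
            out_pd[b] <- out_i
          } else {
            sel_non[a] <- in_i
            out_non[b] <- out_i
          }
        } else {
          stale <- stale + 1L
        }
      }
      list(sel = c(sel_pd, sel_non), loss = loss, trace = trace,
           iters = iters, accepted = accepted)
    })
    log[[r]] <- data.frame(restart = r, iterations = res$iters,
                           accepted = res$accepted,
                           initial_loss = res$trace[1], final_loss = res$loss)
    if (res$loss < best$loss) {
      best <- list(loss = res$loss, sel = res$sel, trace = res$trace)
    }
  }
  list(selected = pool$participant_id[best$sel], loss = best$loss,
       trace = best$trace, log = do.call(rbind, log))
}

#' Sequential leak-free train/dev/test splits
#'
#' The test cohort is selected first by [genetic_balance()]; its participants
#' are removed and the development cohort is selected from the remainder by a
#' second GA run; everyone else is assigned to training. No participant
#' appears in two splits.
#'
#' @param pool Participant data frame (as in [genetic_balance()]).
#' @param test_size,dev_size Selection sizes.
#' @param pd_fraction PD proportion of each balanced cohort.
#' @param targets A [diversity_targets()].
#' @param restarts,max_stale GA settings per stage.
#' @param seed Integer seed.
#' @return List with `assignment` (data frame participant_id, split), and the
#'   two GA results `test_run`, `dev_run`.
#' @export
make_splits <- function(pool, test_size, dev_size, pd_fraction = 0.5,
                        targets = diversity_targets(), restarts = 500L,
                        max_stale = 2000L, seed = 1L) {
  if (nrow(pool) < test_size + dev_size) {
    stopf("pool of %d cannot supply test %d + dev %d", nrow(pool),
          test_size, dev_size)
  }
  test_run <- tryCatch(
    genetic_balance(pool, test_size, pd_fraction, targets, restarts,
                    max_stale, seed = child_seed(seed, "test")),
    error = function(e) stopf("test-stage selection failed: %s", conditionMessage(e)))
  remainder <- pool[!(pool$participant_id %in% test_run$selected), , drop = FALSE]
  dev_run <- tryCatch(
    genetic_balance(remainder, dev_size, pd_fraction, targets, restarts,
                    max_stale, seed = child_seed(seed, "dev")),
    error = function(e) stopf("dev-stage selection failed: %s", conditionMessage(e)))
  split <- ifelse(pool$participant_id %in% test_run$selected, "test",
                  ifelse(pool$participant_id %in% dev_run$selected, "dev",
                         "train"))
  list(assignment = data.frame(participant_id = pool$participant_id,
                               split = split, stringsAsFactors = FALSE),
       test_run = test_run, dev_run = dev_run)
}
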