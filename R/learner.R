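## Learning-trajectory analysis: per-phase d' trajectories, the
## learner/non-learner split by the sign of the Pearson correlation with
## training phase, the random-rater simulation null for that split,
## pre/post/retention deltas, and human-vs-model rank agreement.

#' Training-phase d' trajectory of one participant
#'
#' Extracts the nine training-phase d' values (abnormal categories pooled,
#' i.e. the `all_abnormal` group against each phase's normal trials) in
#' phase order from a [phase_summaries()] table.
#'
#' @param summaries [phase_summaries()] rows for a single participant.
#' @return numeric vector of 9 d' values, ordered by training phase.
#' @export
training_trajectory <- function(summaries) {
  if (length(unique(summaries$participant_id)) != 1)
    stop_gist("summaries must belong to a single participant")
  tr <- summaries[summaries$phase_type == "training" &
                    summaries$category_group == "all_abnormal", , drop = FALSE]
  missing <- setdiff(1:9, tr$phase_index)
  if (length(missing))
    stop_gist("missing training phase(s): ", paste(missing, collapse = ", "))
  tr$dprime[order(tr$phase_index)]
}

#' Classify a training trajectory as learner or non-learner
#'
#' Computes the Pearson correlation between the nine training-phase d'
#' values and the phase index 1..9. A strictly positive coefficient labels
#' the participant a learner; zero or negative (including the degenerate
#' zero-variance trajectory, whose correlation is recorded as 0) labels a
#' non-learner.
#'
#' @param trajectory numeric vector of 9 finite d' values.
#' @param participant_id optional identifier carried into the result.
#' @return list with `participant_id`, `dprime_by_phase`, `pearson_r`,
#'   `label`.
#' @export
classify_learner <- function(trajectory, participant_id = NA_character_) {
  if (length(trajectory) != 9 || !all(is.finite(trajectory)))
    stop_gist("trajectory must hold 9 finite d' values")
  r <- if (stats::sd(trajectory) == 0) 0 else stats::cor(trajectory, 1:9)
  list(participant_id = participant_id,
       dprime_by_phase = trajectory,
       pearson_r = r,
       label = if (r > 0) "learner" else "non_learner")
}

#' Classify every participant in a summary table
#'
#' @param summaries [phase_summaries()] table covering the nine training
#'   phases for each participant.
#' @return data frame with columns `participant_id`, `pearson_r`, `label`.
#' @export
classify_learners <- function(summaries) {
  out <- lapply(split(summaries, summaries$participant_id), function(ss) {
    cl <- classify_learner(training_trajectory(ss), ss$participant_id[1])
    data.frame(participant_id = cl$participant_id, pearson_r = cl$pearson_r,
               label = cl$label, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default phase schedule for the random-rater null
#'
#' A 200-trial pre-test and post-test (80 normal / 120 abnormal) around nine
#' training phases of 720 scored mammogram trials each (288 normal / 432
#' abnormal, the 4 x (72 normal + 108 abnormal) block mix). Attention trials
#' and the viewing-time staircase are omitted: neither affects uniform
#' random ratings.
#'
#' @return named list of per-phase class counts.
#' @export
null_schedule <- function() {
  list(pretest = c(normal = 80L, abnormal = 120L),
       training = c(normal = 288L, abnormal = 432L),
       n_training = 9L,
       posttest = c(normal = 80L, abnormal = 120L))
}

#' Random-rater simulation null for the learner/non-learner split
#'
#' Simulates runs of participants whose every rating is an independent
#' uniform draw on the integers 0--100, pushes each participant through a
#' pre-test, nine training phases, and a post-test, computes the per-phase
#' d' at threshold 50 with the log-linear correction, splits each run's
#' participants by the sign of the Pearson correlation between training d'
#' and phase index, and averages the post-minus-pre d' change within each
#' subgroup. Because the split is made on training-phase noise that is
#' independent of the test phases, neither subgroup gains any performance:
#' both means converge to 0.
#'
#' @param n_runs number of simulated runs (default 1000).
#' @param n_participants participants per run (default 15).
#' @param seed integer seed; results are bit-reproducible from it.
#' @param schedule per-phase class counts, see [null_schedule()].
#' @param continuous draw ratings from a continuous uniform on \[0, 100\]
#'   instead of the integer lattice (default `FALSE`, matching the response
#'   device).
#' @return object of class `gist_null_sim`: run counts, subgroup means of
#'   the post-minus-pre d' (`learner_mean_delta`, `nonlearner_mean_delta`),
#'   95\% CI half-widths over runs (mean +/- 1.96 SD / sqrt(runs)), the
#'   seed, and a `runs` data frame of run-level subgroup deltas.
#' @export
null_simulation <- function(n_runs = 1000, n_participants = 15, seed = NULL,
                            schedule = null_schedule(), continuous = FALSE) {
  if (!is.numeric(n_runs) || n_runs < 1) stop_gist("n_runs must be >= 1")
  if (!is.numeric(n_participants) || n_participants < 1)
    stop_gist("n_participants must be >= 1")

  n_norm <- c(schedule$pretest["normal"],
              rep(schedule$training["normal"], schedule$n_training),
              schedule$posttest["normal"])
  n_abn <- c(schedule$pretest["abnormal"],
             rep(schedule$training["abnormal"], schedule$n_training),
             schedule$posttest["abnormal"])
  n_phases <- length(n_norm)
  ## per-participant grouping: 2 cells (normal, abnormal) per phase
  grp <- rep(seq_len(2L * n_phases), times = rbind(n_norm, n_abn))
  n_per_participant <- sum(n_norm) + sum(n_abn)
  tc <- (1:schedule$n_training) - mean(1:schedule$n_training)

  run_learner <- run_nonlearner <- rep(NA_real_, n_runs)
  run_n_learners <- integer(n_runs)

  with_seed(seed, for (run in seq_len(n_runs)) {
    draws <- if (continuous)
      stats::runif(n_per_participant * n_participants, 0, 100)
    else
      sample.int(101L, n_per_participant * n_participants, replace = TRUE) - 1L
    above <- matrix(as.numeric(draws > 50), nrow = n_per_participant)
    counts <- rowsum(above, grp)                       # 2*n_phases x np
    odd <- seq(1L, 2L * n_phases, by = 2L)
    d <- dprime_from_counts(counts[odd + 1L, , drop = FALSE], n_abn,
                            counts[odd, , drop = FALSE], n_norm)

    traj <- d[1L + seq_len(schedule$n_training), , drop = FALSE]
    cc <- sweep(traj, 2, colMeans(traj))
    denom <- sqrt(colSums(cc^2) * sum(tc^2))
    r <- ifelse(denom == 0, 0, colSums(cc * tc) / denom)

    delta <- d[n_phases, ] - d[1, ]
    learners <- r > 0
    run_n_learners[run] <- sum(learners)
    if (any(learners)) run_learner[run] <- mean(delta[learners])
    if (any(!learners)) run_nonlearner[run] <- mean(delta[!learners])
  })

  structure(list(
    n_runs = as.integer(n_runs),
    n_participants_per_run = as.integer(n_participants),
    learner_mean_delta = mean(run_learner, na.rm = TRUE),
    nonlearner_mean_delta = mean(run_nonlearner, na.rm = TRUE),
    learner_ci95_halfwidth = ci95_halfwidth(run_learner),
    nonlearner_ci95_halfwidth = ci95_halfwidth(run_nonlearner),
    seed = seed,
    runs = data.frame(run = seq_len(n_runs), n_learners = run_n_learners,
                      learner_delta = run_learner,
                      nonlearner_delta = run_nonlearner)
  ), class = "gist_null_sim")
}

#' @export
print.gist_null_sim <- function(x, ...) {
  cat(sprintf("Random-rater null: %d runs x %d participants\n",
              x$n_runs, x$n_participants_per_run))
  cat(sprintf("  learner subgroup mean post-pre d': %+.4f +/- %.4f (95%% CI)\n",
              x$learner_mean_delta, x$learner_ci95_halfwidth))
  cat(sprintf("  non-learner subgroup mean post-pre d': %+.4f +/- %.4f (95%% CI)\n",
              x$nonlearner_mean_delta, x$nonlearner_ci95_halfwidth))
  invisible(x)
}

#' Pre/post/retention changes in d' and criterion
#'
#' Simple per-participant differences (posttest minus pretest, retention
#' minus pretest) in d' and criterion for each category group, plus group
#' means with 95\% confidence intervals (mean +/- 1.96 SD / sqrt(n)).
#' Participants missing a phase get `NA` differences and a flag rather than
#' an error.
#'
#' @param summaries [phase_summaries()] table covering the test phases.
#' @return list of class `gist_deltas` with `participants` (one row per
#'   participant x category group) and `group_means` (per category group and
#'   measure).
#' @export
phase_deltas <- function(summaries) {
  rows <- list()
  for (ss in split(summaries, summaries$participant_id)) {
    for (gg in split(ss, ss$category_group)) {
      pick <- function(type) {
        i <- which(gg$phase_type == type)
        if (length(i) == 1) c(gg$dprime[i], gg$criterion[i]) else c(NA_real_, NA_real_)
      }
      pre <- pick("pretest"); post <- pick("posttest"); ret <- pick("retention")
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = gg$participant_id[1],
        category_group = gg$category_group[1],
        dprime_post_pre = post[1] - pre[1],
        dprime_retention_pre = ret[1] - pre[1],
        criterion_post_pre = post[2] - pre[2],
        criterion_retention_pre = ret[2] - pre[2],
        complete = all(is.finite(c(pre, post, ret))),
        stringsAsFactors = FALSE)
    }
  }
  participants <- do.call(rbind, rows)
  rownames(participants) <- NULL

  measures <- c("dprime_post_pre", "dprime_retention_pre",
                "criterion_post_pre", "criterion_retention_pre")
  gm <- list()
  for (g in unique(participants$category_group)) {
    sub <- participants[participants$category_group == g, , drop = FALSE]
    for (m in measures) {
      x <- sub[[m]][is.finite(sub[[m]])]
      gm[[length(gm) + 1L]] <- data.frame(
        category_group = g, measure = m, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        ci95_halfwidth = ci95_halfwidth(x),
        stringsAsFactors = FALSE)
    }
  }
  group_means <- do.call(rbind, gm)
  rownames(group_means) <- NULL
  structure(list(participants = participants, group_means = group_means),
            class = "gist_deltas")
}

#' @export
print.gist_deltas <- function(x, ...) {
  cat("Test-phase deltas (", length(unique(x$participants$participant_id)),
      " participants)\n", sep = "")
  print(x$group_means)
  invisible(x)
}

#' Rank agreement between human and model abnormality scores
#'
#' Spearman's rank correlation (tie-aware, two-sided p value) between
#' per-stimulus mean human ratings and model-produced abnormality scores,
#' aligned by stimulus identifier.
#'
#' @param human_scores named numeric vector (names are stimulus identifiers)
#'   or data frame with columns `stimulus_id` and `score`.
#' @param model_scores same format as `human_scores`.
#' @return list with `spearman_rho`, `p_value`, `n`.
#' @export
score_agreement <- function(human_scores, model_scores) {
  as_named <- function(x, what) {
    if (is.data.frame(x)) {
      if (!all(c("stimulus_id", "score") %in% names(x)))
        stop_gist(what, " data frame needs columns stimulus_id, score")
      stats::setNames(x$score, x$stimulus_id)
    } else {
      if (is.null(names(x))) stop_gist(what, " must carry stimulus identifiers")
      x
    }
  }
  h <- as_named(human_scores, "human_scores")
  m <- as_named(model_scores, "model_scores")
  orphans <- c(setdiff(names(h), names(m)), setdiff(names(m), names(h)))
  if (length(orphans))
    stop_gist("misaligned stimulus identifiers: ",
              paste(utils::head(orphans, 10), collapse = ", "))
  if (length(h) < 3) stop_gist("need at least 3 aligned stimuli")
  ct <- suppressWarnings(
    stats::cor.test(h, m[names(h)], method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  list(spearman_rho = unname(ct$estimate), p_value = ct$p.value, n = length(h))
}
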