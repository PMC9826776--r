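# In-code fixtures: small valid trial tables built without the full generator.

# n rows with sensible defaults; scalar arguments recycle.
make_trials <- function(n, participant_id = "p1", session_index = 1L,
                        phase_type = "pretest", phase_index = 0L,
                        block_index = 0L, trial_kind = "mammogram",
                        category = "normal", ground_truth = NULL,
                        rating = 0L, viewing_time_ms = 500,
                        rating_time_ms = 1000, max_viewing_time_ms = 500,
                        feedback_given = NULL) {
  if (is.null(ground_truth))
    ground_truth <- ifelse(category %in% c("normal", "scene_beach"),
                           "normal", "abnormal")
  if (is.null(feedback_given))
    feedback_given <- phase_type == "training" | trial_kind == "practice"
  data.frame(participant_id = participant_id, session_index = session_index,
             phase_type = phase_type, phase_index = phase_index,
             block_index = block_index, trial_index = seq_len(n),
             trial_kind = trial_kind, category = category,
             ground_truth = ground_truth, rating = rating,
             viewing_time_ms = viewing_time_ms,
             rating_time_ms = rating_time_ms,
             max_viewing_time_ms = max_viewing_time_ms,
             feedback_given = feedback_given, stringsAsFactors = FALSE)
}

# One training phase holding its 16 attention trials (4 per block), with
# `n_missed` of them failed (beach rated 100), plus a handful of mammograms
# so the phase is non-degenerate.
make_training_phase <- function(pid, phase, n_missed = 0, mam_ratings = NULL) {
  att <- make_trials(16, participant_id = pid, session_index = phase,
                     phase_type = "training", phase_index = phase,
                     block_index = rep(1:4, each = 4), trial_kind = "attention",
                     category = "scene_beach",
                     rating = c(rep(100L, n_missed), rep(0L, 16 - n_missed)))
  cats <- c(rep("normal", 4), "obvious", "obvious", "subtle",
            "contralateral", "prior", "prior")
  if (is.null(mam_ratings)) mam_ratings <- c(rep(20L, 4), rep(80L, 6))
  stopifnot(length(mam_ratings) == 10)
  mam <- make_trials(10, participant_id = pid,
                     session_index = phase, phase_type = "training",
                     phase_index = phase, block_index = 1L,
                     category = cats, rating = mam_ratings)
  mam$trial_index <- mam$trial_index + 16L
  rbind(att, mam)
}

# Nine training phases for one participant with a per-phase miss vector.
make_training_sessions <- function(pid, missed_by_phase = rep(0, 9)) {
  do.call(rbind, lapply(1:9, function(p)
    make_training_phase(pid, p, n_missed = missed_by_phase[p])))
}

# A 200-trial test phase (80 normal / 120 abnormal) from given rating draws.
make_test_phase <- function(pid, phase_type = "pretest",
                            normal_ratings, abnormal_ratings,
                            session_index = 1L) {
  stopifnot(length(normal_ratings) == 80, length(abnormal_ratings) == 120)
  cats <- c(rep("normal", 80), rep(c("obvious", "subtle", "contralateral",
                                     "prior"), each = 30))
  make_trials(200, participant_id = pid, session_index = session_index,
              phase_type = phase_type, category = cats,
              rating = c(normal_ratings, abnormal_ratings))
}

# exhaustive pair-count rank statistic: P(A > N) + P(A = N)/2
rank_statistic <- function(normal, abnormal) {
  mean(outer(abnormal, normal, function(a, n) (a > n) + 0.5 * (a == n)))
}
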