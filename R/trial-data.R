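## Trial-level data model: schema, validation, delimited I/O, participant
## exclusion rules, and screen-timing summaries.

#' Validate a table of trial records
#'
#' Checks the schema and the row-level invariants: ratings in \[0, 100\],
#' viewing time never above the maximum viewing time, attention trials and
#' scene categories implying one another, feedback given on every training
#' trial and on no test-phase trial except practice trials, and phase/block
#' indices consistent with the phase type.
#'
#' @param trials data frame of trial records.
#' @return `trials`, invisibly, if valid; otherwise an error naming the first
#'   offending column or rows.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing))
    stop_gist("trial table schema error: missing column(s) ",
              paste(missing, collapse = ", "))

  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond))
      stop_gist("trial validation error: ", what, " at row(s) ",
                paste(utils::head(rows, 5), collapse = ", "),
                if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5))
    }
  }

  bad_row(!(trials$phase_type %in% phase_types), "unknown phase_type")
  bad_row(!(trials$trial_kind %in% trial_kinds), "unknown trial_kind")
  bad_row(!(trials$category %in% categories_all), "unknown category")
  bad_row(!(trials$ground_truth %in% c("normal", "abnormal")), "unknown ground_truth")
  bad_row(trials$rating < 0 | trials$rating > 100, "rating outside [0, 100]")
  bad_row(trials$viewing_time_ms < 0 | trials$rating_time_ms < 0,
          "negative duration")
  bad_row(trials$viewing_time_ms > trials$max_viewing_time_ms,
          "viewing_time_ms exceeds max_viewing_time_ms")

  scene <- trials$category %in% c("scene_beach", "scene_forest")
  bad_row(xor(scene, trials$trial_kind == "attention"),
          "attention trials and scene categories must coincide")

  train <- trials$phase_type == "training"
  bad_row(train & !trials$feedback_given, "training trial without feedback")
  bad_row(!train & trials$feedback_given & trials$trial_kind != "practice",
          "feedback on a non-practice test-phase trial")

  bad_row(train & !(trials$phase_index %in% 1:9),
          "training phase_index outside 1..9")
  bad_row(!train & trials$phase_index != 0, "nonzero phase_index in test phase")
  bad_row(train & !(trials$block_index %in% 1:4),
          "training block_index outside 1..4")
  bad_row(trials$trial_index < 1, "trial_index below 1")

  invisible(trials)
}

#' Read a delimited trial table
#'
#' Reads a comma-separated (default) or tab-separated trial table with a
#' header row, coerces column types, and validates every row. Row order is
#' preserved.
#'
#' @param path path to the delimited file.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return validated data frame of trial records.
#' @export
read_trials <- function(path, sep = ",") {
  if (!file.exists(path)) stop_gist("trial file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(trial_columns, names(raw))
  if (length(missing))
    stop_gist("trial table schema error: missing column(s) ",
              paste(missing, collapse = ", "))
  int_cols <- c("session_index", "phase_index", "block_index", "trial_index", "rating")
  num_cols <- c("viewing_time_ms", "rating_time_ms", "max_viewing_time_ms")
  for (cc in int_cols) raw[[cc]] <- as.integer(raw[[cc]])
  for (cc in num_cols) raw[[cc]] <- as.numeric(raw[[cc]])
  raw$feedback_given <- as.logical(raw$feedback_given)
  validate_trials(raw)
  raw
}

#' Write a trial table to a delimited file
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(x, f))` reproduces
#' `x` field for field.
#'
#' @param trials validated trial data frame.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, sep = ",") {
  validate_trials(trials)
  utils::write.table(trials, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## A missed attention trial: first-response decision on the wrong side of 50
## under the instruction "rate beaches as 0 and forests as 100".
attention_missed <- function(category, rating) {
  (category == "scene_beach" & rating > 50) |
    (category == "scene_forest" & rating <= 50)
}

#' Apply the pre-registered participant exclusion criteria
#'
#' A participant is excluded for inattention if they (1) missed more than 30
#' of the 144 attention trials across the nine training phases, (2) failed
#' more than 6 of the 16 attention trials within a single training phase, or
#' (3) rated 85\% or more of the trials as exactly 50 in any testing session
#' or in more than one training session. Rule 3 uses mammogram trials only
#' (attention and practice trials are not part of the denominator) and the
#' 85\% boundary is inclusive.
#'
#' @param trials validated trial data frame (one or more participants).
#' @return data frame with one `ExclusionReport` row per participant:
#'   `participant_id`, `total_attention_missed`,
#'   `max_attention_missed_one_session`, `sessions_with_ge85pct_50_ratings`,
#'   `excluded`, `reasons` (semicolon-joined rule identifiers
#'   `attention_total`, `attention_session`, `fifty_ratings`).
#' @export
apply_exclusion_criteria <- function(trials) {
  validate_trials(trials)
  out <- lapply(split(trials, trials$participant_id), function(tt) {
    pid <- tt$participant_id[1]
    train <- tt[tt$phase_type == "training", , drop = FALSE]

    miss_by_phase <- integer(0)
    if (nrow(train)) {
      att <- train[train$trial_kind == "attention", , drop = FALSE]
      phases <- sort(unique(train$phase_index))
      n_att <- vapply(phases, function(p) sum(att$phase_index == p), 0L)
      if (any(n_att == 0))
        stop_gist("malformed schedule: participant ", pid,
                  " has a training phase with zero attention trials (phase ",
                  paste(phases[n_att == 0], collapse = ", "), ")")
      missed <- attention_missed(att$category, att$rating)
      miss_by_phase <- vapply(phases, function(p) sum(missed[att$phase_index == p]), 0L)
    }
    total_missed <- sum(miss_by_phase)
    max_missed <- if (length(miss_by_phase)) max(miss_by_phase) else 0L

    ## rule 3: proportion of mammogram trials rated exactly 50, per phase
    mam <- tt[tt$trial_kind == "mammogram", , drop = FALSE]
    key <- interaction(mam$phase_type, mam$phase_index, drop = TRUE)
    p50 <- vapply(split(mam$rating, key), function(r) mean(r == 50), 0)
    is_test <- !startsWith(names(p50), "training")
    flagged <- p50 >= 0.85
    n_test_flag <- sum(flagged & is_test)
    n_train_flag <- sum(flagged & !is_test)

    reasons <- c(
      if (total_missed > 30) "attention_total",
      if (max_missed > 6) "attention_session",
      if (n_test_flag >= 1 || n_train_flag > 1) "fifty_ratings"
    )
    data.frame(
      participant_id = pid,
      total_attention_missed = total_missed,
      max_attention_missed_one_session = max_missed,
      sessions_with_ge85pct_50_ratings = n_test_flag + n_train_flag,
      excluded = length(reasons) > 0,
      reasons = paste(reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-session screen timing summaries with outlier exclusion
#'
#' Computes the mean and median duration of a screen per participant and
#' session after a single-pass exclusion of outliers lying outside the mean
#' plus/minus 3 standard deviations of that participant-session. The
#' `mammogram` screen summarises `viewing_time_ms` and the `rating` screen
#' `rating_time_ms`, both over mammogram-kind trials; the `feedback` screen
#' summarises the optional `feedback_time_ms` column over training trials and
#' is empty-flagged (zero counts, `NA` means) when that column is absent or
#' the session has no feedback screen.
#'
#' @param trials validated trial data frame.
#' @param screens subset of `c("mammogram", "rating", "feedback")`.
#' @return data frame with columns `participant_id`, `session_index`,
#'   `screen`, `n_trials`, `n_excluded_outliers`, `mean_ms`, `median_ms`.
#' @export
timing_summaries <- function(trials,
                             screens = c("mammogram", "rating", "feedback")) {
  validate_trials(trials)
  screens <- match.arg(screens, several.ok = TRUE)

  screen_values <- function(tt, screen) {
    switch(screen,
      mammogram = tt$viewing_time_ms[tt$trial_kind == "mammogram"],
      rating    = tt$rating_time_ms[tt$trial_kind == "mammogram"],
      feedback  = {
        if (!"feedback_time_ms" %in% names(tt)) numeric(0)
        else tt$feedback_time_ms[tt$feedback_given &
                                   tt$phase_type == "training" &
                                   tt$trial_kind == "mammogram"]
      })
  }

  rows <- list()
  for (pt in split(trials, trials$participant_id)) {
    for (ss in split(pt, pt$session_index)) {
      for (screen in screens) {
        x <- screen_values(ss, screen)
        x <- x[is.finite(x)]
        if (!length(x)) {
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = ss$participant_id[1],
            session_index = ss$session_index[1], screen = screen,
            n_trials = 0L, n_excluded_outliers = 0L,
            mean_ms = NA_real_, median_ms = NA_real_,
            stringsAsFactors = FALSE)
          next
        }
        m <- mean(x)
        s <- stats::sd(x)
        keep <- if (!is.finite(s) || s == 0) rep(TRUE, length(x))
                else abs(x - m) <= 3 * s
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ss$participant_id[1],
          session_index = ss$session_index[1], screen = screen,
          n_trials = length(x), n_excluded_outliers = sum(!keep),
          mean_ms = mean(x[keep]), median_ms = stats::median(x[keep]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
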