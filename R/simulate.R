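## Synthetic experiment generator: stimulus pools, training-block sampling
## with attention trials, the adaptive maximum-viewing-time staircase, and
## parametric observers emitting valid trial tables.

#' Default stimulus pool configuration
#'
#' Training pool of 5668 unilateral mammograms (1558 normal, 1019 obvious,
#' 899 subtle, 1868 contralateral, 324 prior) and a fixed 200-stimulus test
#' set (80 normal, 30 of each abnormal category; 60\% abnormal), disjoint
#' from the training pool.
#'
#' @param training named integer vector of per-category training pool sizes.
#' @param test named integer vector of per-category test set sizes.
#' @return list of class `gist_pool_config`.
#' @export
pool_config <- function(training = c(normal = 1558, obvious = 1019, subtle = 899,
                                     contralateral = 1868, prior = 324),
                        test = c(normal = 80, obvious = 30, subtle = 30,
                                 contralateral = 30, prior = 30)) {
  cats <- c("normal", abnormal_categories)
  if (!all(cats %in% names(training)) || !all(cats %in% names(test)))
    stop_gist("pool config must name all five mammogram categories")
  if (any(training < 0) || any(test < 0)) stop_gist("pool counts must be >= 0")
  structure(list(training = training[cats], test = test[cats]),
            class = "gist_pool_config")
}

#' Build synthetic stimulus pools
#'
#' Creates unique stimulus identifiers per category for the training pool
#' and the test set. Test-set identifiers are disjoint from the training
#' pool: the same 200 test stimuli are reused across the three test phases
#' and never appear in training.
#'
#' @param config a [pool_config()].
#' @param seed unused for the deterministic identifier scheme; accepted for
#'   interface symmetry with the samplers.
#' @return list of class `gist_pools` with `training` (named list of
#'   identifier vectors per category) and `test` (data frame of
#'   `stimulus_id`, `category`, `ground_truth`).
#' @export
stimulus_pools <- function(config = pool_config(), seed = NULL) {
  ids <- function(prefix, cat, n)
    if (n > 0) sprintf("%s_%s_%05d", prefix, cat, seq_len(n)) else character(0)
  training <- lapply(stats::setNames(nm = names(config$training)), function(cat)
    ids("train", cat, config$training[[cat]]))
  test_cat <- rep(names(config$test), config$test)
  test <- data.frame(
    stimulus_id = unlist(lapply(names(config$test), function(cat)
      ids("test", cat, config$test[[cat]])), use.names = FALSE),
    category = test_cat,
    ground_truth = ifelse(test_cat == "normal", "normal", "abnormal"),
    stringsAsFactors = FALSE)
  structure(list(training = training, test = test), class = "gist_pools")
}

#' Sample one 184-trial training block
#'
#' Draws 72 normal, 27 obvious, 27 subtle, and 54 global abnormal mammograms
#' without replacement within the block (repeats can occur across blocks but
#' never within one), shuffles them, and disperses 4 attention trials, one
#' placed uniformly at random within each quarter of the block. The 54
#' global draws come from the combined contralateral + prior pool, so the
#' contralateral:prior split follows the pool sizes.
#'
#' @param pools a [stimulus_pools()] object.
#' @param seed optional integer seed.
#' @return data frame of 184 rows: `slot`, `trial_kind`, `category`,
#'   `ground_truth`, `stimulus_id`.
#' @export
sample_training_block <- function(pools, seed = NULL) {
  with_seed(seed, {
    draw <- function(pool, k, what) {
      if (length(pool) < k)
        stop_gist("pool exhaustion: need ", k, " ", what, " stimuli, have ",
                  length(pool))
      sample(pool, k)
    }
    global_pool <- c(pools$training$contralateral, pools$training$prior)
    stim <- c(draw(pools$training$normal, 72, "normal"),
              draw(pools$training$obvious, 27, "obvious"),
              draw(pools$training$subtle, 27, "subtle"),
              draw(global_pool, 54, "global"))
    stim <- sample(stim)                               # shuffle the 180
    cat <- sub("^train_([a-z]+)_\\d+$", "\\1", stim)
    mam <- data.frame(trial_kind = "mammogram", category = cat,
                      ground_truth = ifelse(cat == "normal", "normal", "abnormal"),
                      stimulus_id = stim, stringsAsFactors = FALSE)
    att_pos <- (0:3) * 46 + vapply(1:4, function(q) sample.int(46, 1), 0L)
    scene <- sample(c("scene_beach", "scene_forest"), 4, replace = TRUE)
    att <- data.frame(trial_kind = "attention", category = scene,
                      ground_truth = ifelse(scene == "scene_beach",
                                            "normal", "abnormal"),
                      stimulus_id = paste0("attention_", scene, "_", 1:4),
                      stringsAsFactors = FALSE)
    block <- vector("list", 184)
    block[att_pos] <- split(att, 1:4)
    block[setdiff(1:184, att_pos)] <- split(mam, 1:180)
    out <- do.call(rbind, block)
    out <- cbind(slot = 1:184, out)
    rownames(out) <- NULL
    out
  })
}

#' Adaptive maximum-viewing-time staircase state
#'
#' @param max_viewing_ms current maximum viewing time (default 2500, the
#'   starting value of the first training block).
#' @param floor_ms lower bound (default 500, the minimum viewing time).
#' @param ceiling_ms upper bound (default 2500).
#' @return list of class `gist_staircase`.
#' @export
staircase_state <- function(max_viewing_ms = 2500, floor_ms = 500,
                            ceiling_ms = 2500) {
  if (max_viewing_ms < floor_ms || max_viewing_ms > ceiling_ms)
    stop_gist("max_viewing_ms must lie in [floor_ms, ceiling_ms]")
  structure(list(max_viewing_ms = max_viewing_ms, floor_ms = floor_ms,
                 ceiling_ms = ceiling_ms), class = "gist_staircase")
}

#' One staircase update after a training block
#'
#' If the block's total d' exceeded 0.2, the maximum viewing time drops to
#' 90\% of the block's average actual viewing time; if it fell below 0.05,
#' it rises to 105\% of the current maximum; in between it is unchanged.
#' The result is clamped to the staircase bounds (500--2500 ms by default),
#' so the viewing window never rises above the 2500 ms start value nor drops
#' below the minimum exposure.
#'
#' @param state a [staircase_state()].
#' @param block_dprime total d' of the completed block.
#' @param mean_actual_viewing_ms average actual viewing time of the block.
#' @return updated `gist_staircase`.
#' @export
staircase_update <- function(state, block_dprime, mean_actual_viewing_ms) {
  stopifnot(inherits(state, "gist_staircase"))
  if (mean_actual_viewing_ms > state$max_viewing_ms + 1e-9)
    stop_gist("mean actual viewing time exceeds the current maximum")
  new_max <- if (block_dprime > 0.2) 0.9 * mean_actual_viewing_ms
             else if (block_dprime < 0.05) 1.05 * state$max_viewing_ms
             else state$max_viewing_ms
  state$max_viewing_ms <- min(max(new_max, state$floor_ms), state$ceiling_ms)
  state
}

#' Parametric observers
#'
#' `random_observer()` rates every mammogram uniformly at random on the
#' integers 0--100. `sdt_observer()` is an equal-variance signal-detection
#' observer: on each trial it draws latent evidence x ~ Normal(mu, 1) with
#' mu = 0 for normal mammograms and mu equal to the effective per-category
#' sensitivity for abnormal ones, then maps the evidence to a graded rating
#' `round(100 * pnorm((x - k) / spread))` through the latent decision cutoff
#' k, so the binary decision induced by the rating threshold 50 reproduces
#' the observer's generative hit/false-alarm structure.
#'
#' Effective sensitivity for category `cat` after `p` completed training
#' phases is `max(0, d0[cat] + learn[cat] * p)`; at the retention test the
#' learned gain is multiplied by `1 - retention_decay`. The cutoff is placed
#' at `k = c0 + c_drift * p + mean(effective d over abnormal categories)/2`,
#' so the `criterion` parameter is expressed in the usual SDT c units
#' (0 = unbiased, negative = liberal) and drifts by `c_drift` per phase.
#'
#' Both observers answer attention trials correctly (beach -> 0,
#' forest -> 100) except with probability `attention_miss_rate`, when the
#' response lands on the wrong side of 50.
#'
#' @param d0 baseline sensitivity: scalar or named vector over the abnormal
#'   categories (obvious, subtle, contralateral, prior).
#' @param learn per-phase sensitivity increment, scalar or named vector.
#' @param c0 baseline criterion (SDT c units).
#' @param c_drift per-phase criterion drift (negative = growing liberal).
#' @param spread positive spread of the evidence-to-rating map; larger values
#'   compress ratings toward 50.
#' @param retention_decay fraction of the learned gain lost at the retention
#'   test, in \[0, 1\].
#' @param attention_miss_rate probability of failing an attention trial.
#' @return object of class `gist_observer`.
#' @export
sdt_observer <- function(d0 = 0, learn = 0, c0 = 0, c_drift = 0, spread = 1,
                         retention_decay = 0, attention_miss_rate = 0) {
  expand <- function(x) {
    if (is.null(names(x))) x <- stats::setNames(rep(x[1], 4), abnormal_categories)
    if (!all(abnormal_categories %in% names(x)))
      stop_gist("named sensitivity vectors must cover all abnormal categories")
    x[abnormal_categories]
  }
  if (spread <= 0) stop_gist("spread must be positive")
  if (retention_decay < 0 || retention_decay > 1)
    stop_gist("retention_decay must lie in [0, 1]")
  structure(list(kind = "sdt", d0 = expand(d0), learn = expand(learn),
                 c0 = c0, c_drift = c_drift, spread = spread,
                 retention_decay = retention_decay,
                 attention_miss_rate = attention_miss_rate),
            class = "gist_observer")
}

#' @rdname sdt_observer
#' @export
random_observer <- function(attention_miss_rate = 0) {
  structure(list(kind = "random", attention_miss_rate = attention_miss_rate),
            class = "gist_observer")
}

#' @export
print.gist_observer <- function(x, ...) {
  if (x$kind == "random") {
    cat("random observer (uniform integer ratings 0-100)\n")
  } else {
    cat("equal-variance SDT observer\n")
    cat("  d0:    ", paste(sprintf("%s=%.2f", names(x$d0), x$d0), collapse = " "), "\n")
    cat("  learn: ", paste(sprintf("%s=%.3f", names(x$learn), x$learn), collapse = " "), "\n")
    cat(sprintf("  c0 = %.2f, drift = %.3f/phase, spread = %.2f, retention decay = %.2f\n",
                x$c0, x$c_drift, x$spread, x$retention_decay))
  }
  invisible(x)
}

## effective per-category sensitivity and latent cutoff at a phase context
observer_params <- function(observer, phases_completed, at_retention = FALSE) {
  gain <- observer$learn * phases_completed
  if (at_retention) gain <- gain * (1 - observer$retention_decay)
  d_eff <- observer$d0 + gain
  d_eff[d_eff < 0] <- 0
  c_eff <- observer$c0 + observer$c_drift * phases_completed
  list(d_eff = d_eff, cutoff = c_eff + mean(d_eff) / 2)
}

#' Simulate observer ratings for a batch of mammogram trials
#'
#' @param observer a [sdt_observer()] or [random_observer()].
#' @param category character vector of stimulus categories (mammogram
#'   categories only).
#' @param phases_completed number of completed training phases (controls
#'   learning and criterion drift).
#' @param at_retention apply the retention decay to the learned gain.
#' @param seed optional integer seed.
#' @return integer ratings in \[0, 100\], one per element of `category`.
#' @export
simulate_observer_rating <- function(observer, category, phases_completed = 0,
                                     at_retention = FALSE, seed = NULL) {
  stopifnot(inherits(observer, "gist_observer"))
  n <- length(category)
  with_seed(seed, {
    if (observer$kind == "random")
      return(sample.int(101L, n, replace = TRUE) - 1L)
    pp <- observer_params(observer, phases_completed, at_retention)
    mu <- rep(0, n)
    for (cat in abnormal_categories)
      mu[category == cat] <- pp$d_eff[[cat]]
    x <- stats::rnorm(n, mu, 1)
    as.integer(pmin(100, pmax(0, round(100 * stats::pnorm((x - pp$cutoff) /
                                                            observer$spread)))))
  })
}

## attention-trial ratings (correct side, flipped with miss probability)
attention_ratings <- function(observer, scene) {
  correct <- ifelse(scene == "scene_beach", 0L, 100L)
  miss <- stats::runif(length(scene)) < observer$attention_miss_rate
  ifelse(miss, 100L - correct, correct)
}

#' Experiment schedule configuration
#'
#' @param n_training_phases number of training phases (default 9).
#' @param blocks_per_phase blocks per training phase (default 4).
#' @param test_exposure_ms fixed mammogram exposure in test phases (500 ms).
#' @param rating_time_meanlog,rating_time_sdlog lognormal parameters of the
#'   simulated self-paced rating times.
#' @param reset_staircase_each_phase restart the staircase at 2500 ms at the
#'   start of every training phase instead of carrying it across phases.
#' @param emit_feedback_time include a `feedback_time_ms` column (lognormal
#'   feedback-screen times on training trials) in the output.
#' @return list of class `gist_schedule`.
#' @export
experiment_schedule <- function(n_training_phases = 9, blocks_per_phase = 4,
                                test_exposure_ms = 500,
                                rating_time_meanlog = log(1500),
                                rating_time_sdlog = 0.4,
                                reset_staircase_each_phase = FALSE,
                                emit_feedback_time = FALSE) {
  structure(as.list(environment()), class = "gist_schedule")
}

## session bookkeeping: session 1 = pretest + training 1; sessions 2..8 =
## training 2..8; session 9 = training 9 + posttest; session 10 = retention.
training_session_index <- function(phase) pmin(phase, 9L)

test_phase_rows <- function(pools, observer, phase_type, session_index,
                            phases_completed, schedule) {
  at_ret <- phase_type == "retention"
  ## 3 practice trials with feedback, drawn from the training pool
  prac_ids <- c(sample(pools$training$normal, 1),
                sample(pools$training$obvious, 1),
                sample(pools$training$subtle, 1))
  prac_cat <- sub("^train_([a-z]+)_\\d+$", "\\1", prac_ids)
  test <- pools$test[sample.int(nrow(pools$test)), , drop = FALSE]
  cat <- c(prac_cat, test$category)
  n <- length(cat)
  data.frame(
    session_index = session_index,
    phase_type = phase_type,
    phase_index = 0L,
    block_index = 0L,
    trial_index = seq_len(n),
    trial_kind = rep(c("practice", "mammogram"), c(3L, n - 3L)),
    category = cat,
    ground_truth = ifelse(cat == "normal", "normal", "abnormal"),
    rating = simulate_observer_rating(observer, cat, phases_completed, at_ret),
    viewing_time_ms = schedule$test_exposure_ms,
    rating_time_ms = stats::rlnorm(n, schedule$rating_time_meanlog,
                                   schedule$rating_time_sdlog),
    max_viewing_time_ms = schedule$test_exposure_ms,
    feedback_given = rep(c(TRUE, FALSE), c(3L, n - 3L)),
    stringsAsFactors = FALSE)
}

#' Simulate a complete multi-session experiment
#'
#' For each observer, generates a pre-test (3 practice + 200 test trials),
#' nine training phases of four 184-trial blocks with the adaptive
#' maximum-viewing-time staircase (starting at 2500 ms in the first block
#' and, by default, carrying across phases), a post-test, and a retention
#' test. The same 200-stimulus test set is reused across the three test
#' phases. The result is a valid trial table accepted by
#' [validate_trials()] and all analysis stages.
#'
#' @param observers list of [sdt_observer()] / [random_observer()] objects
#'   (a single observer is also accepted); names become participant ids,
#'   else `p01`, `p02`, ... are assigned.
#' @param pools a [stimulus_pools()] object.
#' @param schedule an [experiment_schedule()].
#' @param seed optional integer seed; the full table is reproducible from it.
#' @return validated trial data frame.
#' @export
simulate_experiment <- function(observers, pools = stimulus_pools(),
                                schedule = experiment_schedule(), seed = NULL) {
  if (inherits(observers, "gist_observer")) observers <- list(observers)
  ids <- names(observers)
  if (is.null(ids)) ids <- sprintf("p%02d", seq_along(observers))

  with_seed(seed, {
    all_rows <- vector("list", length(observers))
    for (oi in seq_along(observers)) {
      obs <- observers[[oi]]
      parts <- list(test_phase_rows(pools, obs, "pretest", 1L, 0L, schedule))
      st <- staircase_state()
      for (phase in seq_len(schedule$n_training_phases)) {
        if (schedule$reset_staircase_each_phase) st <- staircase_state()
        for (blk in seq_len(schedule$blocks_per_phase)) {
          bl <- sample_training_block(pools)
          n <- nrow(bl)
          rating <- integer(n)
          mam <- bl$trial_kind == "mammogram"
          rating[mam] <- simulate_observer_rating(obs, bl$category[mam],
                                                  phases_completed = phase - 1L)
          rating[!mam] <- attention_ratings(obs, bl$category[!mam])
          viewing <- stats::runif(n, 500, st$max_viewing_ms)
          parts[[length(parts) + 1L]] <- data.frame(
            session_index = training_session_index(phase),
            phase_type = "training", phase_index = phase, block_index = blk,
            trial_index = bl$slot, trial_kind = bl$trial_kind,
            category = bl$category, ground_truth = bl$ground_truth,
            rating = rating,
            viewing_time_ms = viewing,
            rating_time_ms = stats::rlnorm(n, schedule$rating_time_meanlog,
                                           schedule$rating_time_sdlog),
            max_viewing_time_ms = st$max_viewing_ms,
            feedback_given = TRUE,
            stringsAsFactors = FALSE)
          rr <- rate_estimate(rating[mam], bl$ground_truth[mam])
          st <- staircase_update(st, dprime(rr), mean(viewing[mam]))
        }
      }
      parts[[length(parts) + 1L]] <-
        test_phase_rows(pools, obs, "posttest", 9L,
                        schedule$n_training_phases, schedule)
      parts[[length(parts) + 1L]] <-
        test_phase_rows(pools, obs, "retention", 10L,
                        schedule$n_training_phases, schedule)
      tab <- do.call(rbind, parts)
      tab <- cbind(participant_id = ids[oi], tab, stringsAsFactors = FALSE)
      if (schedule$emit_feedback_time) {
        tab$feedback_time_ms <- ifelse(
          tab$phase_type == "training" & tab$trial_kind == "mammogram",
          stats::rlnorm(nrow(tab), log(800), 0.5), NA_real_)
      }
      all_rows[[oi]] <- tab
    }
    out <- do.call(rbind, all_rows)
    rownames(out) <- NULL
    validate_trials(out)
    out
  })
}
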