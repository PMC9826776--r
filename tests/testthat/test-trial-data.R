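test_that("trial tables round-trip through delimited files field for field", {
  tt <- rbind(
    make_test_phase("p1", "pretest", rep(30L, 80), rep(70L, 120)),
    make_training_sessions("p1")
  )
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trials(tt, csv)
  expect_identical(read_trials(csv), tt)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_trials(tt, tsv, sep = "\t")
  expect_identical(read_trials(tsv, sep = "\t"), tt)
})

test_that("schema and row validation errors name the offender", {
  tt <- make_trials(3)
  expect_error(validate_trials(tt[, setdiff(names(tt), "rating")]),
               "missing column.*rating")

  bad <- make_trials(3)
  bad$rating[2] <- 150L
  expect_error(validate_trials(bad), "rating outside \\[0, 100\\].*row\\(s\\) 2")

  bad <- make_trials(2)
  bad$viewing_time_ms[1] <- 900   # above the 500 ms maximum
  expect_error(validate_trials(bad), "exceeds max_viewing_time_ms.*row\\(s\\) 1")

  bad <- make_trials(2)
  bad$category[2] <- "scene_beach"  # scene category on a mammogram trial
  expect_error(validate_trials(bad), "attention trials and scene categories")

  bad <- make_trials(2, phase_type = "training", phase_index = 1L,
                     block_index = 1L, category = "obvious")
  bad$feedback_given[1] <- FALSE
  expect_error(validate_trials(bad), "training trial without feedback")
})

test_that("exclusion rules follow the pre-registered inattention criteria", {
  # rule 1: more than 30 of 144 attention trials missed in total
  r1 <- apply_exclusion_criteria(make_training_sessions("p1", c(4, 4, 4, 4, 4, 4, 4, 2, 1)))
  expect_equal(r1$total_attention_missed, 31)
  expect_true(grepl("attention_total", r1$reasons))
  expect_true(r1$excluded)

  r1b <- apply_exclusion_criteria(make_training_sessions("p2", c(4, 4, 4, 4, 4, 4, 4, 2, 0)))
  expect_equal(r1b$total_attention_missed, 30)
  expect_false(r1b$excluded)            # exactly 30 is retained ("more than 30")

  # rule 2: more than 6 of 16 in one training session
  r2 <- apply_exclusion_criteria(make_training_sessions("p3", c(7, rep(0, 8))))
  expect_true(r2$excluded)
  expect_identical(r2$reasons, "attention_session")
  r2b <- apply_exclusion_criteria(make_training_sessions("p4", c(6, rep(0, 8))))
  expect_false(r2b$excluded)

  # clean participant with varied ratings is retained with empty reasons
  clean <- rbind(make_test_phase("p5", "pretest",
                                 sample(0:40, 80, TRUE), sample(60:100, 120, TRUE)),
                 make_training_sessions("p5"))
  rc <- apply_exclusion_criteria(clean)
  expect_false(rc$excluded)
  expect_identical(rc$reasons, "")

  # rule 3, inclusive boundary: exactly 170 of 200 pretest trials rated 50
  fifty <- make_test_phase("p6", "pretest",
                           c(rep(50L, 70), rep(20L, 10)),
                           c(rep(50L, 100), rep(80L, 20)))
  r3 <- apply_exclusion_criteria(fifty)
  expect_true(r3$excluded)
  expect_identical(r3$reasons, "fifty_ratings")

  below <- make_test_phase("p7", "pretest",
                           c(rep(50L, 69), rep(20L, 11)),
                           c(rep(50L, 100), rep(80L, 20)))
  expect_false(apply_exclusion_criteria(below)$excluded)

  # rule 3 on training: more than one flagged training session required
  tr1 <- make_training_sessions("p8")
  tr1$rating[tr1$trial_kind == "mammogram" & tr1$phase_index == 1] <- 50L
  expect_false(apply_exclusion_criteria(tr1)$excluded)
  tr2 <- tr1
  tr2$rating[tr2$trial_kind == "mammogram" & tr2$phase_index == 2] <- 50L
  expect_true(apply_exclusion_criteria(tr2)$excluded)

  # malformed schedule: a training phase without attention trials
  noatt <- make_training_phase("p9", 1)
  noatt <- noatt[noatt$trial_kind != "attention", ]
  expect_error(apply_exclusion_criteria(noatt), "malformed schedule")
})

test_that("exclusion reports are invariant to trial row order", {
  tt <- rbind(make_training_sessions("a", c(7, rep(0, 8))),
              make_training_sessions("b", rep(0, 9)))
  shuffled <- tt[sample(nrow(tt)), ]
  expect_identical(apply_exclusion_criteria(tt),
                   apply_exclusion_criteria(shuffled))
})

test_that("timing summaries exclude single-pass 3-SD outliers per session", {
  # 100 rating times of 1000 ms plus one of 10000 ms: only the latter drops
  tt <- make_trials(101, rating_time_ms = c(rep(1000, 100), 10000))
  x <- tt$rating_time_ms
  expect_true(10000 > mean(x) + 3 * sd(x))   # hand oracle for the cutoff
  ts <- timing_summaries(tt, screens = "rating")
  expect_equal(ts$n_excluded_outliers, 1L)
  expect_equal(ts$mean_ms, 1000)
  expect_equal(ts$median_ms, 1000)

  # zero variance: nothing excluded, mean = median = the value
  tz <- timing_summaries(make_trials(50, rating_time_ms = 700), screens = "rating")
  expect_equal(tz$n_excluded_outliers, 0L)
  expect_equal(tz$mean_ms, 700)
  expect_equal(tz$median_ms, 700)

  # feedback screen in a test phase: empty-flagged summary, not an error
  tf <- timing_summaries(make_trials(20), screens = "feedback")
  expect_equal(tf$n_trials, 0L)
  expect_true(is.na(tf$mean_ms))

  # feedback screen with the optional duration column present
  tr <- make_trials(30, phase_type = "training", phase_index = 1L,
                    block_index = 1L, category = "obvious",
                    max_viewing_time_ms = 2500)
  tr$feedback_time_ms <- 800
  tfb <- timing_summaries(tr, screens = "feedback")
  expect_equal(tfb$n_trials, 30L)
  expect_equal(tfb$mean_ms, 800)
})
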