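test_that("default stimulus pools match the experimental design", {
  pools <- stimulus_pools()
  expect_equal(sum(lengths(pools$training)), 5668)
  expect_equal(lengths(pools$training),
               c(normal = 1558L, obvious = 1019L, subtle = 899L,
                 contralateral = 1868L, prior = 324L))
  expect_equal(nrow(pools$test), 200)
  expect_equal(mean(pools$test$ground_truth == "abnormal"), 0.6)
  # test identifiers never occur in the training pool
  expect_length(intersect(pools$test$stimulus_id, unlist(pools$training)), 0)
  expect_error(pool_config(training = c(normal = 1)), "categories")
})

test_that("minimal pools raise sampling errors downstream", {
  tiny <- stimulus_pools(pool_config(
    training = c(normal = 1, obvious = 1, subtle = 1, contralateral = 1, prior = 1),
    test = c(normal = 1, obvious = 1, subtle = 1, contralateral = 1, prior = 1)))
  expect_error(sample_training_block(tiny, seed = 1), "pool exhaustion")
})

test_that("training blocks carry the 72/27/27/54 mix and quarterly attention trials", {
  pools <- stimulus_pools()
  bl <- sample_training_block(pools, seed = 2)
  expect_equal(nrow(bl), 184)
  expect_equal(sum(bl$trial_kind == "attention"), 4)
  tab <- table(bl$category[bl$trial_kind == "mammogram"])
  expect_equal(tab[["normal"]], 72)
  expect_equal(tab[["obvious"]], 27)
  expect_equal(tab[["subtle"]], 27)
  expect_equal(sum(tab[c("contralateral", "prior")]), 54)
  # one attention trial per quarter of the block
  q <- findInterval(bl$slot[bl$trial_kind == "attention"],
                    c(1, 47, 93, 139), rightmost.closed = FALSE)
  expect_equal(sort(q), 1:4)

  # fixed counts are seed-invariant (the contralateral:prior split within the
  # 54 global draws is proportional, hence random); composition order is not
  bl2 <- sample_training_block(pools, seed = 3)
  tab2 <- table(bl2$category[bl2$trial_kind == "mammogram"])
  expect_equal(tab2[c("normal", "obvious", "subtle")],
               tab[c("normal", "obvious", "subtle")])
  expect_equal(sum(tab2[c("contralateral", "prior")]), 54)
  expect_false(identical(bl$stimulus_id, bl2$stimulus_id))

  # no stimulus repeats within any block
  set.seed(5)
  for (i in 1:200) {
    b <- sample_training_block(pools)
    ids <- b$stimulus_id[b$trial_kind == "mammogram"]
    expect_equal(anyDuplicated(ids), 0)
  }
})

test_that("the staircase follows the d-prime rule and stays in bounds", {
  st <- staircase_state()
  expect_equal(st$max_viewing_ms, 2500)

  # d' above 0.2: drop to 90% of the block's mean actual viewing time
  up <- staircase_update(staircase_state(1500), 0.3, 1000)
  expect_equal(up$max_viewing_ms, 900)

  # d' below 0.05 at the ceiling: stays at 2500
  expect_equal(staircase_update(staircase_state(2500), 0.04, 1200)$max_viewing_ms, 2500)
  # ... and rises by 5% away from it
  expect_equal(staircase_update(staircase_state(2000), 0.04, 1200)$max_viewing_ms, 2100)

  # dead zone between 0.05 and 0.2: unchanged
  expect_equal(staircase_update(staircase_state(1234), 0.10, 800)$max_viewing_ms, 1234)

  # floor: a fast block cannot push the window below 500 ms
  expect_equal(staircase_update(staircase_state(600), 1.5, 520)$max_viewing_ms, 500)

  expect_error(staircase_update(staircase_state(600), 0.3, 700),
               "exceeds the current maximum")
  expect_error(staircase_state(3000), "must lie in")

  # property: any history of updates stays within [500, 2500]
  set.seed(6)
  st <- staircase_state()
  for (i in 1:500) {
    mv <- runif(1, 500, st$max_viewing_ms)
    st <- staircase_update(st, rnorm(1, 0.1, 0.3), mv)
    expect_gte(st$max_viewing_ms, 500)
    expect_lte(st$max_viewing_ms, 2500)
  }
})

test_that("observer rating models have the intended distributions", {
  # random observer: uniform over the 101-point lattice
  set.seed(7)
  r <- simulate_observer_rating(random_observer(), rep("normal", 1e5))
  expect_true(all(r >= 0 & r <= 100))
  gof <- chisq.test(tabulate(r + 1L, 101L))
  expect_gt(gof$p.value, 0.001)

  # null SDT observer: category does not shift the rating distribution
  obs0 <- sdt_observer(d0 = 0)
  rn <- simulate_observer_rating(obs0, rep("normal", 4000), seed = 8)
  ra <- simulate_observer_rating(obs0, rep("obvious", 4000), seed = 9)
  expect_lt(abs(mean(rn) - mean(ra)), 2)
  expect_gt(suppressWarnings(ks.test(rn, ra)$p.value), 0.001)

  # round-trip recovery of d' and criterion through the analysis path
  obs1 <- sdt_observer(d0 = 1, c0 = 0)
  set.seed(10)
  cats <- rep(c("normal", "obvious", "subtle", "contralateral", "prior"),
              each = 5000)
  rr <- rate_estimate(simulate_observer_rating(obs1, cats),
                      ifelse(cats == "normal", "normal", "abnormal"))
  expect_lt(abs(dprime(rr) - 1), 0.1)
  expect_lt(abs(criterion(rr) - 0), 0.1)

  # a liberal criterion shifts ratings upward
  lib <- sdt_observer(d0 = 0.5, c0 = -0.8)
  rl <- simulate_observer_rating(lib, rep("normal", 5000), seed = 11)
  expect_gt(mean(rl > 50), 0.6)
})

test_that("simulated experiments have the full session structure", {
  tr <- simulate_experiment(sdt_observer(d0 = 0.5), seed = 12)
  expect_equal(nrow(tr), 203 + 9 * 736 + 203 + 203)
  expect_silent(validate_trials(tr))
  expect_equal(as.vector(table(tr$phase_type)[c("pretest", "posttest", "retention")]),
               c(203, 203, 203))

  # per training phase: 4 blocks x 184 trials, mix 288/108/108/216, 16 attention
  for (p in c(1, 5, 9)) {
    ph <- tr[tr$phase_type == "training" & tr$phase_index == p, ]
    expect_equal(nrow(ph), 736)
    expect_equal(sum(ph$trial_kind == "attention"), 16)
    expect_equal(sum(ph$category == "normal"), 288)
    expect_equal(sum(ph$category == "obvious"), 108)
    expect_equal(sum(ph$category == "subtle"), 108)
    expect_equal(sum(ph$category %in% c("contralateral", "prior")), 216)
  }

  # staircase trace stays within bounds and starts at 2500
  expect_equal(tr$max_viewing_time_ms[tr$phase_type == "training"][1], 2500)
  expect_true(all(tr$max_viewing_time_ms[tr$phase_type == "training"] >= 500))
  expect_true(all(tr$max_viewing_time_ms <= 2500))

  # same seed reproduces the table bit for bit; written files round-trip
  tr2 <- simulate_experiment(sdt_observer(d0 = 0.5), seed = 12)
  expect_identical(tr, tr2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, f)
  back <- read_trials(f)
  expect_equal(table(back$phase_type), table(tr$phase_type))

  # attentive observers pass every exclusion rule
  expect_false(any(apply_exclusion_criteria(tr)$excluded))
})

test_that("configured attention misses trigger the exclusion rules", {
  # miss rate 0.3: expected 43 of 144 misses, far above the rule-1 threshold
  tr <- simulate_experiment(sdt_observer(d0 = 0.5, attention_miss_rate = 0.3),
                            seed = 13)
  ex <- apply_exclusion_criteria(tr)
  expect_true(ex$excluded)
  expect_true(grepl("attention_total", ex$reasons))
  expect_gt(ex$total_attention_missed, 30)
})

test_that("learner-type observers are recovered; static observers are unbiased", {
  obs <- c(lapply(1:9, function(i) sdt_observer(d0 = 0.2, learn = 0.08)),
           lapply(1:6, function(i) sdt_observer(d0 = 0.2, learn = 0)))
  names(obs) <- sprintf("s%02d", 1:15)
  tr <- simulate_experiment(obs, seed = 14)
  cl <- classify_learners(phase_summaries(tr))
  cl <- cl[order(cl$participant_id), ]
  expect_gte(sum(cl$label[1:9] == "learner"), 8)
  # statics have sign-symmetric trajectory correlations centred on zero
  expect_lt(abs(mean(cl$pearson_r[10:15])), 0.5)
})
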