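test_that("block preferences reproduce hand-counted fixture values", {
  ex <- example_log()
  down <- block_preferences(ex$trials, shifted_side = "left",
                            session_index = 2)
  expect_identical(down$kind, "small")
  expect_equal(down$blocks$raw, c(14 / 21, 10 / 20, 8 / 20, 5 / 19))
  expect_equal(down$blocks$normalized,
               c(1, 0.75, 0.6, (5 / 19) / (14 / 21)))

  up <- block_preferences(ex$trials, shifted_side = "right",
                          session_index = 3)
  expect_equal(up$blocks$normalized[1:3], c(1, 1.5, 1.8))
})

test_that("normalization is the identity for constant and baseline blocks", {
  choices <- rep("left", 80)
  tr <- data.frame(subject_id = "A", group = "WT_like",
                   phase_label = "small_downshift", session_index = 0L,
                   trial_index = seq_along(choices) - 1L,
                   trial_type = "free_choice", cue_side = "both",
                   choice = choices, correct = TRUE, reward_boluses = 2L,
                   schedule_epoch = "pre_shift", stringsAsFactors = FALSE)
  bp <- block_preferences(tr, "left")
  expect_equal(bp$blocks$normalized, rep(1, 4))      # constant preference
  expect_equal(bp$blocks$normalized[1], 1)           # baseline by definition

  # zero baseline preference: flagged missing, not an error
  tr$choice <- rep("right", 80)
  expect_warning(bp0 <- block_preferences(tr, "left"), "baseline")
  expect_true(all(is.na(bp0$blocks$normalized)))
})

test_that("the learning-bias score follows its sign convention", {
  fake_bp <- function(norms, id = "A") {
    structure(list(subject_id = id, shifted_side = "left", kind = "small",
                   blocks = data.frame(block = c("baseline", "b1", "b2", "b3"),
                                       n_trials = c(21L, 20L, 20L, 19L),
                                       raw = norms * 0.5, normalized = norms,
                                       stringsAsFactors = FALSE)),
              class = "block_preference")
  }
  # delta_u = 0.3, delta_d = 0.1 -> bias = 0.2
  b <- learning_bias(fake_bp(c(1, 1.3, 1.5, 1.6)),
                     fake_bp(c(1, 0.95, 0.9, 0.8)))
  expect_equal(b$delta_u, 0.3)
  expect_equal(b$delta_d, 0.1)
  expect_equal(b$bias, 0.2)

  # equal deltas cancel for any delta
  for (d in c(-0.2, 0, 0.17, 0.8)) {
    b0 <- learning_bias(fake_bp(c(1, 1 + d, 1, 1)),
                        fake_bp(c(1, 1, 1 - d, 1)))
    expect_equal(b0$bias, 0)
  }

  # switching faster after the downshift than the upshift -> negative bias
  b_neg <- learning_bias(fake_bp(c(1, 1.05, 1.3, 1.5)),
                         fake_bp(c(1, 0.6, 0.4, 0.3)))
  expect_lt(b_neg$bias, 0)

  # fixture: delta_u = 0.5, delta_d = 0.4 -> bias = 0.1
  ex <- example_log()
  bias <- learning_bias_table(ex$trials, ex$sessions)
  expect_equal(bias$delta_u, 0.5)
  expect_equal(bias$delta_d, 0.4)
  expect_equal(bias$bias, 0.1, tolerance = 1e-12)
})

test_that("running preference uses a centered, edge-truncated 11-trial window", {
  mk <- function(choices) {
    data.frame(subject_id = "A", group = "WT_like", phase_label = "baseline",
               session_index = 0L, trial_index = seq_along(choices) - 1L,
               trial_type = "free_choice", cue_side = "both",
               choice = choices, correct = TRUE, reward_boluses = 2L,
               schedule_epoch = "pre_shift", stringsAsFactors = FALSE)
  }
  rp <- running_preference(mk(rep("left", 30)), "left")
  expect_equal(rp$preference, rep(1, 30))
  expect_identical(nrow(rp), 30L)

  # strict alternation: interior windows hold 6 or 5 of 11 on a side
  alt <- rep(c("left", "right"), 15)
  rp2 <- running_preference(mk(alt), "left")
  interior <- rp2$preference[6:25]
  expect_true(all(interior %in% c(6 / 11, 5 / 11)))
  # first trial: truncated window of 6 trials (3 left)
  expect_equal(rp2$preference[1], 3 / 6)
  expect_true(rp2$truncated[1])
  expect_false(rp2$truncated[6])
})

test_that("risky-choice scores average test sessions and flag missing data", {
  ex <- example_log()
  rs <- risky_choice_scores(ex$trials, ex$sessions)
  expect_equal(rs$even, 0.5)              # mean of 0.2, 0.4, 0.6, 0.8
  expect_identical(rs$n_test_even, 4L)
  expect_true(is.na(rs$risky_better))     # no sessions for that condition
  expect_true(is.na(rs$average_risky))

  # invariant to session order within a condition
  perm <- ex$sessions
  perm <- perm[rev(seq_len(nrow(perm))), ]
  expect_equal(risky_choice_scores(ex$trials, perm)$even, 0.5)

  # seeded 50/50 chooser lands within 3 s.e. of 0.5
  set.seed(123)
  n_fc <- 60L
  rows <- do.call(rbind, lapply(1:4, function(k) {
    data.frame(subject_id = "B", group = "WT_like",
               phase_label = "risk_test", session_index = k,
               trial_index = seq_len(n_fc) - 1L, trial_type = "free_choice",
               cue_side = "both",
               choice = sample(c("left", "right"), n_fc, replace = TRUE),
               correct = TRUE, reward_boluses = 2L,
               schedule_epoch = "pre_shift", stringsAsFactors = FALSE)
  }))
  sess <- data.frame(subject_id = "B", group = "WT_like", session_index = 1:4,
                     phase_label = "risk_test", shift_kind = NA,
                     shift_direction = NA, shifted_side = NA,
                     risk_condition = "even", risky_side = "left",
                     stringsAsFactors = FALSE)
  rs2 <- risky_choice_scores(rows, sess)
  expect_lt(abs(rs2$even - 0.5), 3 * sqrt(0.25 / (4 * n_fc)))
})

test_that("accuracy series match hand counts", {
  ex <- example_log()
  acc <- accuracy_series(ex$trials)
  expect_equal(acc$pav_1, 0.75)           # 45 of 60 correct
  expect_equal(acc$forced_accuracy, 0.9)  # 54 of 60 forced trials correct
  expect_true(is.na(acc$pav_3))
})

test_that("all metrics are invariant to mirroring left and right", {
  cfg <- small_cohort_config(n_clh = 3, n_wt = 3, seed = 7,
                             phases = list(pavlovian = FALSE))
  cohort <- simulate_cohorts(cfg)
  m <- mirror_log(cohort$trials, cohort$sessions)

  sbt <- shift_block_table(cohort$trials, cohort$sessions, kind = "small")
  sbt_m <- shift_block_table(m$trials, m$sessions, kind = "small")
  expect_equal(sbt$raw, sbt_m$raw)
  expect_equal(sbt$normalized, sbt_m$normalized)

  bias <- learning_bias_table(cohort$trials, cohort$sessions)
  bias_m <- learning_bias_table(m$trials, m$sessions)
  expect_equal(bias$bias, bias_m$bias)

  rs <- risky_choice_scores(cohort$trials, cohort$sessions)
  rs_m <- risky_choice_scores(m$trials, m$sessions)
  expect_equal(rs$average_risky, rs_m$average_risky)

  acc <- accuracy_series(cohort$trials)
  acc_m <- accuracy_series(m$trials)
  expect_equal(acc$forced_accuracy, acc_m$forced_accuracy)
})

test_that("every simulated subject has normalized baseline preference 1", {
  cfg <- small_cohort_config(n_clh = 4, n_wt = 4, seed = 23,
                             phases = list(pavlovian = FALSE, risk = FALSE))
  cohort <- simulate_cohorts(cfg)
  sbt <- shift_block_table(cohort$trials, cohort$sessions, kind = "small")
  base <- sbt[sbt$block == "baseline", ]
  expect_true(all(is.na(base$normalized) | base$normalized == 1))
})

test_that("metric computation on a full cohort is fast", {
  cfg <- small_cohort_config(n_clh = 11, n_wt = 13, seed = 2,
                             phases = list(pavlovian = FALSE,
                                           baseline = FALSE))
  cohort <- simulate_cohorts(cfg)
  elapsed <- system.time({
    shift_block_table(cohort$trials, cohort$sessions, kind = "small")
    learning_bias_table(cohort$trials, cohort$sessions)
    risky_choice_scores(cohort$trials, cohort$sessions)
    accuracy_series(cohort$trials)
  })[["elapsed"]]
  expect_lt(elapsed, 5)
})
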