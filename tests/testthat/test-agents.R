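test_that("the delta rule updates only the chosen side with the signed rate", {
  p <- agent_params(alpha_plus = 0.5, alpha_minus = 0.25, q_init = 2)
  st <- agent_state(p)
  st2 <- q_update(st, "left", 4, p)          # positive error: 2 + 0.5 * 2
  expect_equal(st2$q[["left"]], 3)
  expect_equal(st2$q[["right"]], 2)
  st3 <- q_update(st, "left", 2, p)          # zero error
  expect_equal(st3$q[["left"]], 2)
  st4 <- q_update(st, "right", 0, p)         # negative error: 2 - 0.25 * 2
  expect_equal(st4$q[["right"]], 1.5)
})

test_that("a fixed reward sequence replays to the oracle's final value", {
  p <- agent_params(alpha_plus = 0.3, alpha_minus = 0.07, q_init = 1)
  rewards <- c(4, 1, 7, 2, 2, 0, 5, 1, 3, 4)
  st <- agent_state(p)
  for (r in rewards) st <- q_update(st, "left", r, p)
  # independent step-by-step replay
  q <- 1
  for (r in rewards) {
    d <- r - q
    q <- q + (if (d >= 0) 0.3 else 0.07) * d
  }
  expect_equal(st$q[["left"]], q, tolerance = 1e-12)
})

test_that("softmax choice probabilities match the closed form and saturate", {
  p <- agent_params(beta = 1)
  st <- agent_state(p)
  expect_equal(p_choose_left(st, p), 0.5)
  p0 <- agent_params(beta = 0)
  st$q <- c(left = 7, right = 1)
  expect_equal(p_choose_left(st, p0), 0.5)
  st$q <- c(left = 3, right = 2)
  expect_equal(p_choose_left(st, p), 1 / (1 + exp(-1)), tolerance = 1e-12)
  pbig <- agent_params(beta = 50)
  st$q <- c(left = 10, right = -10)
  expect_identical(p_choose_left(st, pbig), 1)
  st$q <- c(left = -10, right = 10)
  expect_identical(p_choose_left(st, pbig), 0)
})

test_that("forced-trial accuracy follows the lapse rate", {
  p0 <- agent_params(lapse = 0)
  st <- agent_state(p0)
  set.seed(1)
  expect_true(all(replicate(50, respond_forced(st, p0, "left")$correct)))

  p <- agent_params(lapse = 0.1)
  set.seed(2)
  hits <- replicate(10000, respond_forced(st, p, "right")$correct)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(mean(hits) - 0.9), 3 * se)
  # a lapse responds to the un-cued port
  set.seed(3)
  resp <- respond_forced(st, agent_params(lapse = 0.5), "left")
  expect_identical(resp$correct, resp$choice == "left")
})

test_that("Pavlovian responding tracks associative strength and acquires", {
  p1 <- agent_params(v_init = 1, alpha_pav = 0.1)
  st <- agent_state(p1)
  set.seed(4)
  expect_true(all(replicate(50, respond_pavlovian(st, p1, "left")$correct)))

  # v stays in [0, 1] and accuracy is non-decreasing across sessions
  p <- agent_params(alpha_pav = 0.1, v_init = 0)
  pav_plan <- mini_plan(lapply(1:5, function(k)
    tmpl("pavlovian", c(pavlovian_cue = 60L), pav_contingent = k >= 3)))
  acc <- matrix(NA_real_, 200, 5)
  for (agent in 1:200) {
    run <- simulate_subject(pav_plan, p, seed = 9000 + agent)
    expect_true(all(run$trials$v_pav >= 0 & run$trials$v_pav <= 1))
    acc[agent, ] <- tapply(run$trials$correct, run$trials$session_index, mean)
  }
  means <- colMeans(acc)
  expect_true(all(diff(means) > -0.01))      # monotone within sampling noise
  expect_gt(means[5], means[1])
})

test_that("subject simulation is deterministic and structurally correct", {
  shift_plan <- mini_plan(list(
    tmpl("large_upshift",
         c(free_choice = 60L, forced_left = 60L, forced_right = 60L),
         sched = c(left = 2, right = 2), reinit = c(left = 2, right = 2),
         shift = list(kind = "large", direction = "up",
                      target_rule = "nonpreferred"))
  ))
  p <- agent_params(lapse = 0)
  r1 <- simulate_subject(shift_plan, p, seed = 21)
  r2 <- simulate_subject(shift_plan, p, seed = 21)
  expect_identical(r1, r2)
  expect_identical(nrow(r1$trials), 180L)
  expect_identical(sum(r1$trials$trial_type == "free_choice"), 60L)
  # lapse = 0: no errors on forced slots
  forced <- r1$trials$trial_type %in% c("forced_left", "forced_right")
  expect_true(all(r1$trials$correct[forced]))
})

test_that("the simulated Q trajectory equals an independent replay", {
  plan <- mini_plan(list(
    tmpl("retrain", c(free_choice = 20L, forced_left = 20L,
                      forced_right = 20L),
         sched = c(left = 3, right = 3), reinit = c(left = 3, right = 3)),
    tmpl("small_downshift",
         c(free_choice = 80L, forced_left = 80L, forced_right = 80L),
         sched = c(left = 3, right = 3),
         shift = list(kind = "small", direction = "down",
                      target_rule = "opposite"))
  ), anchor = "left")
  p <- agent_params(alpha_plus = 0.04, alpha_minus = 0.2, lapse = 0.1)
  run <- simulate_subject(plan, p, seed = 77)
  replay <- q_replay_oracle(run$trials, p,
                            resets = list(c(3, 3), NULL))
  expect_equal(run$trials$q_left, replay[, 1], tolerance = 1e-12)
  expect_equal(run$trials$q_right, replay[, 2], tolerance = 1e-12)
})

test_that("Q values stay within the schedule's reward range", {
  cfg <- small_cohort_config(n_clh = 2, n_wt = 2, seed = 31,
                             phases = list(pavlovian = FALSE))
  cohort <- simulate_cohorts(cfg)
  expect_true(all(cohort$trials$q_left <= 7 + 1e-12))
  expect_true(all(cohort$trials$q_right <= 7 + 1e-12))
  expect_true(all(cohort$trials$q_left >= 0))
  expect_true(all(cohort$trials$q_right >= 0))
})

test_that("cohort simulation has the published sizes and is reproducible", {
  cfg <- default_cohort_config()
  plan <- build_protocol(list(n_clh = cfg$groups$cLH_like$n,
                              n_wt = cfg$groups$WT_like$n),
                         rng_seed = cfg$seed)
  expect_length(plan$subjects, 24L)       # 11 cLH-like + 13 WT-like

  cfg_small <- small_cohort_config(seed = 17)
  c1 <- simulate_cohorts(cfg_small)
  c2 <- simulate_cohorts(cfg_small)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$params, c2$params)
})

risk_block_plan <- function() {
  mini_plan(c(
    lapply(1:3, function(k)
      tmpl("risk_train",
           c(free_choice = 60L, forced_left = 60L, forced_right = 60L),
           risk = list(condition = "even", risky_side = "left"),
           reinit = if (k == 1) c(left = 2, right = 2))),
    lapply(1:2, function(k)
      tmpl("risk_test",
           c(free_choice = 60L, forced_left = 60L, forced_right = 60L),
           risk = list(condition = "even", risky_side = "left")))
  ))
}

even_risky_fraction <- function(alpha_plus, alpha_minus, n_agents, seed0) {
  plan <- risk_block_plan()
  vapply(seq_len(n_agents), function(i) {
    p <- agent_params(alpha_plus = alpha_plus, alpha_minus = alpha_minus,
                      beta = 1, q_init = 2, lapse = 0.1)
    run <- simulate_subject(plan, p, seed = seed0 + i)
    tr <- run$trials
    fc <- tr[tr$trial_type == "free_choice" & tr$phase_label == "risk_test", ]
    mean(fc$choice == "left")
  }, 0)
}

test_that("learning-rate asymmetry drives risk sensitivity monotonically", {
  # ratio alpha_minus / alpha_plus swept upward at fixed mean rate
  ratios <- c(0.25, 0.5, 1, 2, 4)
  means <- vapply(seq_along(ratios), function(k) {
    am <- 0.05 * sqrt(ratios[k])
    ap <- 0.05 / sqrt(ratios[k])
    mean(even_risky_fraction(ap, am, 200, seed0 = 4000 * k))
  }, 0)
  expect_true(all(diff(means) < 0))     # strictly decreasing in the ratio

  # symmetric rates: indifferent to risk (within 3 s.e. of 0.5)
  sym <- even_risky_fraction(0.05, 0.05, 200, seed0 = 80000)
  se <- sd(sym) / sqrt(length(sym))
  expect_lt(abs(mean(sym) - 0.5), 3 * se + 0.02)

  # negative bias: risk averse
  averse <- even_risky_fraction(0.02, 0.3, 200, seed0 = 90000)
  expect_lt(mean(averse), 0.5)
})

test_that("biased and symmetric cohorts separate on small shifts", {
  # direction of the shift asymmetry: faster downshift switching and slower
  # upshift switching for negatively biased agents, across seeded cohorts
  cfg <- small_cohort_config(n_clh = 6, n_wt = 6, seed = 0,
                             phases = list(pavlovian = FALSE,
                                           baseline = FALSE, risk = FALSE))
  signs <- vapply(1:12, function(k) {
    cfg$seed <- 300 + k
    cohort <- simulate_cohorts(cfg)
    sbt <- shift_block_table(cohort$trials, cohort$sessions, kind = "small")
    mb <- function(sh, bl, g) {
      mean(sbt$normalized[sbt$shift == sh & sbt$block == bl &
                            sbt$group == g], na.rm = TRUE)
    }
    c(down = mb("down", "b2", "cLH_like") < mb("down", "b2", "WT_like"),
      up = mb("up", "b1", "cLH_like") < mb("up", "b1", "WT_like"))
  }, logical(2))
  # sign test: at least 10/12 cohorts in the predicted direction
  expect_gte(sum(signs["down", ]), 10)
  expect_gte(sum(signs["up", ]), 10)
})
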