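#' Simulate one subject through its protocol plan
#'
#' Runs an asymmetric-learning-rate agent through every session of its plan
#' and returns the complete trial log plus a resolved per-session manifest.
#' Action values persist across sessions (the protocol's retraining sessions
#' re-equalize them, as in the animals); the Pavlovian associative strength
#' persists across the five Pavlovian sessions. Mid-session shifts fire once
#' the 21st free-choice trial completes; the large upshift targets the side
#' the subject chose on a minority of those 21 trials (ties broken toward
#' left), and that side becomes the subject's "anchor" side: the large
#' downshift re-targets it and the small shifts target its opposite.
#'
#' @param sub_plan one element of `build_protocol(...)$subjects`.
#' @param params an [agent_params()] object.
#' @param seed integer seed; logs are deterministic given seed, plan, params.
#' @param update_on_forced_error if `TRUE`, an erroneous forced trial updates
#'   the cued side's value toward 0 (reward omission); default `FALSE` (no
#'   reward, no update).
#' @return list with `trials` (data.frame, one row per trial: subject_id,
#'   group, phase_label, session_index, trial_index, trial_type, cue_side,
#'   choice, correct, reward_boluses, schedule_epoch, plus agent-internal
#'   columns q_left, q_right, v_pav) and `sessions` (one row per session with
#'   the resolved schedules, shifted side, risk condition and risky side).
#' @export
simulate_subject <- function(sub_plan, params, seed,
                             update_on_forced_error = FALSE) {
  validate_agent_params(params)
  with_preserved_seed({
    set.seed(as.integer(seed))
    sim_subject_impl(sub_plan, params, update_on_forced_error)
  })
}

TYPE_CODES <- c(free_choice = 1L, forced_left = 2L, forced_right = 3L,
                pavlovian_cue = 4L)
SIDE_LEVELS <- c("left", "right", "both")

sim_subject_impl <- function(sub_plan, params, update_on_forced_error) {
  anchor <- NA_character_
  qL <- params$q_init
  qR <- params$q_init
  v <- params$v_init
  trial_chunks <- vector("list", length(sub_plan$sessions))
  sess_rows <- vector("list", length(sub_plan$sessions))

  for (si in seq_along(sub_plan$sessions)) {
    tmpl <- sub_plan$sessions[[si]]
    needs_anchor <-
      (!is.null(tmpl$sched) && "anchor" %in% names(tmpl$sched)) ||
      (!is.null(tmpl$reinit) && "anchor" %in% names(tmpl$reinit)) ||
      (!is.null(tmpl$shift) &&
         tmpl$shift$target_rule %in% c("anchor", "opposite"))
    if (needs_anchor && is.na(anchor)) {
      anchor <- sub_plan$fallback_anchor_side
    }
    if (!is.null(tmpl$reinit)) {
      # phase boundary: the interposed (re)training is modeled as completed,
      # so action values start at the incoming baseline schedule's values
      q0 <- resolve_boluses(tmpl$reinit, anchor)
      qL <- q0[["left"]]
      qR <- q0[["right"]]
    }
    res <- sim_session(tmpl, params, qL, qR, v, anchor,
                       update_on_forced_error)
    qL <- res$qL
    qR <- res$qR
    v <- res$v
    anchor <- res$anchor
    trial_chunks[[si]] <- res$rec
    sess_rows[[si]] <- list(
      res$pool[["free_choice"]], res$pool[["forced_left"]],
      res$pool[["forced_right"]], res$pool[["pavlovian_cue"]],
      res$shift_kind, res$shift_direction, res$shifted_side,
      res$shift_trigger, res$risk_condition, res$risky_side,
      res$pre_schedule, res$post_schedule
    )
  }
  sess_col <- function(k, cast) cast(vapply(sess_rows, function(r)
    as.vector(r[[k]]), cast(NA)))
  sessions <- data.frame(
    subject_id = sub_plan$subject_id,
    group = sub_plan$group,
    session_index = seq_along(sess_rows) - 1L,
    phase_label = vapply(sub_plan$sessions, function(s) s$phase, ""),
    n_free = sess_col(1, as.integer),
    n_forced_left = sess_col(2, as.integer),
    n_forced_right = sess_col(3, as.integer),
    n_pavlovian = sess_col(4, as.integer),
    shift_kind = sess_col(5, as.character),
    shift_direction = sess_col(6, as.character),
    shifted_side = sess_col(7, as.character),
    shift_trigger = sess_col(8, as.integer),
    risk_condition = sess_col(9, as.character),
    risky_side = sess_col(10, as.character),
    pre_schedule = sess_col(11, as.character),
    post_schedule = sess_col(12, as.character),
    stringsAsFactors = FALSE
  )

  n_sess <- vapply(trial_chunks, function(r) length(r$type), 0L)
  trials <- data.frame(
    subject_id = sub_plan$subject_id,
    group = sub_plan$group,
    phase_label = rep(vapply(sub_plan$sessions, function(s) s$phase, ""),
                      n_sess),
    session_index = rep(seq_along(n_sess) - 1L, n_sess),
    trial_index = unlist(lapply(n_sess, function(n) seq_len(n) - 1L),
                         use.names = FALSE),
    trial_type = names(TYPE_CODES)[unlist(lapply(trial_chunks, `[[`, "type"),
                                          use.names = FALSE)],
    cue_side = SIDE_LEVELS[unlist(lapply(trial_chunks, `[[`, "cue"),
                                  use.names = FALSE)],
    choice = SIDE_LEVELS[unlist(lapply(trial_chunks, `[[`, "choice"),
                                use.names = FALSE)],
    correct = unlist(lapply(trial_chunks, `[[`, "correct"),
                     use.names = FALSE),
    reward_boluses = unlist(lapply(trial_chunks, `[[`, "reward"),
                            use.names = FALSE),
    schedule_epoch = c("pre_shift", "post_shift")[
      unlist(lapply(trial_chunks, `[[`, "post"), use.names = FALSE) + 1L],
    q_left = unlist(lapply(trial_chunks, `[[`, "qL"), use.names = FALSE),
    q_right = unlist(lapply(trial_chunks, `[[`, "qR"), use.names = FALSE),
    v_pav = unlist(lapply(trial_chunks, `[[`, "v"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  list(trials = trials, sessions = sessions)
}

# Resolve a template's symbolic schedule (anchor/opposite roles) to concrete
# per-side bolus counts.
resolve_boluses <- function(sched, anchor) {
  if (all(c("left", "right") %in% names(sched))) {
    return(c(left = unname(sched[["left"]]), right = unname(sched[["right"]])))
  }
  if (is.na(anchor)) {
    stop("protocol error: anchor side needed before it was resolved",
         call. = FALSE)
  }
  out <- c(left = NA_real_, right = NA_real_)
  out[[anchor]] <- sched[["anchor"]]
  out[[other_side(anchor)]] <- sched[["opposite"]]
  out
}

bol_schedule <- function(bol) {
  reward_schedule(bol[["left"]], bol[["right"]])
}

sim_session <- function(tmpl, params, qL, qR, v, anchor,
                        update_on_forced_error) {
  pool <- stats::setNames(integer(length(TYPE_CODES)), names(TYPE_CODES))
  pool[names(tmpl$pool)] <- as.integer(tmpl$pool)
  n <- sum(pool)
  types <- TYPE_CODES[sample(rep(names(pool), times = pool))]

  is_risk <- !is.null(tmpl$risk)
  is_shift <- !is.null(tmpl$shift)
  is_pav <- tmpl$phase == "pavlovian"

  risky_code <- 0L
  risky_draws <- NULL
  pre_sched <- NULL
  if (is_risk) {
    sched <- make_risk_schedule(tmpl$risk$condition, tmpl$risk$risky_side)
    risky_code <- match(tmpl$risk$risky_side, SIDE_LEVELS)
    risky_draws <- draw_reward(sched, tmpl$risk$risky_side, n)
    bol <- c(left = 2, right = 2)  # safe value; risky draws override
    pre_sched <- sched
  } else if (!is_pav) {
    bol <- resolve_boluses(tmpl$sched, anchor)
    pre_sched <- bol_schedule(bol)
  }

  trigger <- if (is_shift) 21L else 0L
  post_bol <- NULL
  post_sched <- NULL
  shifted_side <- NA_character_
  post_active <- FALSE
  alpha_plus <- params$alpha_plus
  alpha_minus <- params$alpha_minus
  beta <- params$beta
  lapse <- params$lapse
  alpha_pav <- params$alpha_pav
  contingent <- isTRUE(tmpl$pav_contingent)

  u <- stats::runif(n)
  pav_cues <- if (is_pav) sample(1:2, n, replace = TRUE) else integer(0)

  cue <- integer(n)
  choice <- integer(n)
  correct <- logical(n)
  reward <- integer(n)
  post <- logical(n)
  qL_tr <- numeric(n)
  qR_tr <- numeric(n)
  v_tr <- numeric(n)

  fc_count <- 0L
  fc_left_21 <- 0L
  rk <- 0L

  for (i in seq_len(n)) {
    tt <- types[i]
    post[i] <- post_active
    if (tt == 1L) {                      # free choice
      x <- beta * (qL - qR)
      pl <- if (x > 35) 1 else if (x < -35) 0 else 1 / (1 + exp(-x))
      ch <- if (u[i] < pl) 1L else 2L
      cue[i] <- 3L
      choice[i] <- ch
      correct[i] <- TRUE
      fc_count <- fc_count + 1L
      if (fc_count <= 21L && ch == 1L) fc_left_21 <- fc_left_21 + 1L
      if (is_risk && ch == risky_code) {
        rk <- rk + 1L
        rw <- risky_draws[rk]
      } else if (is_risk) {
        rw <- 2L
      } else {
        rw <- if (post_active) post_bol[ch] else bol[ch]
      }
      reward[i] <- rw
      q <- if (ch == 1L) qL else qR
      d <- rw - q
      q <- q + (if (d >= 0) alpha_plus else alpha_minus) * d
      if (ch == 1L) qL <- q else qR <- q
      if (is_shift && fc_count == trigger && !post_active) {
        # resolve the shift target and switch the schedule for all
        # subsequent trials
        rule <- tmpl$shift$target_rule
        if (rule == "nonpreferred") {
          preferred <- if (2L * fc_left_21 >= 21L) "left" else "right"
          shifted_side <- other_side(preferred)
          anchor <- shifted_side
        } else if (rule == "anchor") {
          shifted_side <- anchor
        } else {
          shifted_side <- other_side(anchor)
        }
        shift_sess <- make_shift_session(tmpl$shift$kind,
                                         tmpl$shift$direction,
                                         shifted_side, bol_schedule(bol))
        post_sched <- shift_sess$post_shift_schedule
        post_bol <- c(left = constant_boluses(post_sched, "left"),
                      right = constant_boluses(post_sched, "right"))
        post_active <- TRUE
      }
    } else if (tt == 2L || tt == 3L) {   # forced trials
      cs <- tt - 1L                      # 1 = left cue, 2 = right cue
      ok <- u[i] >= lapse
      ch <- if (ok) cs else 3L - cs
      cue[i] <- cs
      choice[i] <- ch
      correct[i] <- ok
      if (ok) {
        if (is_risk && ch == risky_code) {
          rk <- rk + 1L
          rw <- risky_draws[rk]
        } else if (is_risk) {
          rw <- 2L
        } else {
          rw <- if (post_active) post_bol[ch] else bol[ch]
        }
        reward[i] <- rw
        q <- if (ch == 1L) qL else qR
        d <- rw - q
        q <- q + (if (d >= 0) alpha_plus else alpha_minus) * d
        if (ch == 1L) qL <- q else qR <- q
      } else {
        reward[i] <- 0L
        if (update_on_forced_error) {
          # reward omission on the cued side drives a negative update
          q <- if (cs == 1L) qL else qR
          q <- q + alpha_minus * (0 - q)
          if (cs == 1L) qL <- q else qR <- q
        }
      }
    } else {                             # pavlovian cue
      cs <- pav_cues[i]
      p_correct <- 0.5 + 0.5 * v
      ok <- u[i] < p_correct
      cue[i] <- cs
      choice[i] <- if (ok) cs else 3L - cs
      correct[i] <- ok
      reward[i] <- if (!contingent || ok) 2L else 0L
      if (!contingent || ok) {
        v <- v + alpha_pav * (1 - v)
        if (v > 1) v <- 1 else if (v < 0) v <- 0
      }
    }
    qL_tr[i] <- qL
    qR_tr[i] <- qR
    v_tr[i] <- v
  }

  list(
    rec = list(type = types, cue = cue, choice = choice, correct = correct,
               reward = reward, post = post, qL = qL_tr, qR = qR_tr,
               v = v_tr),
    pool = pool, qL = qL, qR = qR, v = v, anchor = anchor,
    shift_kind = if (is_shift) tmpl$shift$kind else NA_character_,
    shift_direction = if (is_shift) tmpl$shift$direction else NA_character_,
    shifted_side = shifted_side,
    shift_trigger = if (is_shift) trigger else NA_integer_,
    risk_condition = if (is_risk) tmpl$risk$condition else NA_character_,
    risky_side = if (is_risk) tmpl$risk$risky_side else NA_character_,
    pre_schedule = format_schedule(pre_sched),
    post_schedule = format_schedule(post_sched)
  )
}

#' Simulate full cohorts of subjects
#'
#' Builds the protocol plan for both cohorts, draws per-subject agent
#' parameters from the group distributions, assigns each subject a child seed
#' from the master seed, and simulates every subject through the full
#' protocol.
#'
#' @param config a cohort configuration, see [default_cohort_config()].
#' @return an object of class `rs_cohort`: a list with `trials` (all
#'   subjects' trial logs), `sessions` (resolved session manifest), `params`
#'   (per-subject sampled parameters and seeds), `plan` and `config`.
#' @export
simulate_cohorts <- function(config = default_cohort_config()) {
  plan <- build_protocol(
    list(n_clh = config$groups$cLH_like$n, n_wt = config$groups$WT_like$n,
         protocol = config$protocol),
    rng_seed = config$seed
  )
  validate_plan(plan)
  n_total <- length(plan$subjects)

  drawn <- with_preserved_seed({
    set.seed(as.integer(config$seed))
    params <- lapply(plan$subjects, function(sub) {
      sample_agent_params(config$groups[[sub$group]]$params)
    })
    child_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    list(params = params, child_seeds = child_seeds)
  })

  runs <- lapply(seq_len(n_total), function(i) {
    simulate_subject(plan$subjects[[i]], drawn$params[[i]],
                     seed = drawn$child_seeds[i],
                     update_on_forced_error =
                       isTRUE(config$update_on_forced_error))
  })

  params_tab <- do.call(rbind, lapply(seq_len(n_total), function(i) {
    p <- drawn$params[[i]]
    data.frame(subject_id = plan$subjects[[i]]$subject_id,
               group = plan$subjects[[i]]$group,
               alpha_plus = p$alpha_plus, alpha_minus = p$alpha_minus,
               beta = p$beta, q_init = p$q_init, alpha_pav = p$alpha_pav,
               v_init = p$v_init, lapse = p$lapse,
               seed = drawn$child_seeds[i], stringsAsFactors = FALSE)
  }))

  structure(
    list(trials = do.call(rbind, lapply(runs, `[[`, "trials")),
         sessions = do.call(rbind, lapply(runs, `[[`, "sessions")),
         params = params_tab, plan = plan, config = config),
    class = "rs_cohort"
  )
}

#' @export
print.rs_cohort <- function(x, ...) {
  cat("<rs_cohort>", nrow(x$params), "subjects,", nrow(x$sessions),
      "sessions,", nrow(x$trials), "trials\n")
  invisible(x)
}

TRIAL_LOG_COLUMNS <- c("subject_id", "group", "phase_label", "session_index",
                       "trial_index", "trial_type", "cue_side", "choice",
                       "correct", "reward_boluses", "schedule_epoch")

#' Read and write trial-log CSV files
#'
#' The trial-log CSV dialect has a fixed header of eleven columns
#' (`subject_id, group, phase_label, session_index, trial_index, trial_type,
#' cue_side, choice, correct, reward_boluses, schedule_epoch`), UTF-8,
#' comma-separated, one row per trial. Agent-internal columns present in
#' simulated logs (`q_left`, `q_right`, `v_pav`) are not written.
#'
#' @param trials a trial-log data.frame.
#' @param path file path.
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns a validated trial-log data.frame.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials[, TRIAL_LOG_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(trials))
  if (length(missing) > 0L) {
    stop("malformed trial log '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  checks <- list(
    trial_type = names(TYPE_CODES),
    cue_side = SIDE_LEVELS,
    choice = c("left", "right"),
    schedule_epoch = c("pre_shift", "post_shift")
  )
  for (col in names(checks)) {
    bad <- which(!(trials[[col]] %in% checks[[col]]))
    if (length(bad) > 0L) {
      stop("malformed trial log '", path, "': row ", bad[1], ", column '",
           col, "': invalid value '", trials[[col]][bad[1]], "'",
           call. = FALSE)
    }
  }
  trials$correct <- as.logical(trials$correct)
  trials
}

#' @rdname write_trial_log
#' @param sessions a session-manifest data.frame as produced by
#'   [simulate_subject()] / [simulate_cohorts()].
#' @export
write_session_manifest <- function(sessions, path) {
  # schedule strings contain commas, so character fields are quoted
  utils::write.csv(sessions, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_session_manifest <- function(path) {
  sessions <- utils::read.csv(path, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8")
  required <- c("subject_id", "group", "session_index", "phase_label",
                "shifted_side", "risk_condition", "risky_side")
  missing <- setdiff(required, names(sessions))
  if (length(missing) > 0L) {
    stop("malformed session manifest '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sessions
}
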