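#' Session specifications and protocol plans
#'
#' A session specification describes one operant session: its phase label, the
#' pool of trial types to interleave, the reward schedule in force at the start
#' of the session, and — for shift sessions — the post-shift schedule and the
#' free-choice count that triggers the switch.
#'
#' @name session_spec
NULL

PHASE_LEVELS <- c("pavlovian", "baseline", "large_upshift", "large_downshift",
                  "discrimination", "small_downshift", "small_upshift",
                  "retrain", "risk_train", "risk_test")

TRIAL_TYPES <- c("free_choice", "forced_left", "forced_right", "pavlovian_cue")

#' Construct a session specification
#'
#' @param phase_label one of `"pavlovian"`, `"baseline"`, `"large_upshift"`,
#'   `"large_downshift"`, `"discrimination"`, `"small_downshift"`,
#'   `"small_upshift"`, `"retrain"`, `"risk_train"`, `"risk_test"`.
#' @param trial_pool named non-negative integer vector with any of the names
#'   `free_choice`, `forced_left`, `forced_right`, `pavlovian_cue`; the session
#'   contains exactly these counts of each type.
#' @param pre_shift_schedule [reward_schedule()] in force from trial 0 (may be
#'   `NULL` for Pavlovian sessions).
#' @param post_shift_schedule schedule in force after the shift trigger fires,
#'   or `NULL` for sessions without a mid-session shift.
#' @param shift_trigger_free_choice_count number of completed free-choice
#'   trials after which the post-shift schedule takes over (`NULL` when there
#'   is no shift).
#' @param risky_side for risk sessions, which port is risky; otherwise `NULL`.
#' @param ... additional metadata fields (e.g. `shift_kind`,
#'   `shift_direction`, `target_side`, `risk_condition`, `pav_contingent`)
#'   stored on the spec.
#' @return an object of class `session_spec`.
#' @export
session_spec <- function(phase_label, trial_pool,
                         pre_shift_schedule = NULL,
                         post_shift_schedule = NULL,
                         shift_trigger_free_choice_count = NULL,
                         risky_side = NULL, ...) {
  phase_label <- match.arg(phase_label, PHASE_LEVELS)
  pool <- stats::setNames(integer(length(TRIAL_TYPES)), TRIAL_TYPES)
  if (is.null(names(trial_pool)) ||
      !all(names(trial_pool) %in% TRIAL_TYPES)) {
    stop("trial_pool must be named with a subset of: ",
         paste(TRIAL_TYPES, collapse = ", "), call. = FALSE)
  }
  pool[names(trial_pool)] <- as.integer(trial_pool)
  if (any(pool < 0L)) stop("trial_pool counts must be non-negative",
                           call. = FALSE)
  if (!is.null(post_shift_schedule) &&
      is.null(shift_trigger_free_choice_count)) {
    stop("a post-shift schedule requires shift_trigger_free_choice_count",
         call. = FALSE)
  }
  if (!is.null(shift_trigger_free_choice_count)) {
    trig <- as.integer(shift_trigger_free_choice_count)
    if (trig < 1L || trig > pool[["free_choice"]]) {
      stop("shift trigger (", trig, ") must be a positive count no larger ",
           "than the free-choice pool (", pool[["free_choice"]], ")",
           call. = FALSE)
    }
  }
  structure(
    c(list(
      phase_label = phase_label,
      trial_pool = pool,
      pre_shift_schedule = pre_shift_schedule,
      post_shift_schedule = post_shift_schedule,
      shift_trigger_free_choice_count =
        if (is.null(shift_trigger_free_choice_count)) NULL
        else as.integer(shift_trigger_free_choice_count),
      risky_side = risky_side
    ), list(...)),
    class = "session_spec"
  )
}

#' @export
print.session_spec <- function(x, ...) {
  pool <- x$trial_pool[x$trial_pool > 0L]
  cat("<session_spec> phase:", x$phase_label, "| trials:",
      sum(x$trial_pool), paste0("(", paste(names(pool), pool, sep = "=",
                                           collapse = ", "), ")"), "\n")
  if (!is.null(x$shift_trigger_free_choice_count)) {
    cat("  shift after", x$shift_trigger_free_choice_count,
        "free-choice trials:", format_schedule(x$pre_shift_schedule), "->",
        format_schedule(x$post_shift_schedule), "\n")
  } else if (!is.null(x$pre_shift_schedule)) {
    cat("  schedule:", format_schedule(x$pre_shift_schedule), "\n")
  }
  invisible(x)
}

total_trials <- function(spec) sum(spec$trial_pool)

#' Build a mid-session reward-shift session
#'
#' Large shifts change the target side from two to four boluses (upshift) or
#' four to one (downshift) over a 180-trial session (60 free-choice, 60
#' forced-left, 60 forced-right). Small shifts change the target side from
#' three to two boluses (downshift) or — with three boluses on the opposite
#' side — from two to four boluses (upshift) over a 240-trial session
#' (80/80/80). In every case the shift fires once 21 free-choice trials (the
#' baseline block) have completed.
#'
#' @param kind `"large"` or `"small"`.
#' @param direction `"up"` or `"down"`.
#' @param target_side the side whose reward size changes.
#' @param base_schedule constant [reward_schedule()] in force before the
#'   shift; its bolus counts must match the requested shift (large up: target
#'   at 2; large down: target at 4; small down: target at 3; small up: target
#'   at 2 with the opposite side at 3).
#' @return a `session_spec` with `shift_trigger_free_choice_count = 21`.
#' @export
make_shift_session <- function(kind = c("large", "small"),
                               direction = c("up", "down"),
                               target_side = c("left", "right"),
                               base_schedule) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  target_side <- match.arg(target_side)
  validate_reward_schedule(base_schedule)
  if (!side_is_constant(base_schedule, "left") ||
      !side_is_constant(base_schedule, "right")) {
    stop("protocol error: shift sessions require a constant base schedule",
         call. = FALSE)
  }
  tgt <- constant_boluses(base_schedule, target_side)
  oth <- constant_boluses(base_schedule, other_side(target_side))
  need <- switch(paste(kind, direction),
    "large up" = list(pre = 2L, post = 4L),
    "large down" = list(pre = 4L, post = 1L),
    "small down" = list(pre = 3L, post = 2L),
    "small up" = list(pre = 2L, post = 4L, other = 3L)
  )
  if (tgt != need$pre) {
    stop("protocol error: a ", kind, " ", direction, "shift requires ",
         need$pre, " boluses on the target side before the shift (got ",
         tgt, ")", call. = FALSE)
  }
  if (!is.null(need$other) && oth != need$other) {
    stop("protocol error: a small upshift requires ", need$other,
         " boluses on the non-target side (got ", oth, ")", call. = FALSE)
  }
  post_args <- list(bolus_volume_ul = base_schedule$bolus_volume_ul)
  post_args[[target_side]] <- need$post
  post_args[[other_side(target_side)]] <- oth
  post <- do.call(reward_schedule, post_args)
  n <- if (kind == "large") 60L else 80L
  session_spec(
    phase_label = paste0(kind, "_", direction, "shift"),
    trial_pool = c(free_choice = n, forced_left = n, forced_right = n),
    pre_shift_schedule = base_schedule,
    post_shift_schedule = post,
    shift_trigger_free_choice_count = 21L,
    shift_kind = kind,
    shift_direction = direction,
    target_side = target_side
  )
}

#' Randomly interleave the trial types of a session
#'
#' Draws a uniformly random permutation of the session's pooled trial types
#' (sampling without replacement), so the per-type totals always equal the
#' pool exactly. Uses the current R random number stream.
#'
#' @param spec a [session_spec()].
#' @return character vector of trial types, one per trial slot.
#' @export
interleave_trials <- function(spec) {
  pool <- spec$trial_pool
  slots <- rep(names(pool), times = pool)
  if (length(slots) <= 1L) return(slots)
  sample(slots)
}

#' Default protocol configuration
#'
#' Returns the configuration of the full behavioral protocol: five Pavlovian
#' conditioning sessions (reward delivery contingent on a correct response
#' from session 3 onward), six baseline lever-pressing sessions, a large
#' upshift / discrimination / large downshift block, two retraining sessions
#' at three boluses, a small downshift, discrimination, small upshift and
#' discrimination block, one retraining session at two boluses, and three
#' risk-aversion conditions of ten sessions each (3 training + 2 test per
#' side assignment, sides swapped once within each condition).
#'
#' @param pavlovian_trials trials per Pavlovian session (the original sessions
#'   were duration-limited; a fixed trial count replaces the 60-minute limit).
#' @param phases named list of logical toggles: `pavlovian`, `baseline`,
#'   `large_shifts`, `small_shifts`, `risk`. Disabled phases are omitted from
#'   the plan (when large shifts are disabled, the small-shift anchor side is
#'   drawn at random per subject).
#' @return a named list of protocol options.
#' @export
default_protocol_config <- function(pavlovian_trials = 60L,
                                    phases = list()) {
  ph <- list(pavlovian = TRUE, baseline = TRUE, large_shifts = TRUE,
             small_shifts = TRUE, risk = TRUE)
  ph[names(phases)] <- phases
  list(
    pavlovian_sessions = 5L,
    pavlovian_trials = as.integer(pavlovian_trials),
    baseline_sessions = 6L,
    standard_pool = c(free_choice = 60L, forced_left = 60L,
                      forced_right = 60L),
    small_pool = c(free_choice = 80L, forced_left = 80L, forced_right = 80L),
    retrain_small_sessions = 2L,
    prerisk_sessions = 1L,
    risk_train_sessions = 3L,
    risk_test_sessions = 2L,
    shift_trigger = 21L,
    phases = ph
  )
}

# A symbolic session template. Side-dependent schedules are expressed through
# roles: "anchor" is the side manipulated during the large shifts (resolved at
# simulation time from the 21-trial baseline preference), "opposite" its
# mirror. `sched` is either c(left=, right=) or c(anchor=, opposite=).
session_template <- function(phase, pool, sched = NULL, shift = NULL,
                             risk = NULL, pav_contingent = NULL,
                             reinit = NULL) {
  list(phase = phase, pool = pool, sched = sched, shift = shift,
       risk = risk, pav_contingent = pav_contingent, reinit = reinit)
}

#' Build the per-subject protocol plan for two cohorts
#'
#' Lays out every subject's ordered session sequence and counterbalances the
#' risk-aversion condition order: within each cohort, half the subjects start
#' with the risky-better condition and half with safe-better (for odd cohort
#' sizes the extra subject is assigned by a seeded draw); the even condition
#' is always run between the other two. Each subject's initial risky side is
#' drawn at random and then alternates with every 5-session block.
#'
#' @param config cohort/protocol options: a list with `n_clh`, `n_wt`
#'   (positive cohort sizes) and optionally `protocol`
#'   (see [default_protocol_config()]).
#' @param rng_seed integer seed; plans are deterministic given seed + config.
#' @return an object of class `protocol_plan`: a list with `subjects` (one
#'   plan per subject: id, group, session templates, risk condition order,
#'   risky-side sequence) and the config snapshot.
#' @export
build_protocol <- function(config = list(n_clh = 11L, n_wt = 13L),
                           rng_seed = 1L) {
  n_clh <- config$n_clh
  n_wt <- config$n_wt
  for (field in c("n_clh", "n_wt")) {
    n <- config[[field]]
    if (is.null(n) || !is.numeric(n) || length(n) != 1L || n < 1L ||
        n != round(n)) {
      stop("configuration error: '", field,
           "' must be a positive integer cohort size", call. = FALSE)
    }
  }
  proto <- config$protocol
  if (is.null(proto)) proto <- default_protocol_config()

  groups <- c(rep("cLH_like", n_clh), rep("WT_like", n_wt))
  ids <- c(sprintf("cLH%02d", seq_len(n_clh)), sprintf("WT%02d", seq_len(n_wt)))

  subjects <- with_preserved_seed({
    set.seed(as.integer(rng_seed))
    first_cond <- c(assign_start_conditions(n_clh),
                    assign_start_conditions(n_wt))
    risky0 <- sample(c("left", "right"), length(ids), replace = TRUE)
    anchor0 <- sample(c("left", "right"), length(ids), replace = TRUE)
    lapply(seq_along(ids), function(i) {
      cond1 <- first_cond[i]
      cond3 <- setdiff(c("risky_better", "safe_better"), cond1)
      list(
        subject_id = ids[i],
        group = groups[i],
        risk_condition_order = c(cond1, "even", cond3),
        initial_risky_side = risky0[i],
        # used only when large shifts are disabled; otherwise resolved
        # from the large-upshift baseline preference at simulation time
        fallback_anchor_side = anchor0[i],
        sessions = subject_sessions(proto, cond_order = c(cond1, "even", cond3),
                                    risky0 = risky0[i])
      )
    })
  })

  structure(list(subjects = subjects, protocol = proto,
                 n_clh = as.integer(n_clh), n_wt = as.integer(n_wt),
                 rng_seed = as.integer(rng_seed)),
            class = "protocol_plan")
}

# Exactly half of a cohort starts with risky_better; the extra subject of an
# odd cohort goes either way by a seeded coin flip. Returned in a seeded
# random order over subjects.
assign_start_conditions <- function(n) {
  half <- n %/% 2L
  conds <- c(rep("risky_better", half), rep("safe_better", half))
  if (n %% 2L == 1L) {
    conds <- c(conds, sample(c("risky_better", "safe_better"), 1L))
  }
  sample(conds)
}

subject_sessions <- function(proto, cond_order, risky0) {
  ph <- proto$phases
  std <- proto$standard_pool
  sml <- proto$small_pool
  sess <- list()
  add <- function(s) sess[[length(sess) + 1L]] <<- s

  if (isTRUE(ph$pavlovian)) {
    for (k in seq_len(proto$pavlovian_sessions)) {
      add(session_template("pavlovian",
                           c(pavlovian_cue = proto$pavlovian_trials),
                           pav_contingent = k >= 3L))
    }
  }
  if (isTRUE(ph$baseline)) {
    for (k in seq_len(proto$baseline_sessions)) {
      add(session_template("baseline", std, sched = c(left = 2, right = 2),
                           reinit = if (k == 1L) c(left = 2, right = 2)))
    }
  }
  if (isTRUE(ph$large_shifts)) {
    # large upshift, its carry-over discrimination session, and the large
    # downshift run as one continuous block (no retraining intervenes)
    add(session_template("large_upshift", std,
                         sched = c(left = 2, right = 2),
                         reinit = c(left = 2, right = 2),
                         shift = list(kind = "large", direction = "up",
                                      target_rule = "nonpreferred")))
    add(session_template("discrimination", std,
                         sched = c(anchor = 4, opposite = 2)))
    add(session_template("large_downshift", std,
                         sched = c(anchor = 4, opposite = 2),
                         shift = list(kind = "large", direction = "down",
                                      target_rule = "anchor")))
  }
  if (isTRUE(ph$small_shifts)) {
    for (k in seq_len(proto$retrain_small_sessions)) {
      add(session_template("retrain", std, sched = c(left = 3, right = 3),
                           reinit = if (k == 1L) c(left = 3, right = 3)))
    }
    add(session_template("small_downshift", sml,
                         sched = c(left = 3, right = 3),
                         reinit = if (proto$retrain_small_sessions == 0L)
                           c(left = 3, right = 3),
                         shift = list(kind = "small", direction = "down",
                                      target_rule = "opposite")))
    add(session_template("discrimination", std,
                         sched = c(anchor = 3, opposite = 2)))
    add(session_template("small_upshift", sml,
                         sched = c(anchor = 3, opposite = 2),
                         shift = list(kind = "small", direction = "up",
                                      target_rule = "opposite")))
    add(session_template("discrimination", std,
                         sched = c(anchor = 3, opposite = 4)))
  }
  if (isTRUE(ph$risk)) {
    for (k in seq_len(proto$prerisk_sessions)) {
      add(session_template("retrain", std, sched = c(left = 2, right = 2),
                           reinit = if (k == 1L) c(left = 2, right = 2)))
    }
    risky <- risky0
    for (cond in cond_order) {
      for (block in 1:2) {
        for (k in seq_len(proto$risk_train_sessions)) {
          add(session_template("risk_train", std,
                               risk = list(condition = cond,
                                           risky_side = risky),
                               reinit = if (k == 1L) c(left = 2, right = 2)))
        }
        for (k in seq_len(proto$risk_test_sessions)) {
          add(session_template("risk_test", std,
                               risk = list(condition = cond,
                                           risky_side = risky)))
        }
        risky <- other_side(risky)
      }
    }
  }
  sess
}

#' @export
print.protocol_plan <- function(x, ...) {
  n <- length(x$subjects)
  cat("<protocol_plan>", n, "subjects (", x$n_clh, "cLH-like,", x$n_wt,
      "WT-like ),", length(x$subjects[[1]]$sessions),
      "sessions per subject\n")
  invisible(x)
}

#' Validate protocol-plan invariants
#'
#' Checks, for every subject: five Pavlovian and six baseline sessions (when
#' those phases are enabled); each risk condition comprises 3 training + 2
#' test sessions per side assignment with the risky side swapped exactly once
#' within the condition; the even condition sits between the other two. Across
#' each cohort, the number of subjects starting with risky-better differs from
#' half the cohort by at most the odd remainder (exactly half for even sizes).
#'
#' @param plan a [build_protocol()] result.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_plan <- function(plan) {
  proto <- plan$protocol
  ph <- proto$phases
  for (sub in plan$subjects) {
    phases <- vapply(sub$sessions, function(s) s$phase, "")
    if (isTRUE(ph$pavlovian) && sum(phases == "pavlovian") != 5L) {
      stop("plan invariant violated: subject ", sub$subject_id,
           " does not have 5 Pavlovian sessions", call. = FALSE)
    }
    if (isTRUE(ph$baseline) && sum(phases == "baseline") != 6L) {
      stop("plan invariant violated: subject ", sub$subject_id,
           " does not have 6 baseline sessions", call. = FALSE)
    }
    if (length(sub$risk_condition_order) != 3L ||
        sub$risk_condition_order[2] != "even") {
      stop("plan invariant violated: subject ", sub$subject_id,
           " risk conditions must run the even condition second",
           call. = FALSE)
    }
    if (isTRUE(ph$risk)) {
      risk <- Filter(function(s) !is.null(s$risk), sub$sessions)
      for (cond in sub$risk_condition_order) {
        cs <- Filter(function(s) s$risk$condition == cond, risk)
        labs <- vapply(cs, function(s) s$phase, "")
        sides <- vapply(cs, function(s) s$risk$risky_side, "")
        per_block <- proto$risk_train_sessions + proto$risk_test_sessions
        ok <- length(cs) == 2L * per_block &&
          identical(labs, rep(c(rep("risk_train", proto$risk_train_sessions),
                                rep("risk_test", proto$risk_test_sessions)),
                              2L)) &&
          length(unique(sides[seq_len(per_block)])) == 1L &&
          length(unique(sides[-seq_len(per_block)])) == 1L &&
          sides[1] != sides[length(sides)]
        if (!ok) {
          stop("plan invariant violated: subject ", sub$subject_id,
               " condition '", cond, "' is not 3 train + 2 test per side ",
               "with one side swap", call. = FALSE)
        }
      }
    }
  }
  for (grp in c("cLH_like", "WT_like")) {
    subs <- Filter(function(s) s$group == grp, plan$subjects)
    n <- length(subs)
    n_rb <- sum(vapply(subs, function(s) s$risk_condition_order[1], "") ==
                  "risky_better")
    if (abs(n_rb - n / 2) > 0.5) {
      stop("plan invariant violated: cohort ", grp, " has ", n_rb, " of ", n,
           " subjects starting with risky_better", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Tabulate a protocol plan
#'
#' One row per subject-session with the phase, trial pool and (symbolic)
#' schedule; suitable for writing as a plain-text manifest.
#'
#' @param plan a [build_protocol()] result.
#' @return a data.frame.
#' @export
plan_manifest <- function(plan) {
  rows <- lapply(plan$subjects, function(sub) {
    data.frame(
      subject_id = sub$subject_id,
      group = sub$group,
      session_index = seq_along(sub$sessions) - 1L,
      phase_label = vapply(sub$sessions, function(s) s$phase, ""),
      n_free = vapply(sub$sessions, function(s)
        as.integer(s$pool["free_choice"] %||% 0L), 0L),
      n_forced_left = vapply(sub$sessions, function(s)
        as.integer(s$pool["forced_left"] %||% 0L), 0L),
      n_forced_right = vapply(sub$sessions, function(s)
        as.integer(s$pool["forced_right"] %||% 0L), 0L),
      n_pavlovian = vapply(sub$sessions, function(s)
        as.integer(s$pool["pavlovian_cue"] %||% 0L), 0L),
      schedule = vapply(sub$sessions, function(s) {
        if (!is.null(s$risk)) {
          paste0("risk:", s$risk$condition, ":risky=", s$risk$risky_side)
        } else if (is.null(s$sched)) {
          "pavlovian"
        } else {
          paste(names(s$sched), s$sched, sep = "=", collapse = ",")
        }
      }, ""),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

# Evaluate expr without disturbing the caller's random number stream.
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}
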