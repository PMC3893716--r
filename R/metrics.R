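#' Block-normalized side preference for a shift session
#'
#' Free-choice trials of a shift session are partitioned into a 21-trial
#' baseline block and subsequent blocks (20/20/19 trials for 80-free-choice
#' small-shift sessions; 20/19 for 60-free-choice large-shift sessions). Raw
#' preference is the fraction of each block's free-choice trials on the
#' shifted side; normalized preference divides each block's raw preference by
#' the baseline block's, so the baseline block is 1 by construction. A subject
#' whose baseline preference for the shifted side is zero cannot be
#' normalized; its normalized values are returned as `NA` with a warning and
#' the subject-block is treated as missing downstream.
#'
#' @param trials trial-log rows; if `session_index` is given the rows are
#'   filtered to that session first, otherwise they must already belong to a
#'   single session.
#' @param shifted_side the side whose reward size changed (`"left"` or
#'   `"right"`).
#' @param session_index optional session to extract from `trials`.
#' @param kind `"auto"` (default; sessions with >= 80 free-choice trials are
#'   small, else large), `"small"` or `"large"`.
#' @return an object of class `block_preference`: a list with `subject_id`,
#'   `shifted_side`, `kind` and `blocks`, a data.frame with columns `block`
#'   (baseline, b1, b2, b3), `n_trials`, `raw` and `normalized`.
#' @export
block_preferences <- function(trials, shifted_side, session_index = NULL,
                              kind = c("auto", "small", "large")) {
  kind <- match.arg(kind)
  stopifnot(shifted_side %in% c("left", "right"))
  if (!is.null(session_index)) {
    trials <- trials[trials$session_index == session_index, , drop = FALSE]
  }
  if (length(unique(trials$subject_id)) != 1L ||
      length(unique(trials$session_index)) != 1L) {
    stop("block_preferences expects trials from a single subject-session",
         call. = FALSE)
  }
  fc <- trials[trials$trial_type == "free_choice", , drop = FALSE]
  fc <- fc[order(fc$trial_index), , drop = FALSE]
  if (kind == "auto") kind <- if (nrow(fc) >= 80L) "small" else "large"
  sizes <- if (kind == "small") c(baseline = 21L, b1 = 20L, b2 = 20L,
                                  b3 = 19L)
           else c(baseline = 21L, b1 = 20L, b2 = 19L)
  if (nrow(fc) < sum(sizes)) {
    stop("session has ", nrow(fc), " free-choice trials; ", sum(sizes),
         " required for ", kind, "-shift block scoring", call. = FALSE)
  }
  idx <- rep(names(sizes), times = sizes)
  on_side <- as.numeric(fc$choice[seq_along(idx)] == shifted_side)
  raw <- as.numeric(tapply(on_side, factor(idx, levels = names(sizes)), mean))
  if (raw[1] > 0) {
    normalized <- raw / raw[1]
  } else {
    warning("baseline preference for the shifted side is 0 for subject ",
            trials$subject_id[1], "; normalized preference undefined",
            call. = FALSE)
    normalized <- rep(NA_real_, length(raw))
  }
  structure(
    list(subject_id = trials$subject_id[1],
         shifted_side = shifted_side,
         kind = kind,
         blocks = data.frame(block = names(sizes), n_trials = unname(sizes),
                             raw = raw, normalized = normalized,
                             stringsAsFactors = FALSE)),
    class = "block_preference"
  )
}

#' @export
print.block_preference <- function(x, ...) {
  cat("<block_preference>", x$subject_id, "|", x$kind, "shift | shifted side:",
      x$shifted_side, "\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

block_value <- function(bp, block, scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  bp$blocks[[scale]][match(block, bp$blocks$block)]
}

#' Learning-bias score from upshift and downshift block preferences
#'
#' The bias contrasts how quickly preference moves toward an upshifted side
#' with how quickly it moves away from a downshifted side. With normalized
#' block preferences (baseline = 1), the upshift delta is the block-1
#' preference change toward the upshifted side, `delta_u = pref_up(b1) - 1`,
#' and the downshift delta is the block-2 preference change away from the
#' downshifted side, `delta_d = 1 - pref_down(b2)`. The score is
#' `bias = delta_u - delta_d`: a subject that switches faster after an upshift
#' than after a downshift scores positive; faster after a downshift, negative.
#' Both deltas are signed (a subject drifting the "wrong" way makes them
#' negative).
#'
#' @param up_pref [block_preferences()] result for the small upshift session.
#' @param down_pref [block_preferences()] result for the small downshift
#'   session of the same subject.
#' @param scale `"normalized"` (default, matching the normalized preference
#'   analysis) or `"raw"`.
#' @return an object of class `bias_score`: list with `subject_id`,
#'   `delta_u`, `delta_d` and `bias` (any of which is `NA` when the
#'   corresponding block data are missing).
#' @export
learning_bias <- function(up_pref, down_pref,
                          scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  if (!identical(up_pref$subject_id, down_pref$subject_id)) {
    stop("up_pref and down_pref belong to different subjects", call. = FALSE)
  }
  delta_u <- block_value(up_pref, "b1", scale) -
    block_value(up_pref, "baseline", scale)
  delta_d <- block_value(down_pref, "baseline", scale) -
    block_value(down_pref, "b2", scale)
  structure(list(subject_id = up_pref$subject_id, delta_u = delta_u,
                 delta_d = delta_d, bias = delta_u - delta_d,
                 scale = scale),
            class = "bias_score")
}

#' @export
print.bias_score <- function(x, ...) {
  cat("<bias_score>", x$subject_id, "| delta_u =", signif(x$delta_u, 4),
      "| delta_d =", signif(x$delta_d, 4), "| bias =", signif(x$bias, 4),
      "(", x$scale, "scale )\n")
  invisible(x)
}

#' Running side preference across a session
#'
#' For each free-choice trial, the fraction of choices on `side` within a
#' centered window of 11 free-choice trials (the trial itself plus the 5
#' before and 5 after). Near the session edges the window is truncated to the
#' available trials (shrinking window), so the series has one value per
#' free-choice trial; truncated positions are flagged.
#'
#' @param trials trial-log rows from a single subject-session.
#' @param side the side whose preference is tracked.
#' @param half_window trials on each side of the center (default 5).
#' @return data.frame with columns `free_choice_index` (1-based among
#'   free-choice trials), `trial_index` (within the session), `preference`,
#'   `window_n` and `truncated`.
#' @export
running_preference <- function(trials, side = c("left", "right"),
                               half_window = 5L) {
  side <- match.arg(side)
  fc <- trials[trials$trial_type == "free_choice", , drop = FALSE]
  fc <- fc[order(fc$trial_index), , drop = FALSE]
  n <- nrow(fc)
  if (n == 0L) {
    return(data.frame(free_choice_index = integer(0),
                      trial_index = integer(0), preference = numeric(0),
                      window_n = integer(0), truncated = logical(0)))
  }
  x <- as.numeric(fc$choice == side)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_window)
  hi <- pmin(n, i + half_window)
  wn <- hi - lo + 1L
  data.frame(
    free_choice_index = i,
    trial_index = fc$trial_index,
    preference = (cs[hi + 1L] - cs[lo]) / wn,
    window_n = wn,
    truncated = wn < 2L * half_window + 1L
  )
}

#' Per-subject risky-choice scores
#'
#' For each risk condition, the risky-choice score is the unweighted mean,
#' over that condition's test sessions, of the session's fraction of
#' free-choice trials on the risky side. `average_risky` is the mean of the
#' three condition scores. A condition with no test sessions in the log is
#' flagged missing (`NA`).
#'
#' @param trials trial-log data.frame (any number of subjects).
#' @param sessions session manifest with `phase_label`, `risk_condition` and
#'   `risky_side` (as produced by [simulate_cohorts()]).
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   condition scores `risky_better`, `even`, `safe_better`, their per-
#'   condition test-session counts, and `average_risky`.
#' @export
risky_choice_scores <- function(trials, sessions) {
  tests <- sessions[sessions$phase_label == "risk_test", , drop = FALSE]
  fc <- trials[trials$trial_type == "free_choice",
               c("subject_id", "session_index", "choice")]
  key <- paste(fc$subject_id, fc$session_index)
  skey <- paste(tests$subject_id, tests$session_index)
  frac <- vapply(seq_len(nrow(tests)), function(i) {
    ch <- fc$choice[key == skey[i]]
    if (length(ch) == 0L) return(NA_real_)
    mean(ch == tests$risky_side[i])
  }, 0)

  subjects <- unique(trials[, c("subject_id", "group")])
  conds <- c("risky_better", "even", "safe_better")
  out <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    row <- list(subject_id = sid, group = subjects$group[i])
    for (cond in conds) {
      sel <- tests$subject_id == sid & tests$risk_condition == cond
      vals <- frac[sel]
      vals <- vals[!is.na(vals)]
      row[[cond]] <- if (length(vals) == 0L) NA_real_ else mean(vals)
      row[[paste0("n_test_", cond)]] <- length(vals)
    }
    row$average_risky <- mean(c(row$risky_better, row$even, row$safe_better))
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pavlovian and forced-choice accuracy per subject
#'
#' Pavlovian accuracy is the fraction of cue trials with a correct first
#' response, per Pavlovian session. Forced-choice accuracy pools the forced
#' trials of the first six baseline sessions (the sessions with equal,
#' constant reward on both sides).
#'
#' @inheritParams risky_choice_scores
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `pav_1` ... `pav_5` (Pavlovian session accuracies, `NA` when the session
#'   is absent) and `forced_accuracy`.
#' @export
accuracy_series <- function(trials) {
  subjects <- unique(trials[, c("subject_id", "group")])
  out <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    tr <- trials[trials$subject_id == sid, , drop = FALSE]
    pav <- tr[tr$phase_label == "pavlovian", , drop = FALSE]
    pav_sessions <- sort(unique(pav$session_index))
    pav_acc <- rep(NA_real_, 5L)
    for (k in seq_along(pav_sessions)) {
      if (k > 5L) break
      pav_acc[k] <- mean(pav$correct[pav$session_index == pav_sessions[k]])
    }
    base <- tr[tr$phase_label == "baseline", , drop = FALSE]
    base_sessions <- sort(unique(base$session_index))
    base_sessions <- base_sessions[seq_len(min(6L, length(base_sessions)))]
    forced <- base[base$session_index %in% base_sessions &
                     base$trial_type %in% c("forced_left", "forced_right"), ,
                   drop = FALSE]
    data.frame(subject_id = sid, group = subjects$group[i],
               pav_1 = pav_acc[1], pav_2 = pav_acc[2], pav_3 = pav_acc[3],
               pav_4 = pav_acc[4], pav_5 = pav_acc[5],
               forced_accuracy = if (nrow(forced) == 0L) NA_real_
                                 else mean(forced$correct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Block preferences for every subject's shift sessions
#'
#' Applies [block_preferences()] to each subject's shift sessions of the
#' requested kind, reading the resolved shifted side from the session
#' manifest.
#'
#' @inheritParams risky_choice_scores
#' @param kind `"small"` (default) or `"large"`.
#' @return long data.frame: `subject_id`, `group`, `shift` (`"up"`/`"down"`),
#'   `block`, `n_trials`, `raw`, `normalized`.
#' @export
shift_block_table <- function(trials, sessions, kind = c("small", "large")) {
  kind <- match.arg(kind)
  shift_sess <- sessions[!is.na(sessions$shift_kind) &
                           sessions$shift_kind == kind, , drop = FALSE]
  if (nrow(shift_sess) == 0L) {
    stop("no ", kind, "-shift sessions found in the session manifest",
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(shift_sess)), function(i) {
    s <- shift_sess[i, ]
    tr <- trials[trials$subject_id == s$subject_id &
                   trials$session_index == s$session_index, , drop = FALSE]
    bp <- suppressWarnings(
      block_preferences(tr, shifted_side = s$shifted_side, kind = kind)
    )
    data.frame(subject_id = s$subject_id, group = s$group,
               shift = s$shift_direction, bp$blocks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Learning-bias scores for every subject
#'
#' Computes [learning_bias()] for each subject from its small upshift and
#' small downshift sessions.
#'
#' @inheritParams risky_choice_scores
#' @param scale `"normalized"` (default) or `"raw"`.
#' @return data.frame: `subject_id`, `group`, `delta_u`, `delta_d`, `bias`.
#' @export
learning_bias_table <- function(trials, sessions,
                                scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  subjects <- unique(sessions[, c("subject_id", "group")])
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    ss <- sessions[sessions$subject_id == sid, , drop = FALSE]
    up <- ss[!is.na(ss$shift_kind) & ss$shift_kind == "small" &
               ss$shift_direction == "up", , drop = FALSE]
    dn <- ss[!is.na(ss$shift_kind) & ss$shift_kind == "small" &
               ss$shift_direction == "down", , drop = FALSE]
    if (nrow(up) != 1L || nrow(dn) != 1L) {
      stop("subject ", sid, " does not have exactly one small upshift and ",
           "one small downshift session", call. = FALSE)
    }
    bp_of <- function(s) {
      tr <- trials[trials$subject_id == sid &
                     trials$session_index == s$session_index, , drop = FALSE]
      suppressWarnings(
        block_preferences(tr, shifted_side = s$shifted_side, kind = "small")
      )
    }
    b <- learning_bias(bp_of(up), bp_of(dn), scale = scale)
    data.frame(subject_id = sid, group = subjects$group[i],
               delta_u = b$delta_u, delta_d = b$delta_d, bias = b$bias,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Preference for the larger reward in discrimination sessions
#'
#' For every discrimination session (a full session with unequal constant
#' rewards), the fraction of free-choice trials on the side delivering the
#' larger reward.
#'
#' @inheritParams risky_choice_scores
#' @return data.frame: `subject_id`, `group`, `disc_index` (1-based order of
#'   the subject's discrimination sessions), `session_index`, `big_side`,
#'   `preference`.
#' @export
discrimination_preferences <- function(trials, sessions) {
  disc <- sessions[sessions$phase_label == "discrimination", , drop = FALSE]
  if (nrow(disc) == 0L) {
    return(data.frame(subject_id = character(0), group = character(0),
                      disc_index = integer(0), session_index = integer(0),
                      big_side = character(0), preference = numeric(0)))
  }
  disc <- disc[order(disc$subject_id, disc$session_index), , drop = FALSE]
  rows <- lapply(seq_len(nrow(disc)), function(i) {
    s <- disc[i, ]
    sched <- parse_schedule(s$pre_schedule)
    bl <- constant_boluses(sched, "left")
    br <- constant_boluses(sched, "right")
    big <- if (bl >= br) "left" else "right"
    tr <- trials[trials$subject_id == s$subject_id &
                   trials$session_index == s$session_index &
                   trials$trial_type == "free_choice", , drop = FALSE]
    data.frame(subject_id = s$subject_id, group = s$group,
               session_index = s$session_index, big_side = big,
               preference = mean(tr$choice == big),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$disc_index <- stats::ave(seq_len(nrow(out)), out$subject_id,
                               FUN = seq_along)
  rownames(out) <- NULL
  out[, c("subject_id", "group", "disc_index", "session_index", "big_side",
          "preference")]
}
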