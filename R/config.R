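#' Read a cohort/protocol configuration from a YAML file
#'
#' The file may set any of: `n_clh`, `n_wt`, `seed`, `pavlovian_trials`,
#' `phases` (named logical toggles, see [default_protocol_config()]),
#' `update_on_forced_error`, and `groups` — a mapping from group name
#' (`cLH_like`, `WT_like`) to parameter overrides, each a `{mean, sd}`
#' mapping per agent parameter. Unset fields keep their defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return a cohort configuration list (see [default_cohort_config()]).
#' @export
read_config <- function(path = NULL) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  cohort_config_from_list(y)
}

cohort_config_from_list <- function(y) {
  proto <- default_protocol_config(
    pavlovian_trials = y$pavlovian_trials %||% 60L,
    phases = y$phases %||% list()
  )
  cfg <- default_cohort_config(
    n_clh = y$n_clh %||% 11L,
    n_wt = y$n_wt %||% 13L,
    seed = y$seed %||% 20140116L,
    protocol = proto
  )
  if (!is.null(y$update_on_forced_error)) {
    cfg$update_on_forced_error <- isTRUE(y$update_on_forced_error)
  }
  for (grp in names(y$groups)) {
    if (!grp %in% names(cfg$groups)) {
      stop("configuration error: unknown group '", grp,
           "' (expected cLH_like or WT_like)", call. = FALSE)
    }
    g <- y$groups[[grp]]
    if (!is.null(g$n)) cfg$groups[[grp]]$n <- as.integer(g$n)
    for (nm in setdiff(names(g), "n")) {
      if (!nm %in% names(cfg$groups[[grp]]$params)) {
        stop("configuration error: unknown agent parameter '", nm,
             "' in group '", grp, "'", call. = FALSE)
      }
      ov <- g[[nm]]
      cur <- cfg$groups[[grp]]$params[[nm]]
      if (!is.null(ov$mean)) cur[["mean"]] <- as.numeric(ov$mean)
      if (!is.null(ov$sd)) cur[["sd"]] <- as.numeric(ov$sd)
      cfg$groups[[grp]]$params[[nm]] <- cur
    }
  }
  cfg
}

#' A small hand-constructed example trial log
#'
#' One deterministic subject whose metric values are known by hand count,
#' used as a worked example and as a test fixture. The log contains: a
#' Pavlovian session with 45/60 correct (accuracy 0.75); a baseline session
#' with 54/60 correct forced trials (accuracy 0.9); a small downshift session
#' (shifted side left) whose free choices land 14/21, 10/20, 8/20, 5/19 on
#' the shifted side across the baseline/b1/b2/b3 blocks (normalized 1, 0.75,
#' 0.6, 15/38); a small upshift session (shifted side right) landing 7/21,
#' 10/20, 12/20, 12/19 (normalized 1, 1.5, 1.8, 36/19 x 1/2); and four even-
#' condition risk test sessions with risky-side fractions 0.2, 0.4, 0.6 and
#' 0.8 (condition score 0.5). The learning bias is therefore
#' delta_u - delta_d = 0.5 - 0.4 = 0.1.
#'
#' @return list with `trials` and `sessions` data.frames.
#' @export
example_log <- function() {
  sid <- "EX01"
  grp <- "WT_like"

  block_choices <- function(n_on, sizes, side, other) {
    # within each block, the first n_on trials go to `side`
    unlist(mapply(function(k, n) c(rep(side, k), rep(other, n - k)),
                  n_on, sizes, SIMPLIFY = FALSE), use.names = FALSE)
  }

  fc_session <- function(session_index, phase, choices) {
    data.frame(
      subject_id = sid, group = grp, phase_label = phase,
      session_index = session_index,
      trial_index = seq_along(choices) - 1L,
      trial_type = "free_choice", cue_side = "both", choice = choices,
      correct = TRUE, reward_boluses = 2L, schedule_epoch = c(
        rep("pre_shift", 21L), rep("post_shift", length(choices) - 21L)),
      stringsAsFactors = FALSE
    )
  }

  pav <- data.frame(
    subject_id = sid, group = grp, phase_label = "pavlovian",
    session_index = 0L, trial_index = 0:59,
    trial_type = "pavlovian_cue",
    cue_side = rep(c("left", "right"), 30L),
    choice = c(rep(c("left", "right"), 22L), rep(c("right", "left"), 8L))[1:60],
    correct = rep(c(TRUE, FALSE), c(45L, 15L)),
    reward_boluses = 2L, schedule_epoch = "pre_shift",
    stringsAsFactors = FALSE
  )
  pav$choice <- ifelse(pav$correct, pav$cue_side,
                       ifelse(pav$cue_side == "left", "right", "left"))

  base <- data.frame(
    subject_id = sid, group = grp, phase_label = "baseline",
    session_index = 1L, trial_index = 0:59,
    trial_type = rep(c("forced_left", "forced_right"), 30L),
    cue_side = rep(c("left", "right"), 30L),
    correct = rep(c(TRUE, FALSE), c(54L, 6L)),
    schedule_epoch = "pre_shift",
    stringsAsFactors = FALSE
  )
  base$choice <- ifelse(base$correct, base$cue_side,
                        ifelse(base$cue_side == "left", "right", "left"))
  base$reward_boluses <- ifelse(base$correct, 2L, 0L)
  base <- base[, names(pav)]

  down <- fc_session(2L, "small_downshift",
                     block_choices(c(14L, 10L, 8L, 5L), c(21L, 20L, 20L, 19L),
                                   "left", "right"))
  up <- fc_session(3L, "small_upshift",
                   block_choices(c(7L, 10L, 12L, 12L), c(21L, 20L, 20L, 19L),
                                 "right", "left"))

  risk_fracs <- c(0.2, 0.4, 0.6, 0.8)
  risk <- do.call(rbind, lapply(seq_along(risk_fracs), function(k) {
    choices <- c(rep("left", risk_fracs[k] * 10L),
                 rep("right", 10L - risk_fracs[k] * 10L))
    data.frame(
      subject_id = sid, group = grp, phase_label = "risk_test",
      session_index = 3L + k, trial_index = 0:9,
      trial_type = "free_choice", cue_side = "both", choice = choices,
      correct = TRUE, reward_boluses = 2L, schedule_epoch = "pre_shift",
      stringsAsFactors = FALSE
    )
  }))

  trials <- rbind(pav, base, down, up, risk)

  sessions <- data.frame(
    subject_id = sid, group = grp, session_index = 0:7,
    phase_label = c("pavlovian", "baseline", "small_downshift",
                    "small_upshift", rep("risk_test", 4L)),
    n_free = c(0L, 0L, 80L, 80L, rep(10L, 4L)),
    n_forced_left = c(0L, 30L, 0L, 0L, rep(0L, 4L)),
    n_forced_right = c(0L, 30L, 0L, 0L, rep(0L, 4L)),
    n_pavlovian = c(60L, rep(0L, 7L)),
    shift_kind = c(NA, NA, "small", "small", rep(NA, 4L)),
    shift_direction = c(NA, NA, "down", "up", rep(NA, 4L)),
    shifted_side = c(NA, NA, "left", "right", rep(NA, 4L)),
    shift_trigger = c(NA, NA, 21L, 21L, rep(NA, 4L)),
    risk_condition = c(rep(NA, 4L), rep("even", 4L)),
    risky_side = c(rep(NA, 4L), rep("left", 4L)),
    pre_schedule = c(NA, "L:2@1|R:2@1", "L:3@1|R:3@1", "L:3@1|R:2@1",
                     rep("L:1@0.833333333333,7@0.166666666667|R:2@1", 4L)),
    post_schedule = c(NA, NA, "L:2@1|R:3@1", "L:3@1|R:4@1", rep(NA, 4L)),
    stringsAsFactors = FALSE
  )

  list(trials = trials, sessions = sessions)
}
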