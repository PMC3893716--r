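#' Reward schedules for a two-port operant chamber
#'
#' A reward schedule gives, for each response port (left, right), a discrete
#' probability distribution over bolus counts. Constant schedules (one outcome
#' per side) describe baseline, shift and discrimination sessions; two-outcome
#' schedules describe the risky side of risk sessions.
#'
#' @param left,right outcomes for one side: either a single positive integer
#'   (a constant schedule delivering that many boluses with probability 1) or
#'   a two-column structure (`boluses`, `prob`) coercible to a data.frame.
#' @param bolus_volume_ul nominal bolus volume in microliters; informational
#'   only (it never enters any computation).
#' @return an object of class `reward_schedule`: a list with elements `left`,
#'   `right` (data.frames with columns `boluses`, `prob`) and
#'   `bolus_volume_ul`.
#' @examples
#' reward_schedule(2, 2)                       # constant 2 boluses both sides
#' reward_schedule(list(boluses = c(1, 7), prob = c(0.75, 0.25)), 2)
#' @export
reward_schedule <- function(left, right, bolus_volume_ul = 20) {
  sched <- structure(
    list(
      left = as_side_outcomes(left, "left"),
      right = as_side_outcomes(right, "right"),
      bolus_volume_ul = bolus_volume_ul
    ),
    class = "reward_schedule"
  )
  validate_reward_schedule(sched)
  sched
}

as_side_outcomes <- function(x, side) {
  if (is.numeric(x) && length(x) == 1L) {
    out <- data.frame(boluses = as.integer(x), prob = 1)
  } else {
    out <- as.data.frame(x)
    if (!all(c("boluses", "prob") %in% names(out))) {
      stop("outcomes for side '", side,
           "' must have fields 'boluses' and 'prob'", call. = FALSE)
    }
    out <- out[, c("boluses", "prob")]
    out$boluses <- as.integer(out$boluses)
  }
  out
}

validate_reward_schedule <- function(x) {
  for (side in c("left", "right")) {
    o <- x[[side]]
    if (nrow(o) < 1L) {
      stop("schedule side '", side, "' has no outcomes", call. = FALSE)
    }
    if (any(o$boluses < 1L)) {
      stop("schedule side '", side, "' has bolus counts < 1", call. = FALSE)
    }
    if (any(o$prob < 0) || abs(sum(o$prob) - 1) > 1e-12) {
      stop("schedule side '", side, "' probabilities must be non-negative ",
           "and sum to 1 (got ", format(sum(o$prob), digits = 15), ")",
           call. = FALSE)
    }
  }
  if (!is.numeric(x$bolus_volume_ul) || x$bolus_volume_ul <= 0) {
    stop("bolus_volume_ul must be a positive number", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.reward_schedule <- function(x, ...) {
  cat("<reward_schedule> (bolus volume", x$bolus_volume_ul, "ul)\n")
  for (side in c("left", "right")) {
    o <- x[[side]]
    cat(" ", side, ": ",
        paste0(o$boluses, " bolus @ ", signif(o$prob, 6), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Expected bolus count on one side of a schedule
#'
#' @param schedule a [reward_schedule()].
#' @param side `"left"` or `"right"`.
#' @return expected number of boluses delivered per rewarded response.
#' @export
schedule_mean <- function(schedule, side = c("left", "right")) {
  side <- match.arg(side)
  o <- schedule[[side]]
  sum(o$boluses * o$prob)
}

#' Draw rewards from one side of a schedule
#'
#' Samples bolus counts using the current R random number stream (seed with
#' [set.seed()] for reproducibility).
#'
#' @inheritParams schedule_mean
#' @param n number of draws.
#' @return integer vector of bolus counts of length `n`.
#' @export
draw_reward <- function(schedule, side = c("left", "right"), n = 1L) {
  side <- match.arg(side)
  o <- schedule[[side]]
  if (nrow(o) == 1L) {
    return(rep.int(o$boluses, n))
  }
  sample(o$boluses, size = n, replace = TRUE, prob = o$prob)
}

side_is_constant <- function(schedule, side) {
  nrow(schedule[[side]]) == 1L
}

constant_boluses <- function(schedule, side) {
  o <- schedule[[side]]
  if (nrow(o) != 1L) return(NA_integer_)
  o$boluses
}

other_side <- function(side) {
  if (side == "left") "right" else "left"
}

#' Build the reward schedule for a risk-aversion condition
#'
#' The safe side always delivers two boluses. The risky side delivers one or
#' seven boluses; the mixing probability sets whether the risky side is better
#' than, equal to, or worse than the safe side in expectation:
#' risky-better = 1 bolus 75% / 7 boluses 25% (mean 2.5), even = 5/6 and 1/6
#' (mean 2 exactly), safe-better = 90% / 10% (mean 1.6).
#'
#' @param condition `"risky_better"`, `"even"` or `"safe_better"`.
#' @param risky_side which port carries the variable reward.
#' @return a [reward_schedule()].
#' @export
make_risk_schedule <- function(condition = c("risky_better", "even", "safe_better"),
                               risky_side = c("left", "right")) {
  condition <- match.arg(condition)
  risky_side <- match.arg(risky_side)
  p7 <- switch(condition,
    risky_better = 0.25,
    even = 1 / 6,
    safe_better = 0.10
  )
  risky <- data.frame(boluses = c(1L, 7L), prob = c(1 - p7, p7))
  args <- list(bolus_volume_ul = 20)
  args[[risky_side]] <- risky
  args[[other_side(risky_side)]] <- 2
  do.call(reward_schedule, args)
}

# Compact single-string serialization used in the session manifest,
# e.g. "L:2@1|R:1@0.75,7@0.25".
format_schedule <- function(schedule) {
  if (is.null(schedule)) return(NA_character_)
  fmt <- function(side, tag) {
    o <- schedule[[side]]
    paste0(tag, ":", paste0(o$boluses, "@", format(o$prob, digits = 12,
                                                   trim = TRUE),
                            collapse = ","))
  }
  paste(fmt("left", "L"), fmt("right", "R"), sep = "|")
}

parse_schedule <- function(s) {
  if (is.na(s)) return(NULL)
  parts <- strsplit(s, "|", fixed = TRUE)[[1]]
  out <- list(bolus_volume_ul = 20)
  for (p in parts) {
    tag <- sub(":.*", "", p)
    side <- if (tag == "L") "left" else "right"
    items <- strsplit(sub("^[LR]:", "", p), ",", fixed = TRUE)[[1]]
    bol <- as.integer(sub("@.*", "", items))
    prob <- as.numeric(sub(".*@", "", items))
    out[[side]] <- data.frame(boluses = bol, prob = prob / sum(prob))
  }
  do.call(reward_schedule, out)
}
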