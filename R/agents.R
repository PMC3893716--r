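#' Asymmetric-learning-rate agent parameters
#'
#' The agent is a delta-rule action-value learner with separate learning rates
#' for positive and negative reward prediction errors, a softmax choice rule
#' on free-choice trials, a fixed lapse rate on forced trials, and a
#' Rescorla-Wagner-style associative strength for Pavlovian cue responding.
#' Values are in bolus units throughout. An agent whose negative-error rate
#' exceeds its positive-error rate underweights rare large payoffs and so
#' avoids variable ("risky") rewards even when utilities are linear in reward
#' size: risk sensitivity emerges from the learning asymmetry alone.
#'
#' @param alpha_plus learning rate in (0, 1] applied when the prediction error
#'   is >= 0.
#' @param alpha_minus learning rate in (0, 1] applied when the prediction
#'   error is < 0.
#' @param beta softmax inverse temperature (>= 0), per bolus of action-value
#'   difference.
#' @param q_init initial action value (boluses).
#' @param alpha_pav Pavlovian association learning rate in (0, 1].
#' @param v_init initial Pavlovian associative strength in [0, 1].
#' @param lapse forced-trial error floor in [0, 0.5]: the probability of
#'   responding to the wrong port on a forced (or the asymptotic error on a
#'   Pavlovian) trial.
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(alpha_plus = 0.15, alpha_minus = 0.15, beta = 1.5,
                         q_init = 2, alpha_pav = 0.10, v_init = 0,
                         lapse = 0.10) {
  p <- structure(list(alpha_plus = alpha_plus, alpha_minus = alpha_minus,
                      beta = beta, q_init = q_init, alpha_pav = alpha_pav,
                      v_init = v_init, lapse = lapse),
                 class = "agent_params")
  validate_agent_params(p)
  p
}

validate_agent_params <- function(p) {
  chk <- function(name, lo, hi, lo_open = FALSE) {
    x <- p[[name]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (if (lo_open) x <= lo else x < lo) || x > hi) {
      stop("agent parameter '", name, "' must lie in ",
           if (lo_open) "(" else "[", lo, ", ", hi, "]", call. = FALSE)
    }
  }
  chk("alpha_plus", 0, 1, lo_open = TRUE)
  chk("alpha_minus", 0, 1, lo_open = TRUE)
  chk("alpha_pav", 0, 1, lo_open = TRUE)
  chk("beta", 0, Inf)
  chk("v_init", 0, 1)
  chk("lapse", 0, 0.5)
  if (!is.numeric(p$q_init) || length(p$q_init) != 1L || is.na(p$q_init)) {
    stop("agent parameter 'q_init' must be a number", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params> a+ =", x$alpha_plus, "| a- =", x$alpha_minus,
      "| beta =", x$beta, "| q0 =", x$q_init, "| a_pav =", x$alpha_pav,
      "| v0 =", x$v_init, "| lapse =", x$lapse, "\n")
  invisible(x)
}

#' Initial agent state
#'
#' @param params an [agent_params()] object.
#' @return list with action values `q` (named `left`, `right`) and Pavlovian
#'   associative strength `v_pav`.
#' @export
agent_state <- function(params) {
  list(q = c(left = params$q_init, right = params$q_init),
       v_pav = params$v_init)
}

#' Delta-rule action-value update with asymmetric learning rates
#'
#' Computes the prediction error `delta = reward - Q[chosen]` and moves the
#' chosen side's value by `alpha_plus * delta` when `delta >= 0` and by
#' `alpha_minus * delta` otherwise. The unchosen value is untouched.
#'
#' @param state an [agent_state()].
#' @param chosen_side `"left"` or `"right"`.
#' @param reward_boluses obtained reward (boluses).
#' @param params an [agent_params()].
#' @return the updated state.
#' @export
q_update <- function(state, chosen_side, reward_boluses, params) {
  stopifnot(chosen_side %in% c("left", "right"))
  q <- state$q[[chosen_side]]
  delta <- reward_boluses - q
  alpha <- if (delta >= 0) params$alpha_plus else params$alpha_minus
  state$q[[chosen_side]] <- q + alpha * delta
  state
}

#' Softmax probability of choosing the left port
#'
#' `P(left) = 1 / (1 + exp(-beta * (Q_left - Q_right)))`, saturating to 0/1
#' for large value differences.
#'
#' @inheritParams q_update
#' @return probability in [0, 1].
#' @export
p_choose_left <- function(state, params) {
  softmax_left(params$beta * (state$q[["left"]] - state$q[["right"]]))
}

softmax_left <- function(x) {
  if (x > 35) return(1)
  if (x < -35) return(0)
  1 / (1 + exp(-x))
}

#' Sample a free-choice response
#'
#' Draws a side from the softmax choice rule using the current R random
#' number stream.
#'
#' @inheritParams q_update
#' @return `"left"` or `"right"`.
#' @export
choose_free <- function(state, params) {
  if (stats::runif(1) < p_choose_left(state, params)) "left" else "right"
}

#' Sample a forced-trial response
#'
#' The agent responds to the cued port with probability `1 - lapse`; a lapse
#' is a response to the opposite port, scored as an error (no reward).
#'
#' @inheritParams q_update
#' @param cue_side the cued port, `"left"` or `"right"`.
#' @return list with `choice` and logical `correct`.
#' @export
respond_forced <- function(state, params, cue_side) {
  stopifnot(cue_side %in% c("left", "right"))
  correct <- stats::runif(1) >= params$lapse
  list(choice = if (correct) cue_side else other_side(cue_side),
       correct = correct)
}

#' Sample a Pavlovian cue response and update the cue association
#'
#' Response accuracy tracks the associative strength:
#' `P(correct) = 0.5 + 0.5 * v_pav`, i.e. chance at `v_pav = 0` and perfect at
#' `v_pav = 1`. In non-contingent sessions (sessions 1-2, where reward is
#' eventually obtained regardless of the first response) the association
#' updates after every trial; in contingent sessions (3-5) only after correct
#' trials. The update is `v_pav <- v_pav + alpha_pav * (1 - v_pav)`, clipped
#' to [0, 1].
#'
#' @inheritParams respond_forced
#' @param contingent logical; whether reward requires a correct first response.
#' @return list with `choice`, logical `correct`, and the updated `state`.
#' @export
respond_pavlovian <- function(state, params, cue_side, contingent = FALSE) {
  stopifnot(cue_side %in% c("left", "right"))
  p_correct <- 0.5 + 0.5 * state$v_pav
  correct <- stats::runif(1) < p_correct
  if (!contingent || correct) {
    state$v_pav <- min(1, max(0, state$v_pav +
                                params$alpha_pav * (1 - state$v_pav)))
  }
  list(choice = if (correct) cue_side else other_side(cue_side),
       correct = correct, state = state)
}

#' Default cohort configuration
#'
#' Two simulated cohorts stand in for the rat groups: 11 "cLH-like" subjects
#' whose learning rate for negative prediction errors exceeds the rate for
#' positive errors (a negative learning bias), and 13 "WT-like" subjects with
#' symmetric rates. The cLH-like group also acquires the Pavlovian association
#' more slowly (smaller `alpha_pav`) and lapses less on forced trials (smaller
#' `lapse`), mirroring the observed group differences in conditioning speed
#' and forced-choice accuracy. Per-subject parameters are drawn from normal
#' distributions (mean, sd per field) and clipped to their legal ranges; these
#' defaults are calibration choices for the simulator, not estimates from any
#' animal.
#'
#' @param n_clh,n_wt cohort sizes.
#' @param seed master seed; per-subject simulation seeds and parameter draws
#'   derive from it.
#' @param protocol protocol options, see [default_protocol_config()].
#' @return a named list: `groups` (per-group `n` and parameter mean/sd lists),
#'   `seed`, `protocol`, `update_on_forced_error`.
#' @export
default_cohort_config <- function(n_clh = 11L, n_wt = 13L, seed = 20140116L,
                                  protocol = default_protocol_config()) {
  list(
    groups = list(
      cLH_like = list(
        n = as.integer(n_clh),
        params = list(
          alpha_plus = c(mean = 0.002, sd = 0.001),
          alpha_minus = c(mean = 0.18, sd = 0.03),
          beta = c(mean = 1.0, sd = 0.08),
          q_init = c(mean = 2, sd = 0),
          alpha_pav = c(mean = 0.005, sd = 0.002),
          v_init = c(mean = 0, sd = 0),
          lapse = c(mean = 0.05, sd = 0.02)
        )
      ),
      WT_like = list(
        n = as.integer(n_wt),
        params = list(
          alpha_plus = c(mean = 0.065, sd = 0.005),
          alpha_minus = c(mean = 0.012, sd = 0.003),
          beta = c(mean = 1.0, sd = 0.08),
          q_init = c(mean = 2, sd = 0),
          alpha_pav = c(mean = 0.015, sd = 0.005),
          v_init = c(mean = 0, sd = 0),
          lapse = c(mean = 0.12, sd = 0.03)
        )
      )
    ),
    seed = as.integer(seed),
    protocol = protocol,
    update_on_forced_error = FALSE
  )
}

# Legal ranges used when sampling per-subject parameters.
PARAM_RANGES <- list(
  alpha_plus = c(1e-4, 1), alpha_minus = c(1e-4, 1), beta = c(0, 50),
  q_init = c(-10, 10), alpha_pav = c(1e-4, 1), v_init = c(0, 1),
  lapse = c(0, 0.5)
)

sample_agent_params <- function(spec) {
  vals <- lapply(names(PARAM_RANGES), function(nm) {
    ms <- spec[[nm]]
    if (is.null(ms)) stop("cohort config missing parameter '", nm, "'",
                          call. = FALSE)
    if (any(ms["sd"] < 0)) stop("configuration error: negative sd for '",
                                nm, "'", call. = FALSE)
    x <- stats::rnorm(1, ms[["mean"]], ms[["sd"]])
    rng <- PARAM_RANGES[[nm]]
    min(rng[2], max(rng[1], x))
  })
  names(vals) <- names(PARAM_RANGES)
  do.call(agent_params, vals)
}
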