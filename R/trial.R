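#' Simulate one trial of the board-ball task
#'
#' Runs the trial state machine at the sampling rate `1/dt`: the ball
#' starts at rest at the center of the start target and is released at
#' trial onset; the dyad's control policy is queried every step; the trial
#' succeeds at the first sample where the ball's continuous in-target dwell
#' reaches `hold_duration`, fails if the ball reaches the board edge
#' (`|x_ball| > l`), and times out at `max_duration`.
#'
#' Completion time is the time from onset until the hold criterion is first
#' satisfied, so it includes the final hold itself.
#'
#' @param policy a function `function(obs) -> hand_input()`-like list with
#'   elements `z_L`, `z_R`, `z_L_dot`, `z_R_dot`. `obs` is a list with
#'   elements `t`, `state` (the current [board_ball_state()], as visible on
#'   screen), `FB_L`, `FB_R` (haptic feedback rendered at the previous
#'   step), `goal_x`, `config`, `params`. Policies may keep internal state
#'   in their closure.
#' @param condition a [haptic_condition()].
#' @param config a [trial_config()].
#' @param params a [model_params()].
#' @param start_side which target the ball starts on (`"left"` or
#'   `"right"`); the goal is the opposite target.
#' @param seed optional integer seed set before the run (for stochastic
#'   policies).
#' @param metadata named list merged into the recording metadata (dyad id,
#'   block index, trial index, ...).
#' @return A `bb_recording`: a data.frame with channels `t, z_L, z_R, F_L,
#'   F_R, FB_L, FB_R, z_board, theta, x_ball` sampled at `1/dt` Hz, with
#'   trial metadata in `attr(, "meta")`.
#' @export
simulate_trial <- function(policy, condition, config = trial_config(),
                           params = model_params(),
                           start_side = c("left", "right"), seed = NULL,
                           metadata = list()) {
  start_side <- match.arg(start_side)
  check_targets_on_board(config, params)
  if (!is.null(seed)) set.seed(seed)
  dt <- params$dt
  start_x <- if (start_side == "left") config$target_positions[1] else
    config$target_positions[2]
  goal_x <- if (start_side == "left") config$target_positions[2] else
    config$target_positions[1]

  # board starts at its rest height under slack hands at z = 0
  z0 <- -(params$M + params$m) * params$g / (2 * params$k_h + params$k_s)
  state <- board_ball_state(z_board = z0, x_ball = start_x)

  n_max <- floor(config$max_duration / dt) + 1L
  hold_n <- ceiling(config$hold_duration / dt - 1e-9)
  ch <- matrix(NA_real_, n_max, 10L,
               dimnames = list(NULL, c("t", "z_L", "z_R", "F_L", "F_R",
                                       "FB_L", "FB_R", "z_board", "theta",
                                       "x_ball")))
  fb <- c(0, 0)
  dwell <- 0L
  outcome <- "failure"; reason <- "timeout"; completion_time <- NA_real_
  n_used <- n_max
  for (i in seq_len(n_max)) {
    t <- (i - 1L) * dt
    hands <- policy(list(t = t, state = state, FB_L = fb[1], FB_R = fb[2],
                         goal_x = goal_x, config = config, params = params))
    F <- hand_forces(hands, state, params)
    F_s <- spring_force(state, params)
    fb <- feedback_forces(F[1], F[2], F_s, condition, t)
    ch[i, ] <- c(t, hands$z_L, hands$z_R, F[1], F[2], fb[1], fb[2],
                 state$z_board, state$theta, state$x_ball)
    if (abs(state$x_ball) > params$l) {
      outcome <- "failure"; reason <- "rolloff"; n_used <- i
      break
    }
    dwell <- if (abs(state$x_ball - goal_x) <= config$target_half_width)
      dwell + 1L else 0L
    if (dwell >= hold_n) {
      outcome <- "success"; reason <- NA_character_
      completion_time <- t; n_used <- i
      break
    }
    state <- step_dynamics(state, F[1], F[2], params)
  }
  rec <- as.data.frame(ch[seq_len(n_used), , drop = FALSE])
  meta <- utils::modifyList(
    list(dyad = NA, pairing = "dyadic", condition = condition$label,
         block = NA, trial = NA, start_side = start_side,
         outcome = outcome, failure_reason = reason,
         completion_time = completion_time, seed = seed,
         params = unclass(params)),
    metadata)
  new_recording(rec, meta)
}

new_recording <- function(df, meta) {
  structure(df, meta = meta, class = c("bb_recording", "data.frame"))
}

#' Trial metadata of a recording
#' @param rec a `bb_recording`.
#' @return the metadata list.
#' @export
rec_meta <- function(rec) attr(rec, "meta")

#' @export
print.bb_recording <- function(x, ...) {
  m <- rec_meta(x)
  if (is.null(m) || is.null(m$params)) {   # e.g. after subsetting
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat(sprintf(
    "Board-ball trial recording: %d samples (%.3f s), condition %s, outcome %s\n",
    nrow(x), nrow(x) * m$params$dt, m$condition, m$outcome))
  if (isTRUE(is.finite(m$completion_time)))
    cat(sprintf("  completion time %.3f s\n", m$completion_time))
  cat(sprintf("  dyad %s, block %s, trial %s, start side %s\n",
              as.character(m$dyad), as.character(m$block),
              as.character(m$trial), m$start_side))
  invisible(x)
}

#' Success/failure events of a ball-position stream
#'
#' Post-hoc event detector over a uniformly sampled ball-position series:
#' emits target enter/exit events, a `success` event at the first sample
#' where the continuous in-target dwell reaches `hold_duration` (boundary
#' inclusive), and a `failure` event at the first sample where the ball is
#' beyond the board edge. Failure takes precedence: samples after a failure
#' are not considered, and a failure fires even if the ball was previously
#' inside the target.
#'
#' @param x_ball ball-position series (m).
#' @param goal_x goal target center (m).
#' @param config a [trial_config()].
#' @param params a [model_params()] (for `l` and `dt`).
#' @return list with `events` (data.frame: sample, time, event), `outcome`
#'   (`"success"`, `"failure"` or `"none"`), `success_sample`,
#'   `failure_sample`.
#' @export
trial_success_monitor <- function(x_ball, goal_x, config = trial_config(),
                                  params = model_params()) {
  dt <- params$dt
  n <- length(x_ball)
  fail <- which(abs(x_ball) > params$l)
  failure_sample <- if (length(fail)) fail[1] else NA_integer_
  last <- if (is.na(failure_sample)) n else failure_sample
  in_t <- abs(x_ball[seq_len(last)] - goal_x) <= config$target_half_width
  if (!is.na(failure_sample)) in_t[failure_sample] <- FALSE
  hold_n <- ceiling(config$hold_duration / dt - 1e-9)

  r <- rle(in_t)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(sample = integer(), event = character())
  success_sample <- NA_integer_
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    ev <- rbind(ev, data.frame(sample = starts[k], event = "enter"))
    if (is.na(success_sample) && r$lengths[k] >= hold_n) {
      success_sample <- starts[k] + hold_n - 1L
      ev <- rbind(ev, data.frame(sample = success_sample, event = "success"))
      break
    }
    if (ends[k] < last)
      ev <- rbind(ev, data.frame(sample = ends[k] + 1L, event = "exit"))
  }
  outcome <- "none"
  if (!is.na(success_sample)) {
    outcome <- "success"
    failure_sample <- NA_integer_    # failure would be after success
  } else if (!is.na(failure_sample)) {
    outcome <- "failure"
    ev <- rbind(ev, data.frame(sample = failure_sample, event = "failure"))
  }
  ev <- ev[order(ev$sample), , drop = FALSE]
  ev$time <- (ev$sample - 1L) * dt
  list(events = ev[, c("sample", "time", "event")], outcome = outcome,
       success_sample = success_sample, failure_sample = failure_sample)
}
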