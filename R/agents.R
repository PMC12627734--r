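#' Parameters of one synthetic agent (one side of the dyad)
#'
#' The synthetic controller is intermittent: whenever the ball error leaves
#' a deadband and the previous submovement has finished (plus a short
#' pause), a proportional-derivative rule maps ball error to a desired
#' board tilt, and the agent executes a discrete minimum-jerk submovement
#' of its hand toward the height that realizes its share of that tilt.
#' Leader/follower asymmetry is expressed through `gain_share` (fraction of
#' the required hand-height differential this agent produces) and
#' `reaction_delay` (lag added to this agent's submovement onsets).
#'
#' @param gain_share fraction in `[0, 1]` of the required differential this
#'   agent intends to produce; the two shares of a dyad must sum to 1.
#' @param reaction_delay onset lag (s) added to every submovement.
#' @param motor_noise_sd SD of Gaussian noise added to each submovement's
#'   target height (m).
#' @param trigger_threshold ball-error deadband (m) below which no new
#'   submovement is triggered.
#' @param submovement_duration duration of each minimum-jerk submovement (s).
#' @param kp proportional gain from ball error to desired tilt (rad/m).
#' @param kd derivative gain from ball velocity to desired tilt (rad s/m).
#' @param angle_bound saturation bound on the desired tilt (rad).
#' @param pause pause after a submovement before the next may trigger (s).
#' @return An object of class `bb_agent`.
#' @export
agent_params <- function(gain_share = 0.5, reaction_delay = 0,
                         motor_noise_sd = 0.001, trigger_threshold = 0.005,
                         submovement_duration = 0.30, kp = 0.14, kd = 0.20,
                         angle_bound = 0.05, pause = 0.10) {
  if (gain_share < 0 || gain_share > 1) stop("gain_share must be in [0, 1]")
  if (reaction_delay < 0) stop("reaction_delay must be >= 0")
  structure(list(gain_share = gain_share, reaction_delay = reaction_delay,
                 motor_noise_sd = motor_noise_sd,
                 trigger_threshold = trigger_threshold,
                 submovement_duration = submovement_duration,
                 kp = kp, kd = kd, angle_bound = angle_bound, pause = pause),
            class = "bb_agent")
}

#' Specification of a synthetic dyad
#'
#' @param left,right [agent_params()] for the two sides. Their gain shares
#'   must sum to 1.
#' @return An object of class `bb_dyad_spec` with a `ground_truth` element
#'   recording the true leader (side with the larger gain share, or
#'   `"none"` for equal shares), the true gain shares, and the follower's
#'   onset delay.
#' @export
dyad_spec <- function(left = agent_params(), right = agent_params()) {
  if (abs(left$gain_share + right$gain_share - 1) > 1e-9)
    stop("gain shares of the two agents must sum to 1")
  leader <- if (left$gain_share > right$gain_share) "L"
            else if (right$gain_share > left$gain_share) "R" else "none"
  follower_delay <- switch(leader, L = right$reaction_delay,
                           R = left$reaction_delay,
                           none = max(left$reaction_delay, right$reaction_delay))
  structure(list(left = left, right = right,
                 ground_truth = list(true_leader = leader,
                                     true_gain_share = c(L = left$gain_share,
                                                         R = right$gain_share),
                                     true_follower_delay = follower_delay)),
            class = "bb_dyad_spec")
}

#' Desired board tilt from the ball state
#'
#' Proportional-derivative rule: with ball error `e = goal - x` (positive
#' when the ball is left of the goal), the desired tilt is
#' `clamp(-kp e + kd xdot, +/- bound)`. The sign follows the ball dynamics
#' `xdd = -g sin(theta)`: a negative tilt accelerates the ball rightward.
#'
#' @param x_ball,x_ball_dot ball position (m) and velocity (m/s).
#' @param goal_x goal target center (m).
#' @param kp,kd controller gains.
#' @param bound tilt saturation (rad).
#' @return desired board angle (rad).
#' @export
desired_angle <- function(x_ball, x_ball_dot, goal_x, kp = 0.14, kd = 0.20,
                          bound = 0.05) {
  th <- -kp * (goal_x - x_ball) + kd * x_ball_dot
  pmin(pmax(th, -bound), bound)
}

#' Minimum-jerk submovement
#'
#' A smooth point-to-point hand trajectory with zero velocity and
#' acceleration at both ends: `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`.
#' Its midpoint displacement is half the amplitude and its peak speed is
#' `1.875 * amplitude / duration`.
#'
#' @param z0,z1 start and end heights (m).
#' @param duration movement time (s); must be positive.
#' @param onset onset time (s).
#' @return An object of class `bb_submovement`; evaluate it with
#'   [eval_submovement()].
#' @export
plan_submovement <- function(z0, z1, duration, onset = 0) {
  if (duration <= 0) stop("duration must be positive")
  structure(list(z0 = z0, z1 = z1, duration = duration, onset = onset),
            class = "bb_submovement")
}

#' Evaluate a minimum-jerk submovement
#'
#' Before onset the trajectory holds `z0`; after `onset + duration` it
#' holds `z1`; consecutive submovements planned from the previous endpoint
#' are therefore position-continuous.
#'
#' @param sm a [plan_submovement()].
#' @param t time(s) at which to evaluate (vectorized).
#' @return data.frame with columns `z` (m) and `z_dot` (m/s).
#' @export
eval_submovement <- function(sm, t) {
  tau <- pmin(pmax((t - sm$onset) / sm$duration, 0), 1)
  A <- sm$z1 - sm$z0
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  sd_ <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / sm$duration
  live <- t >= sm$onset & t <= sm$onset + sm$duration
  data.frame(z = sm$z0 + A * s, z_dot = ifelse(live, A * sd_, 0))
}

# scalar fast path used inside simulation loops: returns c(z, z_dot)
sm_eval1 <- function(sm, t) {
  tau <- (t - sm$onset) / sm$duration
  if (tau <= 0) return(c(sm$z0, 0))
  if (tau >= 1) return(c(sm$z1, 0))
  A <- sm$z1 - sm$z0
  c(sm$z0 + A * (10 * tau^3 - 15 * tau^4 + 6 * tau^5),
    A * (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / sm$duration)
}

#' Intermittent dyadic control policy
#'
#' Builds a stateful policy closure for [simulate_trial()]. Both agents
#' observe the same ball, so trigger decisions are shared: when the leader
#' side is idle (its previous submovement finished plus its pause) and the
#' ball error exceeds the deadband, or the commanded hand differential is
#' stale relative to the currently desired tilt, both agents plan
#' submovements toward their shares of the new differential. Each agent's
#' onset is the trigger time plus its own `reaction_delay`; each target
#' height is perturbed by its motor noise.
#'
#' The required hand-height differential for a desired tilt `theta*` with
#' the ball at `x` is `dz = 2 l sin(theta*) + m g x / (l k_h)`; the second
#' term offsets the static torque of the off-center ball.
#'
#' @param spec a [dyad_spec()].
#' @param params a [model_params()].
#' @return a policy function suitable for [simulate_trial()]. The closure
#'   draws from the R RNG when planning (motor noise), so seed
#'   [simulate_trial()] for reproducibility.
#' @export
dyad_policy <- function(spec, params = model_params()) {
  agents <- list(L = spec$left, R = spec$right)
  lead_side <- if (spec$left$reaction_delay <= spec$right$reaction_delay)
    "L" else "R"
  sm <- list(L = plan_submovement(0, 0, 1e-3, onset = -1),
             R = plan_submovement(0, 0, 1e-3, onset = -1))
  dz_planned <- 0
  function(obs) {
    st <- obs$state
    lead <- agents[[lead_side]]
    lead_sm <- sm[[lead_side]]
    idle <- obs$t >= lead_sm$onset + lead_sm$duration + lead$pause
    if (idle) {
      e <- obs$goal_x - st$x_ball
      th_des <- desired_angle(st$x_ball, st$x_ball_dot, obs$goal_x,
                              lead$kp, lead$kd, lead$angle_bound)
      dz_des <- 2 * params$l * sin(th_des) +
        params$m * params$g * st$x_ball / (params$l * params$k_h)
      if (abs(e) > lead$trigger_threshold ||
          abs(st$x_ball_dot) > 0.02 ||
          abs(dz_des - dz_planned) > 0.001) {
        dz_planned <<- dz_des
        for (side in c("L", "R")) {
          ag <- agents[[side]]
          onset <- obs$t + ag$reaction_delay
          z_from <- sm_eval1(sm[[side]], onset)[1]
          z_to <- (if (side == "L") -1 else 1) * ag$gain_share * dz_des
          if (ag$motor_noise_sd > 0)
            z_to <- z_to + stats::rnorm(1, 0, ag$motor_noise_sd)
          sm[[side]] <<- plan_submovement(z_from, z_to,
                                         ag$submovement_duration, onset)
        }
      }
    }
    L <- sm_eval1(sm$L, obs$t)
    R <- sm_eval1(sm$R, obs$t)
    list(z_L = L[1], z_R = R[1], z_L_dot = L[2], z_R_dot = R[2])
  }
}

#' Generate a synthetic-dyad dataset with known ground truth
#'
#' Simulates an experiment-style session for one synthetic dyad: blocks are
#' organized into sets of five, each set covering all five haptic
#' conditions in a seed-determined random order; each block holds
#' `trials_per_block` recordings with the start target alternating between
#' trials. Failed trials are repeated (the failed recording is kept, marked
#' `repeated = TRUE`) until success or `max_repeats` is hit. The profile
#' for the Unrelated condition is recorded from a Full-condition run of the
#' same dyad.
#'
#' @param spec a [dyad_spec()].
#' @param n_blocks number of blocks; a multiple of 5 covers each condition
#'   equally.
#' @param trials_per_block successful trials required per block.
#' @param condition_schedule optional character vector of length `n_blocks`
#'   overriding the randomized schedule.
#' @param config a [trial_config()].
#' @param params a [model_params()].
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param dyad_id identifier stored in recording metadata.
#' @param max_repeats cap on re-runs of a failed trial.
#' @return list with `recordings` (list of `bb_recording`, successful and
#'   failed), `ground_truth` (the spec's truth plus the schedule), and
#'   `schedule` (data.frame block/condition).
#' @export
generate_dyad_dataset <- function(spec, n_blocks = 5, trials_per_block = 4,
                                  condition_schedule = NULL,
                                  config = trial_config(),
                                  params = model_params(), seed = 1,
                                  dyad_id = "dyad1", max_repeats = 5) {
  stopifnot(inherits(spec, "bb_dyad_spec"))
  set.seed(seed)
  if (is.null(condition_schedule)) {
    n_sets <- ceiling(n_blocks / 5)
    condition_schedule <- unlist(lapply(seq_len(n_sets), function(s)
      sample(haptic_labels())))[seq_len(n_blocks)]
  }
  if (length(condition_schedule) != n_blocks)
    stop("condition_schedule must have one condition per block")

  profile <- NULL
  if ("Unrelated" %in% condition_schedule) {
    # record the feedback channel of a Full-condition run of this dyad
    pre <- simulate_trial(dyad_policy(spec, params),
                          haptic_condition("Full"), config, params,
                          start_side = "left",
                          seed = sample.int(.Machine$integer.max, 1))
    profile <- unrelated_profile(pre$FB_L, pre$FB_R, dt = params$dt)
  }

  recordings <- list()
  for (b in seq_len(n_blocks)) {
    lab <- condition_schedule[b]
    cond <- if (lab == "Unrelated") haptic_condition(lab, profile)
            else haptic_condition(lab)
    side <- if (b %% 2L == 1L) "left" else "right"
    for (tr in seq_len(trials_per_block)) {
      for (rep_i in seq_len(max_repeats)) {
        rec <- simulate_trial(dyad_policy(spec, params), cond, config,
                              params, start_side = side,
                              seed = sample.int(.Machine$integer.max, 1),
                              metadata = list(dyad = dyad_id, block = b,
                                              trial = tr,
                                              repeated = rep_i > 1L))
        recordings[[length(recordings) + 1L]] <- rec
        if (rec_meta(rec)$outcome == "success") break
      }
      side <- if (side == "left") "right" else "left"
    }
  }
  gt <- spec$ground_truth
  gt$condition_schedule <- condition_schedule
  list(recordings = recordings, ground_truth = gt,
       schedule = data.frame(block = seq_len(n_blocks),
                             condition = condition_schedule))
}
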