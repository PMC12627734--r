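test_that("control points follow the board pose", {
  p <- model_params()
  expect_equal(control_points(board_ball_state(), p), c(0, 0))
  expect_equal(control_points(board_ball_state(theta = 0.1), p),
               c(-0.25 * sin(0.1), 0.25 * sin(0.1)))
  expect_equal(control_points(board_ball_state(theta = 0.1), p)[2],
               0.024958, tolerance = 1e-4)
  expect_equal(control_points(board_ball_state(z_board = 0.02), p),
               c(0.02, 0.02))
})

test_that("hand forces combine spring and damper terms", {
  p <- model_params()
  s0 <- board_ball_state()
  expect_equal(hand_forces(hand_input(z_L = 0.01), s0, p), c(2, 0))
  expect_equal(hand_forces(hand_input(z_L_dot = 0.1), s0, p), c(0.2, 0))
  st <- board_ball_state(theta = 0.05)
  f <- hand_forces(hand_input(z_L = 0.01, z_R = -0.01), st, p)
  expect_equal(f[1], 200 * (0.01 + 0.25 * sin(0.05)))
  expect_equal(f[2], 200 * (-0.01 - 0.25 * sin(0.05)))
})

test_that("step dynamics produce the equations-of-motion accelerations", {
  p <- model_params()  # heavier-ball configuration
  dt <- p$dt
  # free fall of the unsupported loaded board
  s1 <- step_dynamics(board_ball_state(), 0, 0, p)
  expect_equal(s1$z_board_dot / dt, -(0.01 + 0.15) * 9.81 / 0.01)
  expect_equal(s1$theta_dot, 0)
  expect_equal(s1$x_ball_dot, 0)
  # differential force torque
  s2 <- step_dynamics(board_ball_state(), -0.05, 0.05, p)
  expect_equal(s2$theta_dot / dt, 0.1 * 0.25 / 4e-4)
  # ball acceleration from tilt
  s3 <- step_dynamics(board_ball_state(theta = 0.05), 0, 0, p)
  expect_equal(s3$x_ball_dot / dt, -9.81 * sin(0.05))
  expect_error(step_dynamics(board_ball_state(), NaN, 0, p), "finite")
})

test_that("feedback sources decompose the full reaction force", {
  full <- feedback_forces(-1, -0.5, 0.6, haptic_condition("Full"))
  expect_equal(full, c(1, 0.5))
  expect_equal(feedback_forces(-1, -0.5, 0.6, haptic_condition("Partner")),
               c(0.3, 0.3))
  expect_equal(feedback_forces(-1, -0.5, 0.6,
                               haptic_condition("Environment")),
               c(0.7, 0.2))
  expect_equal(feedback_forces(-1, -0.5, 0.6, haptic_condition("Without")),
               c(0, 0))
  # partner + environment = full, for arbitrary inputs
  set.seed(1)
  for (i in 1:200) {
    F <- rnorm(3)
    pe <- feedback_forces(F[1], F[2], F[3], haptic_condition("Partner")) +
      feedback_forces(F[1], F[2], F[3], haptic_condition("Environment"))
    expect_equal(pe, feedback_forces(F[1], F[2], F[3],
                                     haptic_condition("Full")),
                 tolerance = 1e-14)
  }
  expect_error(haptic_condition("Unrelated"), "profile")
})

test_that("unrelated profiles loop with a continuous crossfade ramp", {
  set.seed(2)
  n <- 2001  # 2 s at 1000 Hz
  prof <- unrelated_profile(cumsum(rnorm(n, 0, 0.01)),
                            cumsum(rnorm(n, 0, 0.01)))
  v_mid <- profile_value(prof, 2.05)
  expect_equal(v_mid[1], (prof$FB_L[n] + prof$FB_L[1]) / 2)
  expect_equal(v_mid[2], (prof$FB_R[n] + prof$FB_R[1]) / 2)
  # continuity across the whole replayed region
  ts <- seq(1.9, 4.5, by = 1e-3)
  vals <- profile_value(prof, ts)
  max_step <- max(abs(diff(vals[, 1])))
  ramp_slope <- max(abs(prof$FB_L[n] - prof$FB_L[1])) / prof$ramp_duration
  allowed <- max(max(abs(diff(prof$FB_L))), ramp_slope * 1e-3) + 1e-12
  expect_lt(max_step, 2 * allowed)
})

test_that("clamped hands settle the board at the analytic equilibrium", {
  p <- model_params()
  zeq <- equilibrium_height(p)
  expect_equal(zeq, -(0.01 + 0.15) * 9.81 / 140)
  st <- board_ball_state()
  hands <- hand_input(z_L = zeq, z_R = zeq)
  for (i in seq_len(5000)) {
    F <- hand_forces(hands, st, p)
    st <- step_dynamics(st, F[1], F[2], p)
  }
  expect_lt(abs(st$z_board - zeq), 1e-4)
  expect_lt(abs(st$theta), 1e-6)
})

test_that("frozen-tilt free roll matches the closed form", {
  p <- model_params()
  for (th in c(0.02, 0.05, 0.1)) {
    fr <- free_roll(th, x0 = 0, v0 = 0, duration = 1, params = p)
    expect_lt(max(abs(fr$x_ball - (-0.5 * 9.81 * sin(th) * fr$t^2))), 1e-4)
  }
})

test_that("swapping hands mirrors the trajectory", {
  p <- model_params()
  a <- function(t) 0.01 * sin(2 * pi * 0.7 * t)
  b <- function(t) -0.008 * sin(2 * pi * 0.5 * t + 0.4)
  mk <- function(f1, f2) function(obs)
    list(z_L = f1(obs$t), z_R = f2(obs$t), z_L_dot = 0, z_R_dot = 0)
  cfg <- trial_config(max_duration = 2)
  r1 <- simulate_trial(mk(a, b), haptic_condition("Without"), cfg, p,
                       start_side = "left")
  r2 <- simulate_trial(mk(b, a), haptic_condition("Without"), cfg, p,
                       start_side = "right")
  expect_equal(r2$theta, -r1$theta, tolerance = 1e-12)
  expect_equal(r2$x_ball, -r1$x_ball, tolerance = 1e-12)
  expect_equal(r2$z_board, r1$z_board, tolerance = 1e-12)
})

test_that("trial outcomes cover timeout, roll-off and success", {
  p <- model_params()
  # hands hold the board level against the off-center ball's torque, so
  # the ball never leaves the start target and the trial times out
  x0 <- trial_config()$target_positions[1]
  dz <- p$m * p$g * x0 / (p$l * p$k_h)
  idle <- function(obs) list(z_L = -dz / 2, z_R = dz / 2, z_L_dot = 0,
                             z_R_dot = 0)
  cfg <- trial_config(max_duration = 2)
  r <- simulate_trial(idle, haptic_condition("Without"), cfg, p)
  expect_equal(rec_meta(r)$outcome, "failure")
  expect_equal(rec_meta(r)$failure_reason, "timeout")
  # constant tilt: ball accelerates off the edge
  tilt <- function(obs) list(z_L = 0.03, z_R = -0.03, z_L_dot = 0,
                             z_R_dot = 0)
  r2 <- simulate_trial(tilt, haptic_condition("Without"),
                       trial_config(max_duration = 10), p,
                       start_side = "left")
  expect_equal(rec_meta(r2)$failure_reason, "rolloff")
  expect_gt(abs(r2$x_ball[nrow(r2)]), p$l)
  # competent synthetic dyad: success with completion >= hold duration
  spec <- dyad_spec(agent_params(gain_share = 0.7),
                    agent_params(gain_share = 0.3, reaction_delay = 0.12))
  r3 <- simulate_trial(dyad_policy(spec, p), haptic_condition("Full"),
                       trial_config(), p, seed = 4)
  expect_equal(rec_meta(r3)$outcome, "success")
  expect_gte(rec_meta(r3)$completion_time, 1.5)
  # identical seed and policy reproduce the recording exactly
  r4 <- simulate_trial(dyad_policy(spec, p), haptic_condition("Full"),
                       trial_config(), p, seed = 4)
  expect_identical(as.data.frame(r3), as.data.frame(r4))
})

test_that("the success monitor applies dwell and failure rules", {
  cfg <- trial_config()  # hold 1.5 s, half-width 0.03
  p <- model_params()
  goal <- 0.15
  inside <- rep(goal, 1499)
  outside <- rep(0, 200)
  m1 <- trial_success_monitor(c(outside, inside, outside), goal, cfg, p)
  expect_equal(m1$outcome, "none")
  m2 <- trial_success_monitor(c(outside, rep(goal, 1500)), goal, cfg, p)
  expect_equal(m2$outcome, "success")
  expect_equal(m2$success_sample, 200 + 1500)
  # failure takes precedence even after time in target
  m3 <- trial_success_monitor(c(rep(goal, 800), 0.26), goal, cfg, p)
  expect_equal(m3$outcome, "failure")
  expect_equal(m3$failure_sample, 801)
  # hand-spring force bound under motionless hands
  st <- board_ball_state(); hands <- hand_input()
  max_gap <- 0; max_F <- 0
  for (i in 1:2000) {
    F <- hand_forces(hands, st, p)
    cp <- control_points(st, p)
    gap <- max(abs(c(hands$z_L, hands$z_R) - cp))
    cpv <- max(abs(st$z_board_dot) + p$l * abs(st$theta_dot))
    max_F <- max(max_F, abs(F))
    max_gap <- max(max_gap, p$k_h * gap + p$c_h * cpv)
    st <- step_dynamics(st, F[1], F[2], p)
  }
  expect_lte(max_F, max_gap + 1e-9)
})
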