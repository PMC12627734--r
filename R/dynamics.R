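#' Heights of the two control points
#'
#' The hands act on the board through spring-dampers attached at the two
#' control points, a distance `l` either side of the board center. Positive
#' board rotation (counterclockwise) raises the right control point.
#'
#' @param state a [board_ball_state()].
#' @param params a [model_params()].
#' @return numeric length-2 vector `c(left, right)` of control-point
#'   heights (m).
#' @export
control_points <- function(state, params) {
  off <- params$l * sin(state$theta)
  c(state$z_board - off, state$z_board + off)
}

# vertical velocities of the control points (time derivative of the
# control-point heights)
control_point_velocities <- function(state, params) {
  off <- params$l * cos(state$theta) * state$theta_dot
  c(state$z_board_dot - off, state$z_board_dot + off)
}

#' Forces applied by the hands on the board
#'
#' Each hand couples to its control point through a spring-damper:
#' `F = k_h (z_hand - z_point) + c_h (zdot_hand - zdot_point)`.
#'
#' @param hands a [hand_input()].
#' @param state a [board_ball_state()].
#' @param params a [model_params()].
#' @return numeric length-2 vector `c(F_L, F_R)` (N).
#' @export
hand_forces <- function(hands, state, params) {
  zp <- control_points(state, params)
  zpd <- control_point_velocities(state, params)
  c(params$k_h * (hands$z_L - zp[1]) + params$c_h * (hands$z_L_dot - zpd[1]),
    params$k_h * (hands$z_R - zp[2]) + params$c_h * (hands$z_R_dot - zpd[2]))
}

#' Central spring force
#'
#' The board is anchored to the world origin by a linear spring acting on
#' the board-center height: `F_s = -k_s z_board`. This spring carries the
#' partner-sourced component of the haptic feedback.
#'
#' @inheritParams hand_forces
#' @return scalar force (N).
#' @export
spring_force <- function(state, params) {
  -params$k_s * state$z_board
}

#' Advance the board-ball dynamics by one step
#'
#' Equations of motion: the board translates under the two hand forces,
#' gravity of board and ball (normal force approximated as `m g cos^2
#' theta`), and the central spring; it rotates under the differential hand
#' force and the ball's weight; the ball slides on the frictionless board
#' with `xdd = -g sin(theta)`. Velocities are updated first from
#' accelerations evaluated at the pre-step state; positions then advance
#' with the trapezoid of old and new velocity, which is exact under
#' constant acceleration.
#'
#' @param state a [board_ball_state()].
#' @param F_L,F_R hand forces on the board (N).
#' @param params a [model_params()].
#' @return the advanced `bb_state`.
#' @export
step_dynamics <- function(state, F_L, F_R, params) {
  if (!is.finite(F_L) || !is.finite(F_R))
    stop("non-finite force input")
  ct <- cos(state$theta)
  F_s <- -params$k_s * state$z_board
  zdd <- (F_L + F_R - params$M * params$g -
            params$m * params$g * ct^2 + F_s) / params$M
  thdd <- ((F_R - F_L) * params$l * ct -
             params$m * params$g * state$x_ball * ct) / params$I
  xdd <- -params$g * sin(state$theta)
  dt <- params$dt

  zv <- state$z_board_dot + dt * zdd
  tv <- state$theta_dot + dt * thdd
  xv <- state$x_ball_dot + dt * xdd
  structure(list(
    z_board = state$z_board + dt * (state$z_board_dot + zv) / 2,
    z_board_dot = zv,
    theta = state$theta + dt * (state$theta_dot + tv) / 2,
    theta_dot = tv,
    x_ball = state$x_ball + dt * (state$x_ball_dot + xv) / 2,
    x_ball_dot = xv), class = "bb_state")
}

#' Loaded rest height of the board center
#'
#' With the hands holding the board level and motionless, the board settles
#' where the central spring carries the combined weight:
#' `z = -(M + m) g / k_s`.
#'
#' @param params a [model_params()].
#' @return equilibrium board-center height (m).
#' @export
equilibrium_height <- function(params) {
  -(params$M + params$m) * params$g / params$k_s
}

#' Haptic feedback rendered to the hands
#'
#' Decomposes the reaction force by source. `Without` renders nothing;
#' `Full` renders the full reaction `-F_side`; `Partner` renders only the
#' central-spring share `F_s / 2` per side (the component carrying the
#' partner's actions); `Environment` renders the remainder
#' `-F_side - F_s / 2`; `Unrelated` replays a pre-recorded profile. By
#' construction Partner + Environment equals Full exactly.
#'
#' @param F_L,F_R hand forces on the board (N).
#' @param F_s central spring force (N).
#' @param condition a [haptic_condition()].
#' @param t time since trial onset (s); used only by `Unrelated`.
#' @return numeric length-2 vector `c(FB_L, FB_R)` (N).
#' @export
feedback_forces <- function(F_L, F_R, F_s, condition, t = 0) {
  switch(condition$label,
    Without = c(0, 0),
    Full = c(-F_L, -F_R),
    Partner = c(F_s / 2, F_s / 2),
    Environment = c(-F_L - F_s / 2, -F_R - F_s / 2),
    Unrelated = profile_value(condition$profile, t))
}

#' Value of an unrelated-force profile at time t, with ramped looping
#'
#' The first pass plays the profile as recorded. On each replay a linear
#' ramp of `ramp_duration` seconds interpolates from the profile's end
#' value to its start value before the profile restarts, so the rendered
#' force is continuous.
#'
#' @param profile an [unrelated_profile()].
#' @param t time (s), vectorized.
#' @return a length-2 vector `c(FB_L, FB_R)` for scalar `t`, else a matrix
#'   with columns FB_L, FB_R.
#' @export
profile_value <- function(profile, t) {
  n <- length(profile$FB_L)
  D <- (n - 1) * profile$dt            # duration of the recorded profile
  r <- profile$ramp_duration
  one <- function(ti) {
    if (ti <= D) {
      idx <- ti / profile$dt
      lo <- floor(idx); w <- idx - lo
      i <- min(lo, n - 2) + 1L
      c((1 - w) * profile$FB_L[i] + w * profile$FB_L[i + 1L],
        (1 - w) * profile$FB_R[i] + w * profile$FB_R[i + 1L])
    } else {
      u <- (ti - D) %% (D + r)
      if (u < r) {
        a <- u / r
        c((1 - a) * profile$FB_L[n] + a * profile$FB_L[1L],
          (1 - a) * profile$FB_R[n] + a * profile$FB_R[1L])
      } else {
        Recall(u - r)
      }
    }
  }
  if (length(t) == 1L) one(t) else t(vapply(t, one, numeric(2)))
}

#' Ball trajectory under a frozen board angle
#'
#' Integrates only the ball equation `xdd = -g sin(theta)` with the board
#' angle held externally fixed, using the package integrator. Under a
#' frozen angle the closed form is `x(t) = x0 + v0 t - g sin(theta) t^2 / 2`.
#'
#' @param theta frozen board angle (rad).
#' @param x0,v0 initial ball position (m) and velocity (m/s).
#' @param duration simulated time (s).
#' @param params a [model_params()].
#' @return data.frame with columns `t`, `x_ball`, `x_ball_dot`.
#' @export
free_roll <- function(theta, x0 = 0, v0 = 0, duration = 1, params = model_params()) {
  dt <- params$dt
  n <- floor(duration / dt) + 1L
  x <- numeric(n); v <- numeric(n)
  x[1] <- x0; v[1] <- v0
  a <- -params$g * sin(theta)
  for (i in seq_len(n - 1L)) {
    v[i + 1L] <- v[i] + dt * a
    x[i + 1L] <- x[i] + dt * (v[i] + v[i + 1L]) / 2
  }
  data.frame(t = (seq_len(n) - 1L) * dt, x_ball = x, x_ball_dot = v)
}
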