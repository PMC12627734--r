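#' Physical parameters of the virtual board-ball model
#'
#' Collects the physical constants of the simulated task together with the
#' integration/sampling step. Defaults are the published constants of the
#' virtual board-ball apparatus; the ball mass defaults to the heavier
#' (dyadic-study) ball, `m = 0.15` kg, with `m = 0.05` kg available for the
#' lighter variant.
#'
#' @param M board mass (kg).
#' @param m ball mass (kg).
#' @param g gravitational acceleration (m/s^2).
#' @param k_h hand spring stiffness coupling hand to control point (N/m).
#' @param c_h hand damper (N s/m).
#' @param k_s stiffness of the central spring anchoring the board (N/m).
#' @param l distance from board center to each control point (m); also the
#'   roll-off half-length of the board.
#' @param I board moment of inertia about the rotation axis (kg m^2).
#' @param dt integration and sampling step (s); 0.001 gives the 1000 Hz
#'   sampling rate of the recordings.
#' @return An object of class `bb_params`: a named list of the nine constants.
#' @examples
#' p <- model_params()
#' equilibrium_height(p)  # loaded rest height of the board center
#' @export
model_params <- function(M = 0.01, m = 0.15, g = 9.81, k_h = 200, c_h = 2,
                         k_s = 140, l = 0.25, I = 4e-4, dt = 0.001) {
  p <- list(M = M, m = m, g = g, k_h = k_h, c_h = c_h, k_s = k_s,
            l = l, I = I, dt = dt)
  v <- unlist(p)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all model parameters must be finite and strictly positive")
  structure(p, class = "bb_params")
}

#' @export
print.bb_params <- function(x, ...) {
  cat("Board-ball model parameters:\n")
  cat(sprintf("  board M = %g kg, ball m = %g kg, g = %g m/s^2\n",
              x$M, x$m, x$g))
  cat(sprintf("  hand spring k_h = %g N/m, damper c_h = %g N s/m\n",
              x$k_h, x$c_h))
  cat(sprintf("  central spring k_s = %g N/m, half-length l = %g m, I = %g kg m^2\n",
              x$k_s, x$l, x$I))
  cat(sprintf("  dt = %g s (%g Hz)\n", x$dt, 1 / x$dt))
  invisible(x)
}

#' Kinematic state of the board and ball
#'
#' @param z_board board-center height (m).
#' @param z_board_dot board-center vertical velocity (m/s).
#' @param theta board rotation about the x-axis (rad, counterclockwise
#'   positive; positive theta raises the right control point).
#' @param theta_dot angular velocity (rad/s).
#' @param x_ball ball position along the board (m, 0 at center).
#' @param x_ball_dot ball velocity along the board (m/s).
#' @return An object of class `bb_state`.
#' @export
board_ball_state <- function(z_board = 0, z_board_dot = 0, theta = 0,
                             theta_dot = 0, x_ball = 0, x_ball_dot = 0) {
  s <- list(z_board = z_board, z_board_dot = z_board_dot, theta = theta,
            theta_dot = theta_dot, x_ball = x_ball, x_ball_dot = x_ball_dot)
  if (any(!is.finite(unlist(s)))) stop("state values must be finite")
  structure(s, class = "bb_state")
}

#' Hand input (commanded hand heights and velocities)
#'
#' @param z_L,z_R hand heights along z (m).
#' @param z_L_dot,z_R_dot hand vertical velocities (m/s).
#' @return An object of class `bb_hands`.
#' @export
hand_input <- function(z_L = 0, z_R = 0, z_L_dot = 0, z_R_dot = 0) {
  h <- list(z_L = z_L, z_R = z_R, z_L_dot = z_L_dot, z_R_dot = z_R_dot)
  if (any(!is.finite(unlist(h)))) stop("hand inputs must be finite")
  structure(h, class = "bb_hands")
}

#' The five haptic-feedback conditions
#' @export
haptic_labels <- function() {
  c("Without", "Full", "Partner", "Environment", "Unrelated")
}

#' Haptic feedback condition
#'
#' Selects which source of haptic feedback is rendered back to the hands:
#' none (`Without`), the full reaction force (`Full`), only the
#' partner-sourced component carried by the central spring (`Partner`), only
#' the environment-sourced component (`Environment`), or a pre-recorded
#' force profile unrelated to the ongoing trial (`Unrelated`).
#'
#' @param label one of `haptic_labels()`.
#' @param profile an [unrelated_profile()] object; required iff
#'   `label == "Unrelated"`.
#' @return An object of class `bb_condition`.
#' @export
haptic_condition <- function(label, profile = NULL) {
  label <- match.arg(label, haptic_labels())
  if (label == "Unrelated" && is.null(profile))
    stop("the Unrelated condition requires a replay profile")
  if (!is.null(profile) && !inherits(profile, "bb_profile"))
    stop("profile must be an unrelated_profile() object")
  structure(list(label = label, profile = profile), class = "bb_condition")
}

#' Pre-recorded force profile for the Unrelated condition
#'
#' A pair of feedback-force series sampled at the simulation rate. When a
#' trial outlasts the profile, the profile is replayed with a linear ramp
#' between its end and start values so the rendered force stays continuous.
#'
#' @param FB_L,FB_R feedback-force series per side (N), equal length.
#' @param dt sample step of the profile (s).
#' @param ramp_duration crossfade duration between profile end and start
#'   when looping (s).
#' @return An object of class `bb_profile`.
#' @export
unrelated_profile <- function(FB_L, FB_R, dt = 0.001, ramp_duration = 0.1) {
  if (length(FB_L) != length(FB_R) || length(FB_L) < 2L)
    stop("FB_L and FB_R must be equal-length series with >= 2 samples")
  if (any(!is.finite(FB_L)) || any(!is.finite(FB_R)))
    stop("profile forces must be finite")
  structure(list(FB_L = as.numeric(FB_L), FB_R = as.numeric(FB_R),
                 dt = dt, ramp_duration = ramp_duration),
            class = "bb_profile")
}

#' Trial protocol configuration
#'
#' @param target_positions the two target-center positions along the board
#'   (m); trials start with the ball at one and require moving it to the
#'   other.
#' @param target_half_width half-width of the target area (m).
#' @param hold_duration continuous in-target dwell required for success (s).
#' @param reset_hold duration the board must be held horizontal between
#'   trials (s); used by the session runner, excluded from completion time.
#' @param reset_angle_tol |theta| tolerance for "horizontal" during reset
#'   (rad).
#' @param max_duration safety cap on trial duration (s); exceeding it marks
#'   the trial failed with reason `"timeout"`.
#' @return An object of class `bb_trial_config`.
#' @export
trial_config <- function(target_positions = c(-0.15, 0.15),
                         target_half_width = 0.03, hold_duration = 1.5,
                         reset_hold = 1.0, reset_angle_tol = 0.02,
                         max_duration = 60) {
  if (length(target_positions) != 2L)
    stop("target_positions must give exactly two positions")
  if (hold_duration <= 0) stop("hold_duration must be positive")
  structure(list(target_positions = sort(as.numeric(target_positions)),
                 target_half_width = target_half_width,
                 hold_duration = hold_duration, reset_hold = reset_hold,
                 reset_angle_tol = reset_angle_tol,
                 max_duration = max_duration),
            class = "bb_trial_config")
}

# target geometry must fit on the board
check_targets_on_board <- function(config, params) {
  if (max(abs(config$target_positions)) + config$target_half_width >= params$l)
    stop("target areas must lie strictly inside the board half-length l")
  invisible(TRUE)
}
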