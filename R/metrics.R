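#' Per-sample interaction dynamics of the dyad
#'
#' Classifies each sample of the trial into one of four categories from
#' the two hands' movement states: `aligned` when the hands move in
#' opposite vertical directions (rotating the board in the same
#' direction), `opposed` when they move in the same vertical direction,
#' `single` when exactly one hand moves, `stationary` when neither does.
#'
#' @param labels_L,labels_R per-sample hand labels (`bb_segments` objects
#'   or character vectors with values down/stationary/up), same length.
#' @param stationary the stationary label.
#' @return character vector of categories, one per sample.
#' @export
classify_interaction <- function(labels_L, labels_R,
                                 stationary = "stationary") {
  if (inherits(labels_L, "bb_segments")) labels_L <- labels_L$labels
  if (inherits(labels_R, "bb_segments")) labels_R <- labels_R$labels
  if (length(labels_L) != length(labels_R))
    stop("label sequences must have the same length")
  sL <- labels_L == stationary
  sR <- labels_R == stationary
  out <- character(length(labels_L))
  out[sL & sR] <- "stationary"
  out[xor(sL, sR)] <- "single"
  both <- !sL & !sR
  out[both & labels_L == labels_R] <- "opposed"
  out[both & labels_L != labels_R] <- "aligned"
  out
}

#' Interaction-category ratios of a trial
#'
#' Time spent in each interaction category divided by the completion time.
#' The timeline is truncated to the completion window, so the four ratios
#' are nonnegative and sum to one.
#'
#' @param timeline per-sample categories from [classify_interaction()].
#' @param completion_time trial completion time (s).
#' @param dt sample step (s).
#' @return named numeric vector `aligned`, `opposed`, `single`,
#'   `stationary`.
#' @export
coordination_ratios <- function(timeline, completion_time, dt = 0.001) {
  if (!is.finite(completion_time) || completion_time <= 0)
    stop("completion_time must be positive")
  n_ct <- round(completion_time / dt)
  if (length(timeline) < n_ct)
    stop("timeline shorter than the completion window")
  tl <- timeline[seq_len(n_ct)]
  cats <- c("aligned", "opposed", "single", "stationary")
  counts <- vapply(cats, function(k) sum(tl == k), numeric(1))
  counts * dt / completion_time
}

# hand-direction labels consistent with a board rotation label:
# positive theta raises the right control point, so counterclockwise
# rotation (ccw, theta increasing) needs left down / right up.
consistent_hand_labels <- function(board_label) {
  if (board_label == "ccw") c(L = "down", R = "up")
  else c(L = "up", R = "down")
}

#' Onset delays within aligned board rotations
#'
#' For every board-rotation segment whose dominant interaction category is
#' `aligned`, finds each hand's movement onset — the closest non-stationary
#' hand-segment onset within `window` seconds of the board onset whose
#' direction is consistent with the rotation sign — and computes the onset
#' difference `delay = onset_L - onset_R`. A positive delay means the
#' right side moved first. Rotations for which either hand onset cannot be
#' paired are skipped and counted in the `n_skipped` attribute.
#'
#' @param board_segs `bb_segments` of the board angular velocity
#'   (labels cw/stationary/ccw).
#' @param segs_L,segs_R `bb_segments` of the two hands.
#' @param sample_rate sampling rate (Hz).
#' @param window onset-pairing half-window (s).
#' @return data.frame with one row per usable board rotation: `board_start`,
#'   `board_label`, `onset_L`, `onset_R` (s), `delay` (s), `abs_delay` (s);
#'   attribute `n_skipped` counts rejected rotations.
#' @export
aligned_delays <- function(board_segs, segs_L, segs_R, sample_rate = 1000,
                           window = 0.5) {
  rot <- movement_onsets(board_segs)
  tl <- classify_interaction(segs_L, segs_R)
  onsL <- movement_onsets(segs_L)
  onsR <- movement_onsets(segs_R)
  win_n <- window * sample_rate
  rows <- list(); n_skipped <- 0L
  for (i in seq_len(nrow(rot))) {
    idx <- rot$start[i]:rot$end[i]
    counts <- table(factor(tl[idx], levels = c("aligned", "opposed",
                                               "single", "stationary")))
    if (names(which.max(counts)) != "aligned") { next }
    need <- consistent_hand_labels(rot$label[i])
    pick <- function(ons, lab) {
      cand <- ons$start[ons$label == lab &
                          abs(ons$start - rot$start[i]) <= win_n]
      if (!length(cand)) NA_integer_
      else cand[which.min(abs(cand - rot$start[i]))]
    }
    oL <- pick(onsL, need["L"]); oR <- pick(onsR, need["R"])
    if (is.na(oL) || is.na(oR)) { n_skipped <- n_skipped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      board_start = (rot$start[i] - 1L) / sample_rate,
      board_label = rot$label[i],
      onset_L = (oL - 1L) / sample_rate, onset_R = (oR - 1L) / sample_rate)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(board_start = numeric(), board_label = character(),
               onset_L = numeric(), onset_R = numeric())
  out$delay <- out$onset_L - out$onset_R
  out$abs_delay <- abs(out$delay)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Board angle and hand positions at board-rotation segment ends
#'
#' Collects the samples used to fit the movement-ratio model: the board
#' angle and both hand heights at the last sample of each non-stationary
#' board segment (the moment the board has just stopped rotating).
#'
#' @param rec a `bb_recording` (or any data.frame with `theta`, `z_L`,
#'   `z_R`).
#' @param board_segs `bb_segments` of the board angular velocity.
#' @return data.frame with columns `theta`, `z_L`, `z_R`.
#' @export
board_segment_endpoints <- function(rec, board_segs) {
  ends <- movement_onsets(board_segs)$end
  data.frame(theta = rec$theta[ends], z_L = rec$z_L[ends],
             z_R = rec$z_R[ends])
}

#' Movement ratio: each side's share of board-angle control
#'
#' Fits the linear maps `z_L = -k_L theta + b_L` and
#' `z_R = k_R theta + b_R` by ordinary least squares over board-rotation
#' endpoint samples, and derives the movement ratios
#' `p_L = k_L / (k_L + k_R)`, `p_R = k_R / (k_L + k_R)`. The side with
#' `p > 0.5` dominates board manipulation.
#'
#' @param theta board angles at segment endpoints (rad).
#' @param z_L,z_R hand heights at the same samples (m).
#' @param min_points minimum number of endpoint samples required.
#' @return list with `p_L`, `p_R`, `k_L`, `k_R`, `b_L`, `b_R`,
#'   `r_squared` (per side), `n`, and `defined` (FALSE when
#'   `k_L + k_R <= 0`, in which case the ratios are `NA`).
#' @export
movement_ratio <- function(theta, z_L, z_R, min_points = 5) {
  n <- length(theta)
  if (n < min_points)
    stop(sprintf("need at least %d endpoint samples, got %d", min_points, n))
  fL <- stats::lm(z_L ~ theta)
  fR <- stats::lm(z_R ~ theta)
  k_L <- -unname(stats::coef(fL)[2])
  k_R <- unname(stats::coef(fR)[2])
  r2 <- function(f) {
    sst <- sum((f$model[[1]] - mean(f$model[[1]]))^2)
    if (sst == 0) return(1)
    1 - sum(stats::residuals(f)^2) / sst
  }
  defined <- is.finite(k_L + k_R) && (k_L + k_R) > 0
  p_L <- if (defined) k_L / (k_L + k_R) else NA_real_
  list(p_L = p_L, p_R = if (defined) 1 - p_L else NA_real_,
       k_L = k_L, k_R = k_R,
       b_L = unname(stats::coef(fL)[1]), b_R = unname(stats::coef(fR)[1]),
       r_squared = c(L = r2(fL), R = r2(fR)), n = n, defined = defined)
}

#' Cumulative corrective movement of one hand
#'
#' Mean absolute deviation of the hand position from its trailing moving
#' average over the past `k` samples (200 ms at 1000 Hz); the window is
#' truncated to `min(k, t)` samples including the current one.
#'
#' @param z hand-position series (m).
#' @param k moving-average window (samples).
#' @return scalar corrective-movement value (m).
#' @export
corrective_movement <- function(z, k = 200) {
  n <- length(z)
  if (n < 1L) stop("empty series")
  S <- cumsum(z)
  t <- seq_len(n)
  w <- pmin(k, t)
  m <- (S - c(rep(0, min(k, n)), S[seq_len(n - min(k, n))])) / w
  mean(abs(z - m))
}

#' Corrective movement ratio of the dyad
#'
#' @param z_L,z_R hand-position series (m).
#' @param k moving-average window (samples).
#' @return list with `C_L`, `C_R`, `CR_L`, `CR_R`, and `no_movement`
#'   (TRUE when both corrective movements are zero, in which case the
#'   ratios are reported as 0.5/0.5).
#' @export
corrective_ratio <- function(z_L, z_R, k = 200) {
  C_L <- corrective_movement(z_L, k)
  C_R <- corrective_movement(z_R, k)
  # guard against pure floating-point residue on motionless series
  eps <- 1e-12 * max(1, abs(z_L), abs(z_R))
  if (C_L + C_R <= eps)
    return(list(C_L = C_L, C_R = C_R, CR_L = 0.5, CR_R = 0.5,
                no_movement = TRUE))
  list(C_L = C_L, C_R = C_R, CR_L = C_L / (C_L + C_R),
       CR_R = C_R / (C_L + C_R), no_movement = FALSE)
}

#' Unilateral manipulation: per-side path length during single movements
#'
#' Accumulates each hand's movement distance (sum of absolute per-sample
#' displacements) over the intervals where that hand moves while the other
#' is stationary.
#'
#' @param z_L,z_R hand-position series (m).
#' @param labels_L,labels_R per-sample hand labels (or `bb_segments`).
#' @param stationary the stationary label.
#' @return list with `dist_L`, `dist_R` (m), `ratio_L`, `ratio_R`
#'   (NA with `defined = FALSE` when there are no single movements).
#' @export
unilateral_ratio <- function(z_L, z_R, labels_L, labels_R,
                             stationary = "stationary") {
  if (inherits(labels_L, "bb_segments")) labels_L <- labels_L$labels
  if (inherits(labels_R, "bb_segments")) labels_R <- labels_R$labels
  tl <- classify_interaction(labels_L, labels_R, stationary)
  n <- length(tl)
  i <- which(tl == "single")
  i <- i[i > 1L]
  moving_L <- labels_L[i] != stationary
  dist_L <- sum(abs(z_L[i] - z_L[i - 1L])[moving_L])
  dist_R <- sum(abs(z_R[i] - z_R[i - 1L])[!moving_L])
  tot <- dist_L + dist_R
  if (tot == 0)
    return(list(dist_L = dist_L, dist_R = dist_R, ratio_L = NA_real_,
                ratio_R = NA_real_, defined = FALSE))
  list(dist_L = dist_L, dist_R = dist_R, ratio_L = dist_L / tot,
       ratio_R = dist_R / tot, defined = TRUE)
}

#' Motion-triggered trajectory averaging (MTTA)
#'
#' Averages hand trajectories aligned to board-rotation onsets, normalized
#' by each rotation's required total hand displacement
#' `L_req = 2 l (sin theta_end - sin theta_start)`. Trajectories are
#' shifted to zero at the rotation onset; the left side is sign-flipped so
#' both sides are expressed as positive contributions to the rotation, and
#' both are divided by `L_req`. Curves are averaged over all segments per
#' (role, condition) cell, where the trial's leader side contributes to
#' the `leader` curve and the other side to the `follower` curve.
#'
#' Segments whose window leaves the trial are dropped, as are segments
#' with `|L_req|` below `min_L_req`.
#'
#' @param trials a list; each element is a list with elements `rec` (a
#'   `bb_recording` or data.frame with `z_L`, `z_R`, `theta`),
#'   `board_segs` (`bb_segments` of the board), `leader` (`"L"`, `"R"` or
#'   `"none"`; trials with `"none"` are skipped), `condition` (label).
#' @param params a [model_params()].
#' @param window time window around onset (s), default `c(-0.5, 1)`.
#' @param min_L_req minimum |required movement| (m) for a usable segment.
#' @return An object of class `bb_mtta`: a long data.frame with columns
#'   `role`, `condition`, `t`, `NT`, `n_segments`.
#' @export
mtta <- function(trials, params = model_params(), window = c(-0.5, 1),
                 min_L_req = 1e-4) {
  dt <- params$dt
  pre <- round(-window[1] / dt); post <- round(window[2] / dt)
  tax <- (seq_len(pre + post + 1L) - pre - 1L) * dt
  acc <- list()   # key -> list(sum, n)
  for (tr in trials) {
    if (is.null(tr$leader) || tr$leader == "none") next
    rec <- tr$rec
    rot <- movement_onsets(tr$board_segs)
    for (i in seq_len(nrow(rot))) {
      s0 <- rot$start[i]; s1 <- rot$end[i]
      if (s0 - pre < 1L || s0 + post > nrow(rec)) next
      L_req <- 2 * params$l * (sin(rec$theta[s1]) - sin(rec$theta[s0]))
      if (abs(L_req) < min_L_req) next
      idx <- (s0 - pre):(s0 + post)
      trL <- -(rec$z_L[idx] - rec$z_L[s0]) / L_req
      trR <- (rec$z_R[idx] - rec$z_R[s0]) / L_req
      for (side in c("L", "R")) {
        role <- if (side == tr$leader) "leader" else "follower"
        key <- paste(role, tr$condition, sep = "\r")
        cur <- if (side == "L") trL else trR
        if (is.null(acc[[key]])) acc[[key]] <- list(sum = cur, n = 0L)
        else acc[[key]]$sum <- acc[[key]]$sum + cur
        acc[[key]]$n <- acc[[key]]$n + 1L
      }
    }
  }
  out <- do.call(rbind, lapply(names(acc), function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    data.frame(role = parts[1], condition = parts[2], t = tax,
               NT = acc[[key]]$sum / acc[[key]]$n,
               n_segments = acc[[key]]$n)
  }))
  if (is.null(out))
    out <- data.frame(role = character(), condition = character(),
                      t = numeric(), NT = numeric(),
                      n_segments = integer())
  structure(out, class = c("bb_mtta", "data.frame"))
}

#' @export
plot.bb_mtta <- function(x, ...) {
  cells <- unique(x[, c("role", "condition")])
  cols <- seq_len(nrow(cells))
  plot(range(x$t), range(x$NT), type = "n", xlab = "time from onset (s)",
       ylab = "normalized trajectory NT", ...)
  graphics::abline(v = 0, lty = 3); graphics::abline(h = 0, lty = 3)
  for (i in seq_len(nrow(cells))) {
    sub <- x[x$role == cells$role[i] & x$condition == cells$condition[i], ]
    graphics::lines(sub$t, sub$NT, col = cols[i],
                    lty = if (cells$role[i] == "leader") 1 else 2)
  }
  graphics::legend("topleft", bty = "n", col = cols,
                   lty = ifelse(cells$role == "leader", 1, 2),
                   legend = paste(cells$condition, cells$role))
  invisible(x)
}

#' Relative dyadic improvement point
#'
#' Compares a participant's dyadic performance against their own and their
#' partner's individual (bimanual) performance:
#' `x = 1 - T_partner / T`, `y = 1 - T_dyad / T`, with `T` and `T_partner`
#' the stable bimanual completion times of participant and partner and
#' `T_dyad` the stable dyadic completion time. Points above the diagonal
#' indicate the dyad outperformed the pairing's expectation.
#'
#' @param T_self,T_partner,T_dyad stable completion times (s), all > 0.
#' @return list with `x` and `y`.
#' @export
dyadic_improvement <- function(T_self, T_partner, T_dyad) {
  if (any(c(T_self, T_partner, T_dyad) <= 0) ||
      any(!is.finite(c(T_self, T_partner, T_dyad))))
    stop("completion times must be positive and finite")
  list(x = 1 - T_partner / T_self, y = 1 - T_dyad / T_self)
}

#' Leader-follower summary from the four role metrics
#'
#' Combines the movement ratio, mean onset delay, corrective movement
#' ratio and unilateral manipulation ratio into a leader call. Each metric
#' votes for a side when it is decisive (outside its indifference band):
#' `p_L > 0.5` votes left; a negative mean delay (left onsets earlier)
#' votes left; `CR_L > 0.5` votes left; unilateral `ratio_L > 0.5` votes
#' left. The leader is the movement-ratio side, except that when the
#' movement ratio is ambiguous (`|p_L - 0.5| <` its band): then at least
#' two of the remaining metrics must be decisive and unanimous to name a
#' leader, otherwise the summary reports `"none"`.
#'
#' @param p_L movement ratio of the left side.
#' @param mean_delay mean onset delay (s; positive = right first).
#' @param CR_L corrective movement ratio of the left side.
#' @param UR_L unilateral manipulation ratio of the left side.
#' @param band_ratio indifference half-band on the three ratios.
#' @param band_delay indifference band on the mean delay (s).
#' @return An object of class `bb_leadership`: list with the four metrics,
#'   per-metric votes (`"L"`, `"R"` or `NA`), and `leader`
#'   (`"L"`, `"R"` or `"none"`).
#' @export
leadership_summary <- function(p_L, mean_delay, CR_L, UR_L,
                               band_ratio = 0.05, band_delay = 0.01) {
  vote_ratio <- function(p) {
    if (is.na(p) || abs(p - 0.5) < band_ratio) NA_character_
    else if (p > 0.5) "L" else "R"
  }
  votes <- c(
    movement = vote_ratio(p_L),
    delay = if (is.na(mean_delay) || abs(mean_delay) < band_delay)
      NA_character_ else if (mean_delay < 0) "L" else "R",
    corrective = vote_ratio(CR_L),
    unilateral = vote_ratio(UR_L))
  defined <- votes[!is.na(votes)]
  leader <- if (!is.na(votes["movement"])) {
    unname(votes["movement"])
  } else if (length(defined) >= 2L && length(unique(defined)) == 1L) {
    unname(defined[1])
  } else "none"
  structure(list(p_L = p_L, mean_delay = mean_delay, CR_L = CR_L,
                 UR_L = UR_L, votes = votes, leader = leader),
            class = "bb_leadership")
}

#' @export
print.bb_leadership <- function(x, ...) {
  cat("Leader-follower summary\n")
  cat(sprintf("  movement ratio p_L = %.3f   (vote %s)\n", x$p_L,
              x$votes["movement"]))
  cat(sprintf("  mean delay = %+.1f ms        (vote %s)\n",
              1000 * x$mean_delay, x$votes["delay"]))
  cat(sprintf("  corrective CR_L = %.3f      (vote %s)\n", x$CR_L,
              x$votes["corrective"]))
  cat(sprintf("  unilateral UR_L = %.3f      (vote %s)\n", x$UR_L,
              x$votes["unilateral"]))
  cat(sprintf("  leader: %s\n", x$leader))
  invisible(x)
}
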