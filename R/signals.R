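#' Zero-phase low-pass filter specification
#'
#' @param order filter order (even; default 10). The dual-pass applies the
#'   stated design forward and backward, so the effective magnitude
#'   response is the squared order-`order` response.
#' @param cutoff -3 dB cutoff of the single-pass design (Hz).
#' @param sample_rate sampling rate (Hz).
#' @return An object of class `bb_filter_spec`.
#' @export
filter_spec <- function(order = 10, cutoff = 20, sample_rate = 1000) {
  if (order %% 2 != 0 || order < 2) stop("order must be a positive even integer")
  if (cutoff <= 0 || cutoff >= sample_rate / 2)
    stop("cutoff must lie in (0, sample_rate / 2)")
  structure(list(order = order, cutoff = cutoff, sample_rate = sample_rate),
            class = "bb_filter_spec")
}

# Butterworth low-pass as a cascade of unity-DC-gain biquads.
# High-order single-section transfer functions are ill-conditioned at low
# normalized cutoffs, so sections are built directly from the analytic
# analog poles via the bilinear transform.
butter_sections <- function(order, cutoff, sample_rate) {
  n <- order
  wc <- 2 * sample_rate * tan(pi * cutoff / sample_rate)  # pre-warped
  k <- seq_len(n %/% 2)
  pk <- wc * exp(1i * pi * (2 * k + n - 1) / (2 * n))     # analog poles
  zp <- (2 * sample_rate + pk) / (2 * sample_rate - pk)   # bilinear
  t(vapply(seq_along(zp), function(j) {
    a1 <- -2 * Re(zp[j]); a2 <- Mod(zp[j])^2
    g <- (1 + a1 + a2) / 4
    c(g, 2 * g, g, 1, a1, a2)
  }, numeric(6)))
}

#' Dual-pass (zero-phase) Butterworth low-pass filtering
#'
#' Applies the Butterworth design of `spec` forward and then backward, so
#' the phase response cancels exactly while the magnitude response is
#' squared (an amplitude ratio of 0.5 at the single-pass cutoff). Edge
#' transients are suppressed by odd-reflection padding of three times the
#' filter order at both ends (removed after filtering) combined with
#' steady-state filter initialization at the first padded sample, so a
#' constant series passes through unchanged.
#'
#' @param x numeric series.
#' @param spec a [filter_spec()].
#' @return the filtered series, same length as `x`.
#' @export
zero_phase_filter <- function(x, spec = filter_spec()) {
  npad <- 3L * spec$order
  if (length(x) <= npad)
    stop(sprintf("series too short: need more than %d samples", npad))
  sos <- butter_sections(spec$order, spec$cutoff, spec$sample_rate)
  n <- length(x)
  # odd reflection about the end samples
  head_pad <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  xp <- c(head_pad, x, tail_pad)
  y <- sosfilt_zi(xp, sos, xp[1])
  y <- rev(sosfilt_zi(rev(y), sos, y[length(y)]))
  y[seq(npad + 1L, npad + n)]
}

#' Velocity from a position series
#'
#' Central finite differences at interior samples; one-sided differences at
#' the endpoints.
#'
#' @param x position series (m or rad), ideally low-pass filtered first.
#' @param sample_rate sampling rate (Hz).
#' @return velocity series, same length (m/s or rad/s).
#' @export
estimate_velocity <- function(x, sample_rate = 1000) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  dt <- 1 / sample_rate
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v
}
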