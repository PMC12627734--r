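# Shared fixtures and independent oracles. Expensive fixtures are built
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# full recovery pipeline for one synthetic dyad: dataset -> segmenters ->
# per-trial metrics -> pooled leadership
run_recovery <- function(spec, seed, n_blocks = 5, trials_per_block = 4) {
  p <- model_params()
  ds <- generate_dyad_dataset(spec, n_blocks = n_blocks,
                              trials_per_block = trials_per_block,
                              seed = seed)
  ok <- Filter(function(r) rec_meta(r)$outcome == "success", ds$recordings)
  models <- fit_session_segmenters(ok, seed = seed, n_restarts = 3)
  segs <- lapply(ok, segment_recording, models = models)
  pieces <- Map(function(r, s) trial_metrics(r, s, p), ok, segs)
  list(dataset = ds, ok = ok, models = models, segs = segs,
       pieces = pieces, pooled = block_leadership(pieces))
}

leader_dyad_fixture <- function() {
  fixture("leader_dyad", function() {
    spec <- dyad_spec(agent_params(gain_share = 0.7),
                      agent_params(gain_share = 0.3, reaction_delay = 0.12))
    run_recovery(spec, seed = 11)
  })
}

symmetric_dyad_fixture <- function() {
  fixture("symmetric_dyad", function() {
    run_recovery(dyad_spec(agent_params(), agent_params()), seed = 21)
  })
}

# reduced study layout run twice with identical seeds, for determinism
# and schedule-conservation checks
study_fixture <- function() {
  fixture("study", function() {
    sc <- study_config(
      dyads = list(pairA = dyad_spec(agent_params(gain_share = 0.65),
                                     agent_params(gain_share = 0.35,
                                                  reaction_delay = 0.1))),
      n_blocks = 5, trials_per_block = 2, seed = 7)
    d1 <- file.path(tempdir(), "study_run1")
    d2 <- file.path(tempdir(), "study_run2")
    r1 <- run_study(sc, out_dir = d1)
    r2 <- run_study(sc, out_dir = d2)
    list(sc = sc, r1 = r1, r2 = r2, d1 = d1, d2 = d2)
  })
}

# construct a bb_recording from raw channels (for metric-level tests)
scripted_recording <- function(z_L, z_R, theta, x_ball = NULL, dt = 0.001,
                               meta = list()) {
  n <- length(z_L)
  if (is.null(x_ball)) x_ball <- numeric(n)
  df <- data.frame(t = (seq_len(n) - 1) * dt, z_L = z_L, z_R = z_R,
                   F_L = 0, F_R = 0, FB_L = 0, FB_R = 0, z_board = 0,
                   theta = theta, x_ball = x_ball)
  base <- list(dyad = "scripted", pairing = "dyadic", condition = "Full",
               block = 1L, trial = 1L, start_side = "left",
               outcome = "success", failure_reason = NA_character_,
               completion_time = (n - 1) * dt, seed = NULL,
               params = unclass(model_params()))
  structure(df, meta = utils::modifyList(base, meta),
            class = c("bb_recording", "data.frame"))
}

segments_object <- function(labels, sample_rate = 1000) {
  structure(list(labels = labels,
                 segments = segments_from_labels(labels, sample_rate),
                 min_duration = 0, sample_rate = sample_rate),
            class = "bb_segments")
}

# minimum-jerk position profile (independent closed form)
minjerk_pos <- function(t, t0, dur, z0, z1) {
  tau <- pmin(pmax((t - t0) / dur, 0), 1)
  z0 + (z1 - z0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

# velocity threshold oracle for piecewise-constant velocities
threshold_oracle <- function(v, thr, labels = c("down", "stationary", "up")) {
  ifelse(v > thr, labels[3], ifelse(v < -thr, labels[1], labels[2]))
}

# direct double-loop evaluation of the corrective-movement statistic
brute_corrective <- function(z, k = 200) {
  n <- length(z)
  acc <- 0
  for (t in seq_len(n)) {
    w <- min(k, t)
    m <- 0
    for (j in 0:(w - 1)) m <- m + z[t - j]
    acc <- acc + abs(z[t] - m / w)
  }
  acc / n
}

# brute-force one-way repeated-measures ANOVA from sums of squares
brute_rmanova <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  gm <- mean(wide)
  ss_cond <- n * sum((colMeans(wide) - gm)^2)
  ss_subj <- k * sum((rowMeans(wide) - gm)^2)
  ss_tot <- sum((wide - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_ <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(F = F_, df1 = k - 1, df2 = (k - 1) * (n - 1),
       p = stats::pf(F_, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

# hand-evaluated Holm step-down adjustment
hand_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# deterministic MTTA construction: one smooth rotation produced by exact
# hand shares, with exactly known segment boundaries; parameterized by the
# sine of the total rotation so hand trajectories are exactly linear in
# the required movement
mtta_construction <- function(share_L = 0.7, sin_total = sin(0.1),
                              onset = 601L, dur_n = 500L, n = 3001L,
                              params = model_params()) {
  tt <- seq_len(n)
  tau <- pmin(pmax((tt - onset) / dur_n, 0), 1)
  s5 <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  theta <- asin(sin_total * s5)
  z_R <- (1 - share_L) * 2 * params$l * sin_total * s5
  z_L <- -share_L * 2 * params$l * sin_total * s5
  labels <- rep("stationary", n)
  labels[(onset + 1L):(onset + dur_n)] <- "ccw"
  rec <- scripted_recording(z_L, z_R, theta)
  list(rec = rec, board_segs = segments_object(labels), leader = "L",
       condition = "Full")
}
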