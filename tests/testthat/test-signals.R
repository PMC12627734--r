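test_that("dual-pass filtering is zero-phase with the expected gains", {
  fs <- filter_spec()
  # DC gain
  expect_lt(max(abs(zero_phase_filter(rep(2.5, 500), fs) - 2.5)), 1e-9)
  # amplitude ratio ~0.5 at the single-pass cutoff (squared -3 dB point)
  t <- (0:4999) / 1000
  y <- zero_phase_filter(sin(2 * pi * 20 * t), fs)
  expect_equal(max(abs(y[1500:3500])), 0.5, tolerance = 0.02)
  # well inside the passband the series is untouched
  y2 <- zero_phase_filter(sin(2 * pi * 2 * t), fs)
  expect_equal(max(abs(y2[1500:3500])), 1, tolerance = 1e-3)
  # sample-symmetric pulse stays symmetric: zero phase lag
  i <- 0:2000
  pulse <- exp(-((i - 1000)^2) / (2 * 50^2))
  yp <- zero_phase_filter(pulse, fs)
  expect_lt(max(abs(yp - rev(yp))), 1e-9)
  expect_equal(which.max(yp), 1001)
  expect_error(zero_phase_filter(rnorm(20), fs), "too short")
  expect_error(filter_spec(order = 7), "even")
  expect_error(filter_spec(cutoff = 600), "cutoff")
})

test_that("velocity estimation is exact on ramps and accurate on sines", {
  v <- estimate_velocity(0.3 * (0:999) / 1000, 1000)
  expect_equal(v, rep(0.3, 1000))
  expect_equal(estimate_velocity(rep(1.7, 100), 1000), rep(0, 100))
  t <- (0:1999) / 1000
  f <- 3
  vhat <- estimate_velocity(sin(2 * pi * f * t), 1000)
  vtrue <- 2 * pi * f * cos(2 * pi * f * t)
  interior <- 2:1999
  bound <- (2 * pi * f)^3 * (1e-3)^2 / 6   # central-difference remainder
  expect_lt(max(abs(vhat[interior] - vtrue[interior])), bound * 1.01)
})

test_that("the segmenter recovers known emission parameters", {
  # three well-separated Gaussian states with Markov switching
  set.seed(42)
  mu_true <- c(-0.05, 0, 0.05); sd_true <- c(0.006, 0.004, 0.006)
  A <- matrix(0.01, 3, 3); diag(A) <- 0.98
  st <- 2L; v <- numeric(6000)
  for (i in seq_along(v)) {
    st <- sample.int(3, 1, prob = A[st, ])
    v[i] <- rnorm(1, mu_true[st], sd_true[st])
  }
  m <- fit_segmenter(v, seed = 3, n_restarts = 4)
  spacing <- 0.05
  expect_lt(max(abs(m$means - mu_true)), 0.05 * spacing * 2)
  # label-assignment contract: ascending emission means
  expect_true(all(diff(m$means) > 0))
  expect_equal(m$labels, c("down", "stationary", "up"))
  expect_equal(rowSums(m$transition), rep(1, 3))
  # determinism under the seed
  m2 <- fit_segmenter(v, seed = 3, n_restarts = 4)
  expect_identical(m[c("means", "sds", "transition", "loglik")],
                   m2[c("means", "sds", "transition", "loglik")])
  expect_error(fit_segmenter(rep(0.01, 5000)), "degenerate")
})

test_that("decoding matches a threshold oracle on clean square waves", {
  sq <- rep(c(0, 0.05, 0, -0.05), each = 500, times = 3)
  m <- fit_segmenter(sq, seed = 3, n_restarts = 3)
  seg <- decode_segments(sq, m)
  oracle <- threshold_oracle(sq, 0.025)
  expect_gte(mean(seg$labels == oracle), 0.99)
  b_or <- which(diff(match(oracle, m$labels)) != 0)
  b_hm <- which(diff(match(seg$labels, m$labels)) != 0)
  expect_equal(length(b_hm), length(b_or))
  expect_lte(max(abs(b_hm - b_or)), 1)  # boundaries within +/- 1 sample
  # all-zero velocity: one stationary segment
  seg0 <- decode_segments(numeric(2000), m)
  expect_equal(nrow(seg0$segments), 1L)
  expect_equal(seg0$segments$label, "stationary")
  # segments partition the series with alternating labels
  s <- seg$segments
  expect_equal(s$start[1], 1L)
  expect_equal(s$end[nrow(s)], length(sq))
  expect_true(all(s$start[-1] == s$end[-nrow(s)] + 1L))
  expect_true(all(s$label[-1] != s$label[-nrow(s)]))
  expect_true(all(s$duration >= 0.05))
})

test_that("segmentation respects time reversal and offset invariance", {
  # a position trace with two opposite movements, decoded under a
  # direction-symmetric segmenter (the setting in which time reversal is
  # an exact symmetry of the pipeline)
  t <- (0:2999) / 1000
  pos <- minjerk_pos(t, 0.5, 0.4, 0, 0.04) -
    minjerk_pos(t, 1.8, 0.4, 0, 0.04)
  fs <- filter_spec()
  A <- matrix(0.01, 3, 3); diag(A) <- 0.98
  model <- structure(list(means = c(-0.1, 0, 0.1),
                          sds = c(0.02, 0.005, 0.02),
                          transition = A, init = rep(1 / 3, 3),
                          labels = c("down", "stationary", "up"),
                          loglik = NA, n_iter = 0L, seed = NA),
                     class = "bb_segmenter")
  dec <- function(x) {
    v <- estimate_velocity(zero_phase_filter(x, fs), 1000)
    decode_segments(v, model)
  }
  fwd <- dec(pos)
  rev_ <- dec(rev(pos))
  swap <- c(down = "up", stationary = "stationary", up = "down")
  expect_equal(rev_$labels, unname(swap[rev(fwd$labels)]))
  # adding a constant offset to positions changes nothing
  off <- dec(pos + 0.37)
  expect_identical(off$labels, fwd$labels)
})
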