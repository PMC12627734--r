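test_that("interaction categories follow the nine-combination grouping", {
  expect_equal(classify_interaction("up", "down"), "aligned")
  expect_equal(classify_interaction("down", "up"), "aligned")
  expect_equal(classify_interaction("up", "up"), "opposed")
  expect_equal(classify_interaction("down", "down"), "opposed")
  expect_equal(classify_interaction("up", "stationary"), "single")
  expect_equal(classify_interaction("stationary", "down"), "single")
  expect_equal(classify_interaction("stationary", "stationary"),
               "stationary")
  expect_error(classify_interaction(c("up", "up"), "up"), "length")
  # swapping hands leaves every category unchanged
  set.seed(8)
  lL <- sample(c("down", "stationary", "up"), 500, replace = TRUE)
  lR <- sample(c("down", "stationary", "up"), 500, replace = TRUE)
  expect_equal(classify_interaction(lL, lR), classify_interaction(lR, lL))
})

test_that("coordination ratios divide category time by completion time", {
  tl <- rep(c("aligned", "opposed", "single", "stationary"),
            c(2000, 1000, 1000, 1000))
  r <- coordination_ratios(tl, completion_time = 5, dt = 0.001)
  expect_equal(unname(r), c(0.4, 0.2, 0.2, 0.2))
  expect_equal(sum(r), 1)
  r0 <- coordination_ratios(rep("stationary", 3000), 3, 0.001)
  expect_equal(unname(r0), c(0, 0, 0, 1))
  expect_error(coordination_ratios(tl, 0), "positive")
})

test_that("aligned delays use the onset difference with the sign convention", {
  # board rotates ccw from sample 1001; right hand (up) leads at 1001,
  # left hand (down) follows at 1121 -> delay = +0.12 s (right first)
  n <- 2000
  lab_board <- rep(c("stationary", "ccw", "stationary"), c(1000, 500, 500))
  lab_L <- rep(c("stationary", "down", "stationary"), c(1120, 380, 500))
  lab_R <- rep(c("stationary", "up", "stationary"), c(1000, 500, 500))
  d <- aligned_delays(segments_object(lab_board), segments_object(lab_L),
                      segments_object(lab_R))
  expect_equal(nrow(d), 1L)
  expect_equal(d$delay, 0.12)
  expect_equal(d$abs_delay, 0.12)
  # simultaneous onsets: zero delay
  lab_L2 <- rep(c("stationary", "down", "stationary"), c(1000, 500, 500))
  d2 <- aligned_delays(segments_object(lab_board), segments_object(lab_L2),
                       segments_object(lab_R))
  expect_equal(d2$delay, 0)
  # mirror: swapping sides and the rotation sense negates the delay
  lab_board_m <- rep(c("stationary", "cw", "stationary"), c(1000, 500, 500))
  dm <- aligned_delays(segments_object(lab_board_m),
                       segments_object(lab_R), segments_object(lab_L))
  expect_equal(dm$delay, -d$delay)
  # aligned rotation whose left onset is outside the pairing window:
  # the observation is skipped and counted
  lab_far <- rep(c("stationary", "down", "stationary"), c(99, 1501, 400))
  d3 <- aligned_delays(segments_object(lab_board), segments_object(lab_far),
                       segments_object(lab_R))
  expect_equal(nrow(d3), 0L)
  expect_equal(attr(d3, "n_skipped"), 1L)
})

test_that("movement ratio recovers exact linear shares", {
  th <- seq(-0.08, 0.08, length.out = 40)
  mv <- movement_ratio(th, -0.7 * th + 0.01, 0.3 * th + 0.01)
  expect_equal(mv$p_L, 0.7, tolerance = 1e-12)
  expect_equal(mv$p_R, 0.3, tolerance = 1e-12)
  expect_equal(mv$p_L + mv$p_R, 1)
  expect_equal(unname(mv$r_squared), c(1, 1), tolerance = 1e-12)
  # symmetric gains: no leader side
  mv2 <- movement_ratio(th, -0.5 * th, 0.5 * th)
  expect_equal(mv2$p_L, 0.5)
  # height offsets are absorbed by the intercept
  mv3 <- movement_ratio(th, -0.7 * th + 0.25, 0.3 * th - 0.13)
  expect_equal(mv3$p_L, mv$p_L)
  expect_equal(mv3$b_L, 0.25)
  # mirrored data swap the ratios
  mv4 <- movement_ratio(-th, 0.3 * -(-th) + 0.01, -(-0.7) * (-th) + 0.01)
  expect_equal(mv4$p_L, 0.3, tolerance = 1e-12)
  expect_error(movement_ratio(th[1:3], th[1:3], th[1:3]), "at least")
  # degenerate slopes are flagged
  mvd <- movement_ratio(th, 0.5 * th, -0.5 * th)
  expect_false(mvd$defined)
  expect_true(is.na(mvd$p_L))
})

test_that("corrective movement matches brute-force evaluation", {
  # constant positions: zero corrective movement, flagged ratio
  cr0 <- corrective_ratio(rep(0.02, 500), rep(-0.01, 500))
  expect_equal(cr0$C_L, 0)
  expect_true(cr0$no_movement)
  expect_equal(c(cr0$CR_L, cr0$CR_R), c(0.5, 0.5))
  # only one side moves: its ratio is 1
  ramp <- 0.0001 * (1:1000)
  cr1 <- corrective_ratio(rep(0, 1000), ramp)
  expect_equal(cr1$CR_R, 1)
  # ramp deviation approaches v (k - 1) / 2 once the window fills
  k <- 200; v <- 1e-4
  z <- v * (1:500)
  S <- cumsum(z)
  dev_400 <- abs(z[400] - (S[400] - S[400 - k]) / k)
  expect_equal(dev_400, v * (k - 1) / 2, tolerance = 1e-10)
  # implementation equals the double-loop oracle on random series
  set.seed(9)
  for (i in 1:20) {
    z <- cumsum(rnorm(300, 0, 0.002))
    expect_equal(corrective_movement(z, 200), brute_corrective(z, 200),
                 tolerance = 1e-12)
    expect_equal(corrective_movement(z, 50), brute_corrective(z, 50),
                 tolerance = 1e-12)
  }
})

test_that("unilateral manipulation sums path length during single moves", {
  # left moves alone 0.03 m, right moves alone 0.01 m
  z_L <- c(seq(0, 0.03, length.out = 301), rep(0.03, 400))
  z_R <- c(rep(0, 301), seq(0, 0.01, length.out = 201), rep(0.01, 199))
  lab_L <- c(rep("up", 301), rep("stationary", 400))
  lab_R <- c(rep("stationary", 301), rep("up", 201), rep("stationary", 199))
  u <- unilateral_ratio(z_L, z_R, lab_L, lab_R)
  expect_equal(u$ratio_L, 0.75, tolerance = 1e-9)
  expect_equal(u$ratio_R, 0.25, tolerance = 1e-9)
  expect_equal(u$ratio_L + u$ratio_R, 1)
  # offset invariance
  u2 <- unilateral_ratio(z_L + 0.5, z_R - 0.2, lab_L, lab_R)
  expect_equal(u2$ratio_L, u$ratio_L)
  # one side never moves alone
  u3 <- unilateral_ratio(z_L, rep(0, 701), lab_L, rep("stationary", 701))
  expect_equal(u3$ratio_L, 1)
  # no single intervals at all: undefined
  u4 <- unilateral_ratio(z_L, z_R, rep("stationary", 701),
                         rep("stationary", 701))
  expect_false(u4$defined)
})

test_that("MTTA normalizes by the required movement and preserves shares", {
  p <- model_params()
  expect_equal(2 * p$l * (sin(0.1) - sin(0)), 0.0499167, tolerance = 1e-6)
  tr <- mtta_construction(share_L = 0.7)
  curves <- mtta(list(tr), p)
  lead <- curves[curves$role == "leader", ]
  fol <- curves[curves$role == "follower", ]
  expect_equal(lead$NT[lead$t == 0], 0)
  expect_equal(fol$NT[fol$t == 0], 0)
  expect_equal(lead$NT[which.max(lead$t)], 0.7, tolerance = 1e-6)
  expect_equal(fol$NT[which.max(fol$t)], 0.3, tolerance = 1e-6)
  # right hand alone: follower flat at 0, leader rises to 1
  tr1 <- mtta_construction(share_L = 0)
  tr1$leader <- "R"
  c1 <- mtta(list(tr1), p)
  expect_equal(max(abs(c1$NT[c1$role == "follower"])), 0)
  expect_equal(c1$NT[c1$role == "leader" & c1$t == max(c1$t)], 1,
               tolerance = 1e-6)
  # scaling the rotation with proportional hand movement leaves NT fixed
  big <- mtta_construction(share_L = 0.7, sin_total = 2 * sin(0.1))
  cb <- mtta(list(big), p)
  expect_equal(cb$NT, curves$NT, tolerance = 1e-9)
})

test_that("dyadic improvement compares stable completion times", {
  expect_equal(dyadic_improvement(10, 8, 8), list(x = 0.2, y = 0.2))
  expect_equal(dyadic_improvement(10, 10, 10), list(x = 0, y = 0))
  expect_equal(dyadic_improvement(8, 10, 8), list(x = -0.25, y = 0))
  expect_error(dyadic_improvement(0, 1, 1), "positive")
})

test_that("leadership summary combines the four metrics", {
  s <- leadership_summary(p_L = 0.7, mean_delay = -0.1, CR_L = 0.65,
                          UR_L = 0.7)
  expect_equal(s$leader, "L")
  expect_true(all(s$votes == "L"))
  s2 <- leadership_summary(p_L = 0.3, mean_delay = 0.1, CR_L = 0.4,
                           UR_L = 0.3)
  expect_equal(s2$leader, "R")
  # ambiguous movement ratio with conflicting metrics: no leader
  s3 <- leadership_summary(p_L = 0.51, mean_delay = -0.1, CR_L = 0.3,
                           UR_L = 0.5)
  expect_equal(s3$leader, "none")
  # ambiguous movement ratio, no decisive metric: no leader
  s4 <- leadership_summary(p_L = 0.49, mean_delay = 0.001, CR_L = 0.52,
                           UR_L = 0.51)
  expect_equal(s4$leader, "none")
})
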