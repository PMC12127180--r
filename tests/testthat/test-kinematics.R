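test_that("constant-velocity trajectory yields the closed-form speed", {
  # body com advancing 1 px/frame at 30 FPS, 0.1 mm/px -> 3 mm/s
  n <- 300
  traj <- make_traj(cbind(seq_len(n) * 0.1, 0))
  kin <- compute_kinematics(traj)
  mid <- 30:(n - 30)
  expect_equal(median(kin$swim_speed[mid]), 3, tolerance = 1e-6)
  expect_true(all(diff(kin$cumulative_distance) >= 0))
  expect_equal(kin$cumulative_distance[n], (n - 1) * 0.1, tolerance = 1e-6)
})

test_that("sinusoidal head yaw gives the analytic peak angular acceleration", {
  # theta(t) = A sin(2 pi f t): max |theta''| = A (2 pi f)^2; f chosen so
  # peaks fall on the frame grid (24 frames per cycle)
  A <- 10; f <- 1.25; n <- 1200
  t <- (seq_len(n) - 1) / 30
  traj <- make_traj(cbind(0, 0)[rep(1, n), ], yaw = A * sin(2 * pi * f * t))
  kin <- compute_kinematics(traj)
  expect_rel(max(abs(kin$head_ang_accel[20:(n - 20)])), A * (2 * pi * f)^2,
             0.02)
})

test_that("a stationary animal produces near-zero speed and acceleration", {
  traj <- make_traj(cbind(5, 5)[rep(1, 200), ])
  kin <- compute_kinematics(traj)
  expect_equal(max(kin$swim_speed), 0, tolerance = 1e-9)
  expect_equal(max(abs(kin$head_ang_accel)), 0, tolerance = 1e-9)
  expect_error(compute_kinematics(make_traj(cbind(1, 1)[rep(1, 10), ])),
               class = "gazestab_input_error")
})

test_that("dual-threshold detection needs both speed and tail motion", {
  n <- 600
  t <- (seq_len(n) - 1) / 30
  on <- t >= 5 & t < 15
  # swimming segment: 5 mm/s with 4 Hz tail beats
  com <- cbind(cumsum(ifelse(on, 5 / 30, 0)), 0)
  tails <- ifelse(on, 20, 0) * sin(2 * pi * 4 * t)
  kin <- compute_kinematics(make_traj(com, tail_angle = tails))
  b <- detect_bouts(kin)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration, 10, tolerance = 0.2)

  # passive drift: moving but tail still -> no bouts
  kin_drift <- compute_kinematics(make_traj(com))
  expect_equal(nrow(detect_bouts(kin_drift)), 0)

  # tail wiggling in place: no locomotion -> no bouts
  kin_wiggle <- compute_kinematics(
    make_traj(cbind(0, 0)[rep(1, n), ], tail_angle = tails))
  expect_equal(nrow(detect_bouts(kin_wiggle)), 0)
})

test_that("detection recovers scripted bout boundaries within 2 frames", {
  traj <- simulate_swim(swim_preset("axolotl_54"), seed = 3)
  gt <- attr(traj, "ground_truth")
  b <- detect_bouts(compute_kinematics(traj))
  expect_equal(nrow(b), nrow(gt))
  expect_lt(max(abs(b$start - gt$start)), 2.5 / 30)
  expect_lt(max(abs(b$end - gt$end)), 2.5 / 30)
})

test_that("raising the speed threshold never increases total bout time", {
  traj <- simulate_swim(swim_preset("xenopus_54"), seed = 4)
  kin <- compute_kinematics(traj)
  tot <- vapply(c(1, 2, 3, 4, 5, 6),
                function(v) sum(detect_bouts(kin, v_thresh = v)$duration),
                numeric(1))
  expect_true(all(diff(tot) <= 1e-12))
})

test_that("bout summaries weight durations and integrate to one", {
  bouts <- tibble(bout = 1:2, start = c(0, 50), end = c(30, 51),
                  duration = c(30, 1))
  s <- summarize_bouts(bouts, recording_length = 60, bin_width = 0.5)
  dens <- tidy(s)
  expect_equal(sum(dens$density * 0.5), 1, tolerance = 1e-9)
  # the 30 s bout carries 30/31 of the mass
  mass_long <- sum(dens$density[dens$bin_lower >= 29] * 0.5)
  expect_equal(mass_long, 30 / 31, tolerance = 1e-9)

  one <- summarize_bouts(tibble(bout = 1, start = 5, end = 15, duration = 10),
                         recording_length = 60)
  expect_equal(glance(one)$percent_time_swimming, 100 * 10 / 60,
               tolerance = 1e-9)

  # equal durations: weighting is a no-op against the unweighted histogram
  eq <- summarize_bouts(tibble(bout = 1:4, start = c(0, 10, 20, 30),
                               end = c(2, 12, 22, 32), duration = rep(2, 4)),
                        recording_length = 60)
  deq <- tidy(eq)
  expect_equal(deq$density[deq$bin_lower == 1.5], 2, tolerance = 1e-9)

  # total swim time invariant to the binning
  for (bw in c(0.25, 0.5, 2)) {
    expect_equal(glance(summarize_bouts(bouts, 60, bw))$total_swim_time, 31)
  }

  empty <- summarize_bouts(bouts[0, ], 60)
  expect_equal(glance(empty)$n_bouts, 0)
  expect_equal(nrow(tidy(empty)), 0)
})

test_that("KS comparison equals the brute-force ECDF supremum", {
  expect_equal(compare_distributions(1:5, 1:5)$statistic, 0)
  expect_equal(compare_distributions(1:5, 6:10)$statistic, 1)

  set.seed(42)
  a <- rnorm(100); b <- rnorm(100, 0.4)
  got <- compare_distributions(a, b)
  # oracle: max ECDF gap over all pooled points
  pooled <- sort(c(a, b))
  gap <- max(abs(vapply(pooled, function(x) mean(a <= x) - mean(b <= x),
                        numeric(1))))
  expect_equal(got$statistic, gap, tolerance = 1e-12)
  expect_true(got$p.value > 0 && got$p.value < 1)
  expect_error(compare_distributions(numeric(0), 1:3),
               class = "gazestab_input_error")
})

test_that("sinusoidal-yaw acceleration samples follow the arcsine law", {
  # theta'' of A sin(w t) sampled densely is arcsine-distributed on
  # [-M, M]; the discrete second difference scales M by sinc^2(pi f / fps)
  A <- 10; f <- 1.7; fps <- 30; n <- 10000
  t <- (seq_len(n) - 1) / fps
  traj <- make_traj(cbind(0, 0)[rep(1, n), ], yaw = A * sin(2 * pi * f * t))
  kin <- compute_kinematics(traj)
  acc <- kin$head_ang_accel[10:(n - 10)]
  snc <- sin(pi * f / fps) / (pi * f / fps)
  M <- A * (2 * pi * f)^2 * snc^2
  arcsine_cdf <- function(x) 0.5 + asin(pmin(1, pmax(-1, x / M))) / pi
  ks <- suppressWarnings(stats::ks.test(acc, arcsine_cdf))
  expect_lt(unname(ks$statistic), 0.05)
})
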