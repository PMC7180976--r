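test_that("peak picking recovers a known sinusoid period", {
  t <- seq(0, 60, by = 0.01)
  ev <- detect_cycles(sin(2 * pi * t / 1.72), t = t)
  expect_gt(length(ev$periods), 30)
  expect_lt(abs(mean(ev$periods) - 1.72), 0.01)  # within one sample interval
  # offset invariance
  ev2 <- detect_cycles(5 + sin(2 * pi * t / 1.72), t = t)
  expect_identical(ev2$boundary_times, ev$boundary_times)
})

test_that("constant signals and ripple are handled", {
  expect_warning(ev <- detect_cycles(rep(1, 100), t = seq(0, 1, length.out = 100)),
                 "constant")
  expect_length(ev$periods, 0)
  # 5% high-frequency ripple must not split cycles
  t <- seq(0, 60, by = 0.01)
  x <- sin(2 * pi * t / 1.72) + 0.05 * sin(2 * pi * t * 6)
  ev3 <- detect_cycles(x, t = t)
  # ripple peaks rejected: one cycle per fundamental period, mean unchanged
  expect_lt(abs(mean(ev3$periods) - 1.72), 0.02)
  expect_lt(abs(length(ev3$periods) - 33), 2)
})

test_that("stroke metrics follow exact arithmetic", {
  ev <- structure(list(boundary_times = c(0, 1.72, 3.44, 5.16),
                       periods = rep(1.72, 3), peak_index = 1:4,
                       channel = "SFl"), class = "stroke_events")
  sm <- stroke_metrics(ev)
  expect_equal(sm$period_sd, 0)
  expect_equal(sm$stroke_rate, 60 / 1.72, tolerance = 1e-12)
  expect_equal(sm$stroke_rate * sm$period_mean, 60)
  ev2 <- structure(list(boundary_times = cumsum(c(0, 1.6, 1.7, 1.8)),
                        periods = c(1.6, 1.7, 1.8), peak_index = 1:4,
                        channel = "SFl"), class = "stroke_events")
  sm2 <- stroke_metrics(ev2)
  expect_equal(sm2$period_mean, 1.7)
  expect_equal(sm2$period_sd, 0.1)  # sample (n-1) convention
  ev1 <- ev; ev1$periods <- 1.72; ev1$boundary_times <- c(0, 1.72)
  expect_error(stroke_metrics(ev1), "insufficient")
})

test_that("phase labels give the propulsion/recovery ratio", {
  # 2:1 planted duty cycle, three cycles of 1.5 s at 100 Hz
  t <- seq(0, 4.5 - 0.01, by = 0.01)
  u <- (t %% 1.5) / 1.5
  lab <- tibble::tibble(t = t, phase = ifelse(u < 2 / 3, "propulsion", "recovery"))
  ev <- structure(list(boundary_times = c(0, 1.5, 3.0, 4.5),
                       periods = rep(1.5, 3), peak_index = 1:4,
                       channel = "SFl"), class = "stroke_events")
  sm <- stroke_metrics(ev, phase_labels = lab)
  expect_equal(sm$ratio_mean, 2.0)
  expect_equal(sm$ratio_sd, 0)
  expect_equal(sm$cycles$propulsion_s, rep(1.0, 3))
})

test_that("cycle statistics reproduce planted amplitudes and satisfy ROM = MAX - MIN", {
  t <- seq(0, 20, by = 0.01)
  A <- 0.7; m0 <- 1.1
  x <- m0 + A * cos(2 * pi * t / 2)
  ser <- tibble::tibble(t = t, SFl = x)
  ev <- detect_cycles(ser, channel = "SFl")
  cs <- cycle_statistics(ser, ev)
  st <- cs$stats
  expect_equal(st$mean[st$stat == "ROM"], 2 * A, tolerance = 1e-3)
  # the inclusive 0-100% phase axis counts the boundary peak twice,
  # biasing the cycle mean upward by ~A/101
  expect_equal(st$mean[st$stat == "MEAN"], m0, tolerance = 0.01)
  expect_lt(max(st$sd), 1e-6)
  expect_equal(cs$per_cycle$ROM, cs$per_cycle$MAX - cs$per_cycle$MIN)
  expect_equal(nrow(cs$curves), 101)
})

test_that("cycle statistics are invariant to a phase shift of the signal", {
  t <- seq(0, 24, by = 0.01)
  ser1 <- tibble::tibble(t = t, SFl = 1 + 0.5 * cos(2 * pi * t / 1.6))
  ser2 <- tibble::tibble(t = t, SFl = 1 + 0.5 * cos(2 * pi * (t - 0.37) / 1.6))
  s1 <- cycle_statistics(ser1, detect_cycles(ser1, "SFl"))$stats
  s2 <- cycle_statistics(ser2, detect_cycles(ser2, "SFl"))$stats
  expect_equal(s2$mean, s1$mean, tolerance = 1e-3)
})

test_that("cycle amplitude variability propagates into the ROM spread", {
  set.seed(10)
  pr <- rowing_profile(duration = 90, seed = 10, period_jitter_sd = 0,
                       amplitude_jitter_sd = 0.05)
  truth <- simulate_kinematics(pr, upper_body_model())
  ev <- detect_cycles(truth$angles, channel = "SFr")
  cs <- cycle_statistics(truth$angles[, c("t", "SFr")], ev)
  st <- cs$stats
  # ROM = 2 A (1 + eps): SD(ROM) ~ 2 * A * 0.05
  expected_sd <- 2 * 1.02 * 0.05
  expect_gt(st$sd[st$stat == "ROM"], expected_sd * 0.6)
  expect_lt(st$sd[st$stat == "ROM"], expected_sd * 1.5)
})

test_that("agreement analysis is exact on constructed cases", {
  set.seed(11)
  ref <- 1 + 0.5 * sin(seq(0, 20, by = 0.01))
  a <- compare_angle_series(ref, ref)
  expect_equal(a$slope, 1); expect_equal(a$intercept, 0)
  expect_equal(a$correlation, 1); expect_equal(a$bias, 0)
  b <- compare_angle_series(1.05 * ref, ref)
  expect_equal(b$slope, 1.05, tolerance = 1e-12)
  expect_equal(b$correlation, 1, tolerance = 1e-12)
  expect_error(compare_angle_series(ref, rep(1, length(ref))), "degenerate")
})

test_that("Bland-Altman limits approach +/-1.96 sigma for additive noise", {
  set.seed(12)
  ref <- 1 + 0.5 * sin(seq(0, 200, by = 0.01))
  sigma <- 0.05
  test <- ref + stats::rnorm(length(ref), 0, sigma)
  a <- compare_angle_series(test, ref)
  expect_lt(abs(a$bias), 0.005)
  expect_equal(a$loa_upper - a$bias, 1.96 * sigma, tolerance = 0.05)
  expect_equal(glance(a)$slope, a$slope)
})
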