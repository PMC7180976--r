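test_that("objective vanishes exactly at the true orientation", {
  expect_equal(fusion_objective(c(1, 0, 0, 0), c(0, 0, 1), c(0, 0, 1)),
               c(0, 0, 0))
  set.seed(1)
  for (i in 1:10) {
    q <- random_unit_quat()
    p_ref <- stats::rnorm(3)
    p_meas <- rotate_vector(quat_conjugate(q), p_ref / sqrt(sum(p_ref^2)))
    expect_lt(max(abs(fusion_objective(q, p_ref, p_meas))), 1e-12)
  }
  expect_error(fusion_objective(c(1, 0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
               "degenerate")
})

test_that("objective matches the component-wise sandwich expansion", {
  set.seed(2)
  for (i in 1:10) {
    q <- random_unit_quat()
    p_ref <- stats::rnorm(3); p_ref <- p_ref / sqrt(sum(p_ref^2))
    p_meas <- stats::rnorm(3); p_meas <- p_meas / sqrt(sum(p_meas^2))
    oracle <- quat_mult_oracle(quat_mult_oracle(quat_conjugate(q), c(0, p_ref)), q)[2:4] - p_meas
    expect_equal(fusion_objective(q, p_ref, p_meas), oracle, tolerance = 1e-12)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(3)
  h <- 1e-6
  for (i in 1:10) {
    q <- random_unit_quat()
    p_ref <- stats::rnorm(3); p_meas <- stats::rnorm(3)
    p_meas <- p_meas / sqrt(sum(p_meas^2))
    g <- fusion_gradient(q, p_ref, p_meas)
    fd <- vapply(1:4, function(k) {
      e <- numeric(4); e[k] <- h
      fp <- fusion_objective(q + e, p_ref, p_meas)
      fm <- fusion_objective(q - e, p_ref, p_meas)
      (sum(fp^2) - sum(fm^2)) / (4 * h)  # d(1/2 |f|^2)/dq_k
    }, 0)
    expect_equal(g, fd, tolerance = 1e-6)
  }
  # zero at the exact minimizer
  q <- random_unit_quat()
  p_meas <- rotate_vector(quat_conjugate(q), c(0, 0, 1))
  expect_lt(max(abs(fusion_gradient(q, c(0, 0, 1), p_meas))), 1e-10)
})

test_that("with zero gain the filter is pure gyro dead-reckoning", {
  st <- filter_state(xi = 0)
  for (i in 1:100) st <- fusion_step(st, c(0, 0, 1), c(0, 0, 0), c(0, 0, 0), 0.01)
  closed_form <- quat_from_axis_angle(c(0, 0, 1), 1.0)
  expect_lt(quat_angle_between(st$q, closed_form), 1e-3)
  expect_equal(quat_norm(st$q), 1, tolerance = 1e-12)
})

test_that("a stationary aligned node is a fixed point of the filter", {
  st <- filter_state(xi = 0.1, reference_mag = REF_MAG / sqrt(sum(REF_MAG^2)))
  for (i in 1:1000) st <- fusion_step(st, c(0, 0, 0), REF_GRAVITY, REF_MAG, 0.01)
  expect_lt(quat_angle_between(st$q, c(1, 0, 0, 0)), 1e-9)
})

test_that("static gradient descent converges monotonically from 30 degrees", {
  st <- filter_state(q = quat_from_axis_angle(c(1, 0, 0), pi / 6), xi = 0.1,
                     reference_mag = REF_MAG / sqrt(sum(REF_MAG^2)))
  errs <- numeric(200)
  for (i in 1:200) {
    st <- fusion_step(st, c(0, 0, 0), REF_GRAVITY, REF_MAG, 0.01)
    errs[i] <- quat_angle_between(st$q, c(1, 0, 0, 0))
  }
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[200], 0.5 * pi / 180)
  expect_equal(quat_norm(st$q), 1, tolerance = 1e-12)
})

test_that("NaN samples are rejected and the state carried", {
  st <- filter_state(xi = 0.1)
  st2 <- fusion_step(st, c(NA, 0, 0), REF_GRAVITY, REF_MAG, 0.01)
  expect_identical(st2$q, st$q)
})

test_that("a static stream stays within 0.2 degrees of initialization", {
  set.seed(4)
  q <- quat_from_axis_angle(c(0.3, 1, 0.2), 0.8)
  o <- fuse_imu(static_stream(q, n = 500))
  errs <- apply(as.matrix(o[, c("q0", "q1", "q2", "q3")]), 1,
                quat_angle_between, b = q)
  expect_lt(max(errs) * 180 / pi, 0.2)
  expect_equal(nrow(o), 500)
  norms <- sqrt(rowSums(as.matrix(o[, c("q0", "q1", "q2", "q3")])^2))
  expect_equal(norms, rep(1, 500), tolerance = 1e-9)
})

test_that("fuse_imu validates its input stream", {
  s <- static_stream(c(1, 0, 0, 0), n = 10)
  expect_error(fuse_imu(s[, -2]), "columns")
  s2 <- s; s2$t[5] <- s2$t[4]
  expect_error(fuse_imu(s2), "strictly increasing")
  expect_error(fuse_imu(s[0, ]), "empty|strictly|least")
})

test_that("doubling the sample rate barely changes the endpoint orientation", {
  m <- upper_body_model()
  endpoint <- function(rate) {
    pr <- rowing_profile(duration = 10, sample_rate = rate, seed = 20,
                         period_jitter_sd = 0, amplitude_jitter_sd = 0,
                         linear_accel = FALSE)
    truth <- simulate_kinematics(pr, m)
    streams <- imu_from_motion(truth)
    o <- fuse_imu(streams$upperarm_l)
    as.numeric(o[nrow(o), c("q0", "q1", "q2", "q3")])
  }
  expect_lt(quat_angle_between(endpoint(100), endpoint(200)) * 180 / pi, 0.1)
})
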