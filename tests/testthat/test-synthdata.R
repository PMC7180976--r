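test_that("the simulator honours its planted stroke structure", {
  m <- upper_body_model()
  pr <- rowing_profile(duration = 15, seed = 1, period_jitter_sd = 0,
                       amplitude_jitter_sd = 0)
  truth <- simulate_kinematics(pr, m)
  # zero jitter: every cycle exactly the stroke period
  expect_equal(unique(round(diff(truth$boundaries), 9)), 1.72)
  # duty cycle: per-sample propulsion/recovery fractions follow the profile
  ph <- truth$phase$phase[!is.na(truth$phase$phase)]
  ratio <- sum(ph == "propulsion") / sum(ph == "recovery")
  expect_equal(ratio, (2 / 3) / (1 / 3), tolerance = 0.05)
  # channel ROM equals twice the configured amplitude
  for (i in seq_len(nrow(pr$channels))) {
    ch <- pr$channels$channel[i]
    sel <- truth$angles$t > pr$static_time + pr$ramp_time
    rom <- diff(range(truth$angles[[ch]][sel]))
    expect_equal(rom, 2 * pr$channels$amplitude[i], tolerance = 1e-3)
  }
})

test_that("identical seeds give byte-identical simulations", {
  pr <- rowing_profile(duration = 5, seed = 7, gyro_noise_sd = 0.01,
                       accel_noise_sd = 0.05, mag_noise_sd = 0.005)
  m <- upper_body_model()
  t1 <- simulate_kinematics(pr, m); s1 <- imu_from_motion(t1)
  t2 <- simulate_kinematics(pr, m); s2 <- imu_from_motion(t2)
  expect_identical(t1$angles, t2$angles)
  expect_identical(s1, s2)
  pr2 <- pr; pr2$seed <- 8
  s3 <- imu_from_motion(simulate_kinematics(pr2, m))
  expect_false(identical(s1, s3))
})

test_that("the inverse sensor model reproduces static and constant-rate readings", {
  # static identity orientation: accel = gravity up, gyro = 0, mag = field
  m <- upper_body_model()
  pr <- rowing_profile(duration = 3, seed = 2,
                       channels = tibble::tibble(channel = character(),
                                                 amplitude = numeric(),
                                                 mean = numeric(),
                                                 phase = numeric()))
  truth <- simulate_kinematics(pr, m)
  s <- imu_from_motion(truth)$torso
  expect_equal(max(abs(c(s$gx, s$gy, s$gz))), 0)
  expect_equal(unique(round(s$az, 9)), 9.81)
  expect_equal(unique(round(s$my, 9)), round(0.5 * cos(pi / 3), 9))
  expect_equal(unique(round(s$mz, 9)), round(-0.5 * sin(pi / 3), 9))

  # constant 1 rad/s yaw: gyro reads (0, 0, 1) via finite differences
  # (400 Hz keeps the central-difference discretization error below 1e-6)
  n <- 301; tt <- (0:300) / 400
  pr <- rowing_profile(duration = 3, seed = 2, sample_rate = 400,
                       channels = tibble::tibble(channel = character(),
                                                 amplitude = numeric(),
                                                 mean = numeric(),
                                                 phase = numeric()))
  qm <- t(vapply(tt, function(t) quat_from_axis_angle(c(0, 0, 1), t), numeric(4)))
  fake <- structure(list(
    orientations = list(torso = tibble::tibble(t = tt, q0 = qm[, 1], q1 = qm[, 2],
                                               q2 = qm[, 3], q3 = qm[, 4])),
    angles = tibble::tibble(t = tt),
    phase = tibble::tibble(t = tt, cycle = 1L, phase = "propulsion"),
    boundaries = numeric(0), profile = pr, model = m), class = "rowing_truth")
  s2 <- imu_from_motion(fake, linear_accel = FALSE)$torso
  mid <- 10:290
  expect_lt(max(abs(s2$gz[mid] - 1)), 1e-6)
  expect_lt(max(abs(s2$gx[mid])), 1e-6)
  expect_lt(max(abs(s2$gy[mid])), 1e-6)
})

test_that("planted gyro bias and magnetic distortion appear in the streams", {
  m <- upper_body_model()
  S <- diag(c(1.1, 0.95, 1.0)); S[1, 2] <- S[2, 1] <- 0.03
  pr <- rowing_profile(duration = 3, seed = 3, gyro_bias = c(0.01, -0.02, 0.005),
                       hard_iron = c(0.3, -0.2, 0.1), soft_iron = S,
                       channels = tibble::tibble(channel = character(),
                                                 amplitude = numeric(),
                                                 mean = numeric(),
                                                 phase = numeric()))
  truth <- simulate_kinematics(pr, m)
  s <- imu_from_motion(truth)$torso
  expect_equal(s$gx[1], 0.01); expect_equal(s$gy[1], -0.02)
  mag_true <- 0.5 * c(0, cos(pi / 3), -sin(pi / 3))
  expected <- as.numeric(S %*% mag_true + c(0.3, -0.2, 0.1))
  expect_equal(c(s$mx[1], s$my[1], s$mz[1]), expected, tolerance = 1e-9)
})

test_that("calibration-acquisition samples cover the planted ellipsoid", {
  pr <- rowing_profile(seed = 4, hard_iron = c(0.30, -0.20, 0.10))
  samples <- simulate_mag_samples(pr, n = 400)
  cal <- fit_mag_calibration(samples)
  expect_equal(cal$hard_iron, c(0.30, -0.20, 0.10), tolerance = 1e-6)
  expect_equal(cal$field_magnitude, 0.5, tolerance = 1e-6)
})

test_that("the cohort generator yields labelled grouped stroke records", {
  co <- make_cohort(coach_profile(duration = 15), novice_profile(duration = 15),
                    n_trials = 2, n_participants = 2, seed = 5)
  expect_setequal(unique(co$features$label), c("coach", "novice"))
  expect_true(all(table(co$features$label) > 5))
  expect_equal(sum(grepl("^coach_p", unique(co$features$group))), 2)
  # 4 channels x 33 features
  expect_equal(length(feature_cols <- setdiff(names(co$features),
    c("record", "t_start", "t_end", "label", "group"))), 132)
  co2 <- make_cohort(coach_profile(duration = 15), novice_profile(duration = 15),
                     n_trials = 2, n_participants = 2, seed = 5)
  expect_identical(co$features, co2$features)
})
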