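test_that("the default body model is a valid 17-segment tree", {
  m <- default_body_model()
  expect_equal(nrow(m), 17)
  expect_equal(sum(is.na(m$parent)), 1)
  expect_equal(m$segment[is.na(m$parent)], "pelvis")
  d <- as.matrix(m[, c("rest_x", "rest_y", "rest_z")])
  expect_equal(unname(sqrt(rowSums(d^2))), rep(1, 17))
  expect_true(all(m$length > 0))
})

test_that("body-model validation rejects malformed trees", {
  m <- default_body_model()
  bad <- m; bad$parent[bad$segment == "pelvis"] <- "torso"
  expect_error(body_model(bad), "root|cycle")
  bad2 <- m; bad2$length[3] <- -1
  expect_error(body_model(bad2), "lengths")
  bad3 <- m; bad3$parent[5] <- "nonexistent"
  expect_error(body_model(bad3), "unknown parent")
})

test_that("body models round-trip through JSON", {
  m <- default_body_model(height = 1.83)
  f <- withr::local_tempfile(fileext = ".json")
  write_body_model(m, f)
  m2 <- read_body_model(f)
  expect_equal(as.data.frame(m2), as.data.frame(m), tolerance = 1e-12)
})

test_that("rest-pose forward kinematics places joints anthropometrically", {
  m <- default_body_model()
  pose <- forward_kinematics(m, list())
  expect_equal(nrow(pose), 17)
  # rigidity: inter-joint distance equals configured length, exactly
  d <- sqrt((pose$dx - pose$px)^2 + (pose$dy - pose$py)^2 + (pose$dz - pose$pz)^2)
  expect_equal(d, m$length[match(pose$segment, m$segment)], tolerance = 1e-12)
  # arm span at rest: clavicles stick out laterally, arms hang down
  expect_lt(pose$dz[pose$segment == "hand_l"],
            pose$pz[pose$segment == "upperarm_l"])
  expect_equal(pose$dx[pose$segment == "clavicle_l"],
               -pose$dx[pose$segment == "clavicle_r"])
})

test_that("rotating one upper arm moves only its own subtree", {
  m <- default_body_model()
  rest <- forward_kinematics(m, list())
  q90 <- quat_from_axis_angle(c(1, 0, 0), pi / 2)  # arm forward
  pose <- forward_kinematics(m, list(upperarm_l = q90))
  moved <- c("upperarm_l", "forearm_l", "hand_l")
  for (s in setdiff(m$segment, moved)) {
    expect_equal(unlist(pose[pose$segment == s, c("px", "py", "pz", "dx", "dy", "dz")]),
                 unlist(rest[rest$segment == s, c("px", "py", "pz", "dx", "dy", "dz")]),
                 tolerance = 1e-12)
  }
  # the elbow swings from straight down to straight forward (+Y)
  ua <- pose[pose$segment == "upperarm_l", ]
  expect_equal(ua$dy - ua$py, m$length[m$segment == "upperarm_l"],
               tolerance = 1e-12)
  expect_equal(ua$dz, ua$pz, tolerance = 1e-12)
  # uninstrumented children inherit the rotation
  expect_equal(unname(unlist(pose[pose$segment == "forearm_l",
                                  c("q0", "q1", "q2", "q3")])),
               q90, tolerance = 1e-12)
})

test_that("joint_angle matches the atan2 cross-product oracle", {
  expect_equal(joint_angle(c(1, 0, 0), c(0, 1, 0)), pi / 2)
  expect_equal(joint_angle(c(1, 1, 0), c(2, 2, 0)), 0, tolerance = 1e-7)
  expect_equal(joint_angle(c(1, 0, 0), c(-3, 0, 0)), pi)
  set.seed(1)
  for (i in 1:20) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    oracle <- atan2(sqrt(sum(cr^2)), sum(u * v))
    expect_equal(joint_angle(u, v), oracle, tolerance = 1e-12)
  }
  expect_error(joint_angle(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("static alignment calibration inverts planted mounting rotations", {
  m <- upper_body_model()
  qmount <- quat_from_axis_angle(c(0, 0, 1), pi / 2)  # node yawed on the limb
  # static pose: body frames identity, sensor reads q_S^G = (q_B^S)*
  qsg <- quat_conjugate(qmount)
  streams <- list()
  for (s in m$segment[!is.na(m$sensor_id)]) {
    qm <- if (s == "forearm_l") qsg else c(1, 0, 0, 0)
    streams[[s]] <- tibble::tibble(t = 0:4 / 100, q0 = qm[1], q1 = qm[2],
                                   q2 = qm[3], q3 = qm[4])
  }
  calib <- calibrate_alignment(streams, m)
  row <- as.numeric(calib[calib$segment == "forearm_l", c("q0", "q1", "q2", "q3")])
  expect_lt(quat_angle_between(row, qmount), 1e-10)
  # applying the calibration to the static sensor orientation gives identity
  expect_lt(quat_angle_between(segment_orientation(qsg, row), c(1, 0, 0, 0)), 1e-10)
  # identity mounting stays identity
  row2 <- as.numeric(calib[calib$segment == "torso", c("q0", "q1", "q2", "q3")])
  expect_equal(row2, c(1, 0, 0, 0))
  expect_error(calibrate_alignment(streams[-1], m), "pelvis")
})

test_that("joint angles are frame-invariant under a global rotation", {
  m <- upper_body_model()
  pr <- rowing_profile(duration = 6, seed = 31, period_jitter_sd = 0,
                       amplitude_jitter_sd = 0)
  truth <- simulate_kinematics(pr, m)
  ang0 <- suppressWarnings(compute_joint_angles(m, truth$orientations))
  g <- quat_from_axis_angle(c(0.2, 0.5, 1), 1.1)
  rotated <- lapply(truth$orientations, function(o) {
    qm <- as.matrix(o[, c("q0", "q1", "q2", "q3")])
    qr <- t(apply(qm, 1, function(q) quat_multiply(g, q)))
    tibble::tibble(t = o$t, q0 = qr[, 1], q1 = qr[, 2], q2 = qr[, 3], q3 = qr[, 4])
  })
  ang1 <- suppressWarnings(compute_joint_angles(m, rotated))
  for (ch in setdiff(names(ang0), "t"))
    expect_equal(ang1[[ch]], ang0[[ch]], tolerance = 1e-10)
})

test_that("prescribed joint-angle trajectories are reproduced from orientations", {
  m <- upper_body_model()
  pr <- rowing_profile(duration = 10, seed = 32, period_jitter_sd = 0.03)
  truth <- simulate_kinematics(pr, m)
  ang <- suppressWarnings(compute_joint_angles(m, truth$orientations))
  for (ch in c("SFl", "SFr", "EFl", "EFr")) {
    ref <- stats::approx(truth$angles$t, truth$angles[[ch]], xout = ang$t)$y
    expect_lt(sqrt(mean((ang[[ch]] - ref)^2)) * 180 / pi, 1e-6)
    expect_true(all(ang[[ch]] >= 0 & ang[[ch]] <= pi))
  }
})
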