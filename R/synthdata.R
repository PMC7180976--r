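# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Rowing-motion simulation profile
#'
#' Describes one simulated rower: the periodic stroke kinematics (period,
#' per-cycle period jitter, propulsion fraction of the cycle, per-channel
#' waveform amplitude/mean/phase) and the sensor imperfections of the
#' inverse IMU model (noise standard deviations, gyroscope bias, hard/soft
#' iron magnetic distortion). Joint-angle waveforms are two half-cosine arcs
#' per cycle: a propulsion sweep from the channel maximum to its minimum
#' over `propulsion_fraction` of the cycle, and a slower recovery return -
#' continuously differentiable, with exact phase labels. Defaults follow
#' the skilled-rower stroke observed in on-water canoeing: period 1.72 s
#' (SD 0.05 s), propulsion/recovery duty close to 2:1, and channel means
#' and amplitudes at the magnitudes reported for elbow/shoulder flexion.
#'
#' @param stroke_period Mean stroke period in seconds.
#' @param period_jitter_sd SD of per-cycle period jitter (s).
#' @param propulsion_fraction Fraction of the cycle spent in propulsion.
#' @param channels Tibble `channel, amplitude, mean, phase` (radians; phase
#'   as a fraction of the cycle).
#' @param amplitude_jitter_sd SD of per-cycle multiplicative amplitude
#'   jitter (fraction of the amplitude).
#' @param static_time Initial quasi-static standing interval (s) used for
#'   filter initialization and mounting calibration, before any motion.
#' @param ramp_time Smooth blend (s) from the standing pose into the first
#'   stroke cycle.
#' @param sample_rate Sampling rate, Hz.
#' @param duration Recording length, s (includes the warmup).
#' @param gyro_noise_sd,accel_noise_sd,mag_noise_sd Sensor noise SDs
#'   (rad/s, m/s^2, gauss).
#' @param gyro_bias Length-3 gyroscope bias, rad/s.
#' @param hard_iron Length-3 additive magnetic offset, gauss.
#' @param soft_iron 3x3 multiplicative magnetic distortion matrix.
#' @param mounting Named list (by segment) of unit quaternions `q_B^S`
#'   describing how each node is mounted on its segment (identity if
#'   absent).
#' @param linear_accel If `TRUE`, accelerometer readings include the linear
#'   acceleration of the sensor point (second finite difference of its
#'   position); if `FALSE` they observe gravity only, matching the filter's
#'   measurement model.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param mag_field,mag_dip Earth magnetic field magnitude (gauss) and dip
#'   angle (radians, downward positive).
#' @param seed Integer seed driving all randomness of the simulation.
#' @return A `rowing_profile` list.
#' @export
rowing_profile <- function(stroke_period = 1.72,
                           period_jitter_sd = 0.05,
                           propulsion_fraction = 2 / 3,
                           channels = NULL,
                           amplitude_jitter_sd = 0.02,
                           static_time = 2,
                           ramp_time = 1,
                           sample_rate = 100,
                           duration = 30,
                           gyro_noise_sd = 0,
                           accel_noise_sd = 0,
                           mag_noise_sd = 0,
                           gyro_bias = c(0, 0, 0),
                           hard_iron = c(0, 0, 0),
                           soft_iron = diag(3),
                           mounting = list(),
                           linear_accel = TRUE,
                           gravity = 9.81,
                           mag_field = 0.5,
                           mag_dip = pi / 3,
                           seed = NULL) {
  if (is.null(channels)) {
    channels <- tibble::tribble(
      ~channel, ~amplitude, ~mean, ~phase,
      "SFl", 0.80, 0.85, 0,
      "SFr", 1.02, 1.57, 0,
      "EFl", 0.53, 2.55, 0,
      "EFr", 0.30, 2.83, 0
    )
  }
  stopifnot(stroke_period > 0,
            propulsion_fraction > 0, propulsion_fraction < 1,
            sample_rate > 2 / stroke_period)
  structure(list(stroke_period = stroke_period,
                 period_jitter_sd = period_jitter_sd,
                 propulsion_fraction = propulsion_fraction,
                 channels = channels,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 static_time = static_time, ramp_time = ramp_time,
                 sample_rate = sample_rate, duration = duration,
                 gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 mag_noise_sd = mag_noise_sd,
                 gyro_bias = gyro_bias, hard_iron = hard_iron,
                 soft_iron = soft_iron, mounting = mounting,
                 linear_accel = linear_accel, gravity = gravity,
                 mag_field = mag_field, mag_dip = mag_dip, seed = seed),
            class = "rowing_profile")
}

#' Stock profiles: skilled and novice rower
#'
#' The skilled profile uses a 1.72 s stroke with 0.05 s period jitter and
#' tight amplitude consistency; the novice profile a 1.71 s stroke with
#' 0.08 s jitter and markedly larger cycle-to-cycle amplitude variability.
#'
#' @param ... Overrides passed to [rowing_profile()].
#' @return A `rowing_profile`.
#' @export
coach_profile <- function(...) {
  rowing_profile(stroke_period = 1.72, period_jitter_sd = 0.05,
                 propulsion_fraction = 0.664, amplitude_jitter_sd = 0.02, ...)
}

#' @rdname coach_profile
#' @export
novice_profile <- function(...) {
  rowing_profile(stroke_period = 1.71, period_jitter_sd = 0.08,
                 propulsion_fraction = 0.672, amplitude_jitter_sd = 0.10, ...)
}

# piecewise half-cosine stroke waveform on cycle phase u in [0,1)
stroke_wave <- function(u, pf) {
  ifelse(u < pf, cos(pi * u / pf), -cos(pi * (u - pf) / (1 - pf)))
}

#' Simulate ground-truth rowing kinematics
#'
#' Generates per-cycle periods (with jitter), evaluates the asymmetric
#' stroke waveform for every configured joint channel, and composes
#' consistent per-segment orientations down the body tree (torso and legs
#' quasi-static, arms driven by the shoulder/elbow channels about the
#' lateral axis). Joint angles recomputed from the returned orientations
#' reproduce the prescribed channel series exactly.
#'
#' @param profile A [rowing_profile()].
#' @param model A [body_model()] (default [default_body_model()]).
#' @return A `rowing_truth` list: `orientations` (named list of orientation
#'   tibbles per instrumented segment), `angles` (tibble `t` + channel
#'   columns), `phase` (tibble `t, cycle, phase`), `boundaries` (cycle
#'   start times), `profile`, `model`.
#' @export
simulate_kinematics <- function(profile, model = default_body_model()) {
  stopifnot(inherits(profile, "rowing_profile"))
  with_seed(profile$seed, {
    dt <- 1 / profile$sample_rate
    tt <- seq(0, profile$duration, by = dt)
    n <- length(tt)

    warmup <- profile$static_time + profile$ramp_time
    ts <- tt - warmup  # stroke clock: cycles start at 0

    k <- ceiling(profile$duration / (profile$stroke_period * 0.5)) + 2
    periods <- profile$stroke_period +
      stats::rnorm(k, 0, profile$period_jitter_sd)
    periods <- pmax(periods, 0.5 * profile$stroke_period)
    bounds <- c(0, cumsum(periods))
    cyc <- findInterval(pmax(ts, 0), bounds, rightmost.closed = FALSE)
    u <- (pmax(ts, 0) - bounds[cyc]) / periods[cyc]
    u[ts < 0] <- 0  # hold the catch pose through the warmup

    # blend from the standing rest pose into the stroke: 0 during the
    # static interval, smoothstep over the ramp, 1 while rowing
    b <- rep(1, n)
    b[tt < profile$static_time] <- 0
    ramp <- tt >= profile$static_time & tt < warmup
    if (profile$ramp_time > 0) {
      s <- (tt[ramp] - profile$static_time) / profile$ramp_time
      b[ramp] <- s * s * (3 - 2 * s)
    }

    amp_jit <- 1 + stats::rnorm(k, 0, profile$amplitude_jitter_sd)

    ch <- profile$channels
    if (!"rest" %in% names(ch) && nrow(ch))
      ch$rest <- ifelse(grepl("^SF", ch$channel), 0,
                 ifelse(grepl("^FF", ch$channel), pi / 2, pi))
    angles <- tibble::tibble(t = tt)
    for (i in seq_len(nrow(ch))) {
      ui <- (u + ch$phase[i]) %% 1
      a <- ch$amplitude[i] * amp_jit[cyc]
      th <- ch$mean[i] + a * stroke_wave(ui, profile$propulsion_fraction)
      th <- ch$rest[i] + b * (th - ch$rest[i])
      angles[[ch$channel[i]]] <- pmin(pi, pmax(0, th))
    }

    phase <- tibble::tibble(
      t = tt, cycle = ifelse(ts < 0, 0L, cyc),
      phase = ifelse(ts < 0, NA_character_,
                     ifelse(u < profile$propulsion_fraction,
                            "propulsion", "recovery")))

    # compose segment orientations: rotations about the lateral (East) axis
    ident <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
    axis_x_quats <- function(theta)
      cbind(cos(theta / 2), sin(theta / 2), 0, 0)
    orient <- list()
    statics <- intersect(model$segment[!is.na(model$sensor_id)],
                         c("pelvis", "torso", "thigh_l", "thigh_r",
                           "shank_l", "shank_r", "foot_l", "foot_r"))
    for (s in statics) orient[[s]] <- ident
    arm <- function(side) {
      sf <- angles[[paste0("SF", side)]]
      ef <- angles[[paste0("EF", side)]]
      ua <- paste0("upperarm_", side); fa <- paste0("forearm_", side)
      if (!is.null(sf) && ua %in% model$segment)
        orient[[ua]] <<- axis_x_quats(sf)
      if (!is.null(sf) && !is.null(ef) && fa %in% model$segment)
        orient[[fa]] <<- axis_x_quats(sf + pi - ef)
    }
    arm("l"); arm("r")

    orientations <- lapply(orient, function(qm) orientation_tibble(tt, qm))

    structure(list(orientations = orientations, angles = angles,
                   phase = phase,
                   boundaries = warmup + bounds[bounds <= profile$duration - warmup],
                   profile = profile, model = model),
              class = "rowing_truth")
  })
}

# vectorized rotation of a fixed vector by n quaternions (rows of Q)
rotate_rows <- function(Q, v) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  t1 <- 2 * (y * v[3] - z * v[2])
  t2 <- 2 * (z * v[1] - x * v[3])
  t3 <- 2 * (x * v[2] - y * v[1])
  cbind(v[1] + w * t1 + (y * t3 - z * t2),
        v[2] + w * t2 + (z * t1 - x * t3),
        v[3] + w * t3 + (x * t2 - y * t1))
}

# sensor-point (segment midpoint) positions for every segment, vectorized
sensor_positions <- function(model, orient, n) {
  ord <- model_topo_order(model)
  prox <- list(); dist <- list(); qs <- list()
  mid <- list()
  for (s in ord) {
    row <- model[model$segment == s, ]
    Q <- orient[[s]]
    if (is.null(Q)) {
      Q <- if (is.na(row$parent)) matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
           else qs[[row$parent]]
    }
    qs[[s]] <- Q
    p <- if (is.na(row$parent)) matrix(0, n, 3)
         else if (identical(row$attach, "proximal")) prox[[row$parent]]
         else dist[[row$parent]]
    d <- p + row$length * rotate_rows(Q, c(row$rest_x, row$rest_y, row$rest_z))
    prox[[s]] <- p; dist[[s]] <- d
    mid[[s]] <- (p + d) / 2
  }
  mid
}

#' Render ground-truth motion into raw IMU streams
#'
#' The inverse sensor model: for each instrumented segment the gyroscope
#' reads the sensor-frame angular rate (vector part of `2 q* qdot`, by
#' central finite differences), the accelerometer the inverse-rotated
#' gravity reaction plus (optionally) the linear acceleration of the sensor
#' point, and the magnetometer the inverse-rotated earth field passed
#' through the soft-iron distortion plus the hard-iron offset. Gyro bias
#' and i.i.d. Gaussian noise are added per the profile; all randomness
#' derives from the profile seed.
#'
#' @param truth A [simulate_kinematics()] result.
#' @param linear_accel Override of the profile's `linear_accel` flag.
#' @return Named list (by segment) of IMU stream tibbles with columns
#'   `t, gx, gy, gz, ax, ay, az, mx, my, mz`.
#' @export
imu_from_motion <- function(truth, linear_accel = NULL) {
  stopifnot(inherits(truth, "rowing_truth"))
  pr <- truth$profile
  if (is.null(linear_accel)) linear_accel <- pr$linear_accel
  model <- truth$model
  tt <- truth$angles$t
  n <- length(tt)
  dt <- 1 / pr$sample_rate
  g_vec <- c(0, 0, pr$gravity)
  m_vec <- pr$mag_field * c(0, cos(pr$mag_dip), -sin(pr$mag_dip))

  # body orientations as matrices; apply mounting to get sensor orientations
  orient_b <- lapply(truth$orientations, as_quat_matrix)
  orient_s <- orient_b
  for (s in names(orient_s)) {
    qbs <- pr$mounting[[s]]
    if (!is.null(qbs)) {
      qsb <- quat_conjugate(qbs)  # q_S^G = q_B^G x (q_B^S)*
      orient_s[[s]] <- t(apply(orient_b[[s]], 1, function(q) quat_multiply(q, qsb)))
    }
  }

  mids <- if (linear_accel) sensor_positions(model, orient_b, n) else NULL

  seed2 <- if (is.null(pr$seed)) NULL else pr$seed + 1L
  with_seed(seed2, {
    out <- list()
    for (s in names(orient_s)) {
      Q <- orient_s[[s]]
      # angular rate from quaternion central differences
      Qd <- Q
      Qd[2:(n - 1), ] <- (Q[3:n, ] - Q[1:(n - 2), ]) / (2 * dt)
      Qd[1, ] <- (Q[2, ] - Q[1, ]) / dt
      Qd[n, ] <- (Q[n, ] - Q[n - 1, ]) / dt
      gyro <- 2 * cbind(
        -Q[, 2] * Qd[, 1] + Q[, 1] * Qd[, 2] + Q[, 4] * Qd[, 3] - Q[, 3] * Qd[, 4],
        -Q[, 3] * Qd[, 1] - Q[, 4] * Qd[, 2] + Q[, 1] * Qd[, 3] + Q[, 2] * Qd[, 4],
        -Q[, 4] * Qd[, 1] + Q[, 3] * Qd[, 2] - Q[, 2] * Qd[, 3] + Q[, 1] * Qd[, 4])

      acc_g <- matrix(rep(g_vec, each = n), ncol = 3)
      if (linear_accel) {
        p <- mids[[s]]
        a_lin <- matrix(0, n, 3)
        a_lin[2:(n - 1), ] <- (p[3:n, ] - 2 * p[2:(n - 1), ] + p[1:(n - 2), ]) / dt^2
        acc_g <- acc_g + a_lin
      }
      # inverse rotation: rotate by conjugate rows
      Qc <- cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])
      accel <- rotate_rows_mat(Qc, acc_g)
      mag_s <- rotate_rows_mat(Qc, matrix(rep(m_vec, each = n), ncol = 3))
      mag <- mag_s %*% t(pr$soft_iron)
      mag <- sweep(mag, 2, pr$hard_iron, "+")

      gyro <- sweep(gyro, 2, pr$gyro_bias, "+")
      if (pr$gyro_noise_sd > 0)
        gyro <- gyro + matrix(stats::rnorm(3 * n, 0, pr$gyro_noise_sd), n, 3)
      if (pr$accel_noise_sd > 0)
        accel <- accel + matrix(stats::rnorm(3 * n, 0, pr$accel_noise_sd), n, 3)
      if (pr$mag_noise_sd > 0)
        mag <- mag + matrix(stats::rnorm(3 * n, 0, pr$mag_noise_sd), n, 3)

      out[[s]] <- tibble::tibble(t = tt,
                                 gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
                                 ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                                 mx = mag[, 1], my = mag[, 2], mz = mag[, 3])
    }
    out
  })
}

#' Simulate a magnetometer calibration acquisition
#'
#' Emulates the dedicated calibration routine performed before capture:
#' the node is waved through uniformly random orientations while reading
#' the earth field, so the raw samples cover the full distorted ellipsoid
#' (rowing motion alone rotates mostly about one axis and does not give
#' usable coverage). Distortion and noise follow the profile.
#'
#' @param profile A [rowing_profile()] supplying field, distortion and
#'   noise parameters.
#' @param n Number of samples (default 500).
#' @param seed Seed (defaults to the profile seed).
#' @return Tibble with columns `mx, my, mz` (gauss, raw/distorted).
#' @export
simulate_mag_samples <- function(profile, n = 500, seed = profile$seed) {
  m_vec <- profile$mag_field * c(0, cos(profile$mag_dip), -sin(profile$mag_dip))
  with_seed(seed, {
    Q <- matrix(stats::rnorm(4 * n), n, 4)
    Q <- Q / sqrt(rowSums(Q^2))
    Qc <- cbind(Q[, 1], -Q[, 2], -Q[, 3], -Q[, 4])
    mag_s <- rotate_rows_mat(Qc, matrix(rep(m_vec, each = n), ncol = 3))
    mag <- mag_s %*% t(profile$soft_iron)
    mag <- sweep(mag, 2, profile$hard_iron, "+")
    if (profile$mag_noise_sd > 0)
      mag <- mag + matrix(stats::rnorm(3 * n, 0, profile$mag_noise_sd), n, 3)
    tibble::tibble(mx = mag[, 1], my = mag[, 2], mz = mag[, 3])
  })
}

# rotate row i of V by quaternion row i of Q (both n-row matrices)
rotate_rows_mat <- function(Q, V) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  t1 <- 2 * (y * V[, 3] - z * V[, 2])
  t2 <- 2 * (z * V[, 1] - x * V[, 3])
  t3 <- 2 * (x * V[, 2] - y * V[, 1])
  cbind(V[, 1] + w * t1 + (y * t3 - z * t2),
        V[, 2] + w * t2 + (z * t1 - x * t3),
        V[, 3] + w * t3 + (x * t2 - y * t1))
}

#' Simulate a labelled skilled/novice cohort
#'
#' Simulates `n_trials` recordings per class, assigning trials round-robin
#' to `n_participants` simulated participants per class, extracts
#' per-stroke feature records (shoulder-peak to shoulder-peak) from the
#' ground-truth joint angles of the four upper-limb channels, and returns
#' them with class labels and participant ids - the input expected by the
#' proficiency classifiers.
#'
#' @param coach_profile,novice_profile [rowing_profile()]s for the two
#'   classes.
#' @param n_trials Recordings per class.
#' @param n_participants Simulated participants per class.
#' @param seed Integer seed.
#' @param angle_noise_sd Measurement noise added to the angle series before
#'   feature extraction (rad).
#' @return A list: `features` (tibble of per-stroke features with `label`
#'   and `group` columns), `trials` (tibble of per-trial metadata).
#' @export
make_cohort <- function(coach_profile = coach_profile(),
                        novice_profile = novice_profile(),
                        n_trials = 8, n_participants = 4, seed = 1,
                        angle_noise_sd = 0.01) {
  profs <- list(coach = coach_profile, novice = novice_profile)
  rows <- list(); meta <- list()
  for (cls in names(profs)) {
    for (i in seq_len(n_trials)) {
      pr <- profs[[cls]]
      pr$seed <- (if (is.null(seed)) 0L else seed) * 1000L +
        (match(cls, names(profs)) - 1L) * 500L + i
      truth <- simulate_kinematics(pr)
      ang <- truth$angles
      chs <- intersect(names(ang), c("SFl", "SFr", "EFl", "EFr"))
      with_seed(pr$seed + 7L, {
        for (ch in chs) ang[[ch]] <- ang[[ch]] + stats::rnorm(nrow(ang), 0, angle_noise_sd)
      })
      ev <- detect_cycles(ang, channel = "SFl")
      fm <- build_feature_matrix(ang, channels = chs, mode = "strokes",
                                 events = ev, sample_rate = pr$sample_rate)
      if (nrow(fm) == 0) next
      fm$label <- cls
      fm$group <- paste0(cls, "_p", ((i - 1L) %% n_participants) + 1L)
      rows[[paste(cls, i)]] <- fm
      meta[[paste(cls, i)]] <- tibble::tibble(
        trial = i, label = cls, group = fm$group[1], n_strokes = nrow(fm))
    }
  }
  list(features = dplyr::bind_rows(rows), trials = dplyr::bind_rows(meta))
}
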