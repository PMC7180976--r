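# shared fixtures and independent oracles used across test files

REF_DIP <- pi / 3
REF_GRAVITY <- c(0, 0, 9.81)
REF_MAG <- 0.5 * c(0, cos(REF_DIP), -sin(REF_DIP))

# independent Hamilton-product oracle: left-multiplication 4x4 matrix
quat_mult_oracle <- function(a, b) {
  L <- rbind(c(a[1], -a[2], -a[3], -a[4]),
             c(a[2],  a[1], -a[4],  a[3]),
             c(a[3],  a[4],  a[1], -a[2]),
             c(a[4], -a[3],  a[2],  a[1]))
  as.numeric(L %*% b)
}

# independent rotation oracle: Rodrigues formula from the axis-angle form
rotation_oracle <- function(q, v) {
  ang <- 2 * acos(max(-1, min(1, q[1])))
  if (ang < 1e-14) return(v)
  ax <- q[2:4] / sqrt(sum(q[2:4]^2))
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  as.numeric(R %*% v)
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# points uniformly distributed on a sphere of given radius
sphere_points <- function(n, radius = 1) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u / sqrt(rowSums(u^2)) * radius
}

# static IMU stream for a node at a fixed orientation (SCS -> GCS q)
static_stream <- function(q, n = 200, rate = 100) {
  accel <- rotate_vector(quat_conjugate(q), REF_GRAVITY)
  mag <- rotate_vector(quat_conjugate(q), REF_MAG)
  tibble::tibble(t = (seq_len(n) - 1) / rate,
                 gx = 0, gy = 0, gz = 0,
                 ax = accel[1], ay = accel[2], az = accel[3],
                 mx = mag[1], my = mag[2], mz = mag[3])
}

# simulate -> sensors -> calibrate -> fuse -> angles; returns per-channel
# RMSE (degrees) against the prescribed ground truth after convergence
round_trip_rmse <- function(profile, cal = NULL, model = upper_body_model(),
                            settle = 4) {
  truth <- simulate_kinematics(profile, model)
  streams <- imu_from_motion(truth)
  orients <- lapply(streams, fuse_imu, cal = cal)
  static <- lapply(orients, function(o) o[o$t <= profile$static_time, ])
  calib <- calibrate_alignment(static, model)
  ang <- suppressWarnings(compute_joint_angles(model, orients, calib))
  sel <- ang$t > settle
  chans <- intersect(c("SFl", "SFr", "EFl", "EFr"), names(ang))
  vapply(chans, function(ch) {
    ref <- stats::approx(truth$angles$t, truth$angles[[ch]], xout = ang$t[sel])$y
    sqrt(mean((ang[[ch]][sel] - ref)^2)) * 180 / pi
  }, 0)
}

# small separable / shuffled two-class feature sets for classifier tests;
# the informative dimension has its tails clipped so the planted property
# (linear separability at 6 sigma class distance) holds for every draw
gaussian_dataset <- function(n = 120, p = 5, sep = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[, 1] <- pmin(pmax(X[, 1], -2), 2) + ifelse(y == "a", 0, sep)
  d <- tibble::as_tibble(as.data.frame(X))
  names(d) <- paste0("f", seq_len(p))
  d$label <- y
  d$group <- paste0(y, "_g", rep(rep(1:4, length.out = n / 2), 2))
  d
}
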