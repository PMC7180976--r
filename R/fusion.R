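#' Orientation-filter objective function
#'
#' Residual between a reference field direction known in the ground frame
#' and its measurement in the sensor frame, under a candidate orientation:
#' the vector part of `q* x [0, p_ref] x q - [0, p_meas]`. Zero exactly when
#' `q` (SCS to GCS) maps the measured direction onto the reference.
#'
#' @param q Unit quaternion (SCS to GCS).
#' @param p_ref Reference field direction in GCS (normalized internally).
#' @param p_meas Measured field direction in SCS (normalized internally).
#' @return Length-3 residual vector.
#' @export
fusion_objective <- function(q, p_ref, p_meas) {
  nr <- sqrt(sum(p_ref^2)); nm <- sqrt(sum(p_meas^2))
  if (nr < .Machine$double.eps || nm < .Machine$double.eps)
    stop("degenerate observation: zero-norm field vector")
  # raw bilinear sandwich (no renormalization of q), so the analytic
  # Jacobian of fusion_gradient() is exactly its derivative
  P <- c(0, p_ref / nr)
  quat_multiply(quat_multiply(quat_conjugate(q), P), q)[2:4] - p_meas / nm
}

#' Gradient of the orientation-filter objective
#'
#' Returns `t(J) %*% f` where `J` is the 3x4 Jacobian of
#' [fusion_objective()] with respect to the quaternion components. The
#' sandwich product is bilinear in `q`, so each Jacobian column is computed
#' exactly as `vec(e_k* x P x q + q* x P x e_k)`.
#'
#' @inheritParams fusion_objective
#' @return Length-4 gradient vector.
#' @export
fusion_gradient <- function(q, p_ref, p_meas) {
  nr <- sqrt(sum(p_ref^2)); nm <- sqrt(sum(p_meas^2))
  if (nr < .Machine$double.eps || nm < .Machine$double.eps)
    stop("degenerate observation: zero-norm field vector")
  p <- p_ref / nr
  w <- q[1]; u <- q[2:4]
  uxp <- c(u[2] * p[3] - u[3] * p[2], u[3] * p[1] - u[1] * p[3],
           u[1] * p[2] - u[2] * p[1])
  # r = (w^2 - |u|^2) p + 2 (p.u) u - 2 w (u x p); closed-form Jacobian
  f <- (w^2 - sum(u^2)) * p + 2 * sum(p * u) * u - 2 * w * uxp - p_meas / nm
  J <- matrix(0, 3, 4)
  J[, 1] <- 2 * (w * p - uxp)
  ecross <- rbind(c(0, -p[3], p[2]), c(p[3], 0, -p[1]), c(-p[2], p[1], 0))
  for (k in 1:3) {
    ek <- c(0, 0, 0); ek[k] <- 1
    J[, k + 1] <- 2 * (p[k] * u + sum(p * u) * ek - u[k] * p - w * ecross[k, ])
  }
  as.numeric(crossprod(J, f))
}

#' Create an orientation-filter state
#'
#' @param q Initial unit quaternion (SCS to GCS).
#' @param xi Per-step correction gain (dimensionless, default 0.1).
#' @param reference_gravity Up direction in GCS (default `c(0, 0, 1)`).
#' @param reference_mag Magnetic field direction in GCS, conventionally in
#'   the North-Up plane.
#' @return A `filter_state` list.
#' @export
filter_state <- function(q = c(1, 0, 0, 0), xi = 0.1,
                         reference_gravity = c(0, 0, 1),
                         reference_mag = c(0, cos(pi / 3), -sin(pi / 3))) {
  structure(list(q = quat_normalize(q), xi = xi,
                 reference_gravity = reference_gravity,
                 reference_mag = reference_mag),
            class = "filter_state")
}

#' Single update of the gradient-descent orientation filter
#'
#' Propagates the orientation with the gyroscope quaternion rate
#' `qdot = 1/2 q x [0, omega]`, then corrects along the negative gradient of
#' the combined gravity + magnetic objective. The correction step is
#' `xi * grad / max(||grad||, 1)`: normalized (fixed length `xi`) far from
#' the minimum, proportional near it so that descent is monotone and the
#' filter has an exact fixed point at the true orientation. The result is
#' renormalized to unit norm.
#'
#' @param state A [filter_state()].
#' @param gyro Angular rate, rad/s, sensor frame.
#' @param accel Accelerometer reading, m/s^2, sensor frame.
#' @param mag Calibrated magnetometer reading, gauss, sensor frame.
#' @param dt Time step in seconds (> 0).
#' @return Updated `filter_state` with unit-norm `q`.
#' @export
fusion_step <- function(state, gyro, accel, mag, dt) {
  stopifnot(inherits(state, "filter_state"), dt > 0)
  if (any(!is.finite(c(gyro, accel, mag)))) return(state)  # reject, carry
  q <- state$q
  qdot <- 0.5 * quat_multiply(q, c(0, gyro))
  qp <- q + qdot * dt

  g <- c(0, 0, 0, 0)
  if (sum(accel^2) > 0)
    g <- g + fusion_gradient(qp, state$reference_gravity, accel)
  if (sum(mag^2) > 0)
    g <- g + fusion_gradient(qp, state$reference_mag, mag)
  gn <- sqrt(sum(g^2))
  if (gn > 0) qp <- qp - state$xi * g / max(gn, 1)
  state$q <- quat_normalize(qp)
  state
}

#' Run the orientation filter over an IMU stream
#'
#' Fuses a 9-DoF stream into a per-sample SCS-to-GCS orientation series.
#' The first `init_window` seconds are assumed quasi-static (the standing
#' calibration pose): accelerometer and magnetometer readings are averaged
#' to obtain the initial orientation via [quat_from_accel_mag()], and the
#' magnetic reference direction is taken as the initial-orientation image of
#' the mean magnetic measurement (which lies in the North-Up plane by
#' construction, avoiding yaw bias from an assumed dip angle).
#'
#' @param stream Tibble/data frame with columns `t` (s, strictly
#'   increasing), `gx, gy, gz` (rad/s), `ax, ay, az` (m/s^2),
#'   `mx, my, mz` (gauss).
#' @param cal Optional [fit_mag_calibration()] result applied to the
#'   magnetometer columns before fusing.
#' @param xi Per-step correction gain (default 0.1).
#' @param init_window Length of the initialization window in seconds
#'   (default 2).
#' @return A tibble with columns `t, q0, q1, q2, q3`; every row unit-norm,
#'   sign-continuous, first row with `q0 >= 0`.
#' @export
fuse_imu <- function(stream, cal = NULL, xi = 0.1, init_window = 2) {
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az", "mx", "my", "mz")
  if (!all(need %in% names(stream)))
    stop("IMU stream must have columns: ", paste(need, collapse = ", "))
  n <- nrow(stream)
  if (n == 0) stop("empty IMU stream")
  tt <- stream$t
  if (any(diff(tt) <= 0)) stop("IMU timestamps must be strictly increasing")

  M <- as.matrix(stream[, c("mx", "my", "mz")])
  if (!is.null(cal)) M <- apply_mag_calibration(M, cal)
  G <- as.matrix(stream[, c("gx", "gy", "gz")])
  A <- as.matrix(stream[, c("ax", "ay", "az")])

  init_idx <- which(tt <= tt[1] + init_window)
  if (length(init_idx) == 0) init_idx <- 1L
  a0 <- colMeans(A[init_idx, , drop = FALSE])
  m0 <- colMeans(M[init_idx, , drop = FALSE])
  q0 <- quat_from_accel_mag(a0, m0)
  ref_mag <- rotate_vector(q0, m0 / sqrt(sum(m0^2)))
  ref_mag[1] <- 0  # confine to the North-Up plane exactly
  ref_mag <- ref_mag / sqrt(sum(ref_mag^2))

  st <- filter_state(q = q0, xi = xi, reference_mag = ref_mag)
  out <- matrix(NA_real_, n, 4)
  out[1, ] <- st$q
  for (i in seq_len(n)[-1]) {
    st <- fusion_step(st, G[i, ], A[i, ], M[i, ], tt[i] - tt[i - 1])
    # sign continuity with the previous output
    qi <- st$q
    if (sum(qi * out[i - 1, ]) < 0) qi <- -qi
    out[i, ] <- qi
  }
  orientation_tibble(tt, out)
}
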