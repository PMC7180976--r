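#' Quaternion construction
#'
#' Quaternions are plain numeric vectors of length 4 in scalar-first order
#' `c(q0, q1, q2, q3)`, i.e. `q = q0 + q1*i + q2*j + q3*k`, using the
#' right-handed Hamilton product convention. Orientation quaternions map
#' sensor-frame (SCS) vectors into the ground frame (GCS, East-North-Up with
#' +Z up) via the sandwich product `q x [0,v] x q*`.
#'
#' @param q0,q1,q2,q3 Quaternion components (scalar part first).
#' @return Numeric vector of length 4.
#' @export
#' @examples
#' quat(1, 0, 0, 0)  # identity rotation
quat <- function(q0, q1 = 0, q2 = 0, q3 = 0) {
  if (length(q0) == 4 && missing(q1)) return(as.numeric(q0))
  c(q0, q1, q2, q3)
}

#' Hamilton product of two quaternions
#'
#' @param a,b Quaternions (length-4 numeric, scalar first).
#' @return The Hamilton product `a x b` as a length-4 numeric vector.
#' @export
#' @examples
#' quat_multiply(c(0, 1, 0, 0), c(0, 0, 1, 0))  # i x j = k
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate
#'
#' @param q Quaternion.
#' @return `q*`: the vector part negated.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Quaternion norm and normalization
#'
#' @param q Quaternion.
#' @return `quat_norm`: Euclidean norm. `quat_normalize`: unit quaternion.
#' @export
quat_norm <- function(q) sqrt(sum(q^2))

#' @rdname quat_norm
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
  q / n
}

#' Canonicalize quaternion sign
#'
#' `q` and `-q` encode the same rotation; estimation routines return the
#' representative with non-negative scalar part.
#' @param q Quaternion.
#' @return `q` or `-q`, with `q[1] >= 0`.
#' @export
quat_canonical <- function(q) if (q[1] < 0) -q else q

#' Rotate a 3-vector by a unit quaternion
#'
#' Computes the sandwich product `q x [0,v] x q*`, mapping sensor-frame
#' coordinates into the ground frame when `q` is an SCS-to-GCS orientation.
#' Use `quat_conjugate(q)` to rotate the other way.
#'
#' @param q Unit quaternion. Non-unit input is normalized with a warning.
#' @param v Numeric 3-vector.
#' @return The rotated 3-vector; its norm equals `|v|`.
#' @export
#' @examples
#' qz <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
#' rotate_vector(qz, c(1, 0, 0))  # ~ (0, 1, 0)
rotate_vector <- function(q, v) {
  n2 <- sum(q^2)
  if (abs(n2 - 1) > 1e-9) {
    warning("non-unit quaternion passed to rotate_vector(); normalizing")
    q <- q / sqrt(n2)
  }
  # expanded sandwich product, cheaper than two Hamilton products
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  t2 <- 2 * c(y * v[3] - z * v[2], z * v[1] - x * v[3], x * v[2] - y * v[1])
  v + w * t2 + c(y * t2[3] - z * t2[2], z * t2[1] - x * t2[3], x * t2[2] - y * t2[1])
}

#' Direction-cosine matrix of a unit quaternion
#'
#' Returns the 3x3 rotation matrix `R` with `R %*% v == rotate_vector(q, v)`.
#' @param q Unit quaternion.
#' @return 3x3 orthonormal matrix.
#' @export
quat_to_dcm <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#'
#' Shepperd's method; stable for all rotations.
#' @param R 3x3 rotation matrix.
#' @return Unit quaternion with non-negative scalar part.
#' @export
quat_from_dcm <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  quat_canonical(quat_normalize(q))
}

#' Unit quaternion from an axis and angle
#'
#' @param axis Rotation axis (any non-zero 3-vector; normalized internally).
#' @param angle Rotation angle in radians (right-hand rule).
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("zero rotation axis")
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

#' Angular distance between two orientations
#'
#' The rotation angle taking orientation `a` to orientation `b`, insensitive
#' to the quaternion double cover (`q` vs `-q`).
#'
#' @param a,b Unit quaternions.
#' @return Angle in radians, in `[0, pi]`; 0 iff `a == +/-b`.
#' @export
quat_angle_between <- function(a, b) {
  d <- abs(sum(a * b))
  2 * acos(min(1, d))
}

#' Initial orientation from accelerometer and magnetometer
#'
#' TRIAD-style construction of the SCS-to-GCS orientation from a static
#' accelerometer reading (gravity reaction, pointing up in sensor
#' coordinates) and a magnetometer reading. The result maps the measured
#' up-direction to GCS +Z and the measured magnetic field into the GCS
#' North-Up (Y-Z) plane, fixing heading. Invariant to positive scaling of
#' either input.
#'
#' @param accel Static accelerometer reading (m/s^2, sensor frame).
#' @param mag Calibrated magnetometer reading (gauss, sensor frame).
#' @return Unit quaternion (SCS to GCS) with non-negative scalar part.
#' @export
#' @examples
#' dip <- pi / 3
#' quat_from_accel_mag(c(0, 0, 9.81), c(0, cos(dip), -sin(dip)) * 0.5)
quat_from_accel_mag <- function(accel, mag) {
  na <- sqrt(sum(accel^2)); nm <- sqrt(sum(mag^2))
  if (na < .Machine$double.eps || nm < .Machine$double.eps)
    stop("degenerate observation: zero accelerometer or magnetometer vector")
  up_s <- accel / na
  m_s <- mag / nm
  east_s <- c(m_s[2] * up_s[3] - m_s[3] * up_s[2],
              m_s[3] * up_s[1] - m_s[1] * up_s[3],
              m_s[1] * up_s[2] - m_s[2] * up_s[1])
  ne <- sqrt(sum(east_s^2))
  if (ne < 1e-8)
    stop("degenerate observation: accelerometer and magnetometer are parallel")
  east_s <- east_s / ne
  north_s <- c(up_s[2] * east_s[3] - up_s[3] * east_s[2],
               up_s[3] * east_s[1] - up_s[1] * east_s[3],
               up_s[1] * east_s[2] - up_s[2] * east_s[1])
  # columns are the GCS basis vectors expressed in SCS; R maps SCS -> GCS
  S <- unname(cbind(east_s, north_s, up_s))
  quat_from_dcm(t(S))
}

#' Chordal mean of unit quaternions
#'
#' Averages a small set of nearby orientations by sign-aligning against the
#' first quaternion, taking the component-wise mean and renormalizing.
#' Adequate for static calibration windows where all inputs are close.
#'
#' @param qs Matrix with 4 columns (one quaternion per row), or a list of
#'   length-4 vectors.
#' @return Unit quaternion.
#' @export
quat_mean <- function(qs) {
  if (is.list(qs)) qs <- do.call(rbind, qs)
  qs <- as.matrix(qs)
  ref <- qs[1, ]
  sgn <- sign(qs %*% ref)
  sgn[sgn == 0] <- 1
  m <- colMeans(qs * as.numeric(sgn))
  quat_canonical(quat_normalize(m))
}

# internal: tibble <-> quaternion matrix helpers for orientation series
quat_cols <- c("q0", "q1", "q2", "q3")

as_quat_matrix <- function(df) {
  stopifnot(all(quat_cols %in% names(df)))
  as.matrix(df[, quat_cols])
}

orientation_tibble <- function(t, qmat) {
  tibble::tibble(t = t, q0 = qmat[, 1], q1 = qmat[, 2],
                 q2 = qmat[, 3], q3 = qmat[, 4])
}
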