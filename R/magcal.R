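#' Magnetometer calibration by ellipsoid fitting
#'
#' Body-worn magnetometers read the earth field distorted by an additive
#' hard-iron offset (magnetised material on or near the node) and a
#' multiplicative soft-iron distortion (permeable material warping the
#' field). Under rotation of the node through varied attitudes the distorted
#' readings lie on an ellipsoid; an algebraic least-squares quadric fit
#' recovers the ellipsoid centre (hard iron) and shape (soft iron).
#'
#' The fit solves, in the total-least-squares sense, for the quadric
#' `x'Ax + b'x + c = 0` through the samples (design-matrix singular vector
#' of smallest singular value), then extracts the centre `-A^{-1}b/2` and
#' the symmetric positive-definite correction `W = A^{1/2}` scaled to unit
#' determinant, so the correction is volume-preserving and free of
#' rotational ambiguity. `mode = "sphere"` restricts the fit to a sphere
#' (hard iron + single scale), the soft-iron term being small in typical
#' deployments.
#'
#' @param samples Data frame with columns `mx, my, mz` (gauss), or a
#'   3-column matrix. At least 9 samples with non-degenerate angular
#'   coverage are required.
#' @param mode `"ellipsoid"` (default, full 9-parameter fit) or `"sphere"`.
#' @return An object of class `mag_calibration`: a list with `hard_iron`
#'   (length-3 offset, gauss), `soft_iron` (3x3 SPD matrix, unit
#'   determinant), `field_magnitude` (mean corrected radius, gauss),
#'   `rms_residual` (gauss) and `mode`.
#' @export
#' @examples
#' set.seed(1)
#' u <- matrix(rnorm(300), ncol = 3)
#' u <- u / sqrt(rowSums(u^2)) * 0.5
#' fit_mag_calibration(data.frame(mx = u[, 1] + 0.3, my = u[, 2], mz = u[, 3]))
fit_mag_calibration <- function(samples, mode = c("ellipsoid", "sphere")) {
  mode <- match.arg(mode)
  M <- mag_sample_matrix(samples)
  if (nrow(M) < 9) stop("need at least 9 magnetometer samples")
  x <- M[, 1]; y <- M[, 2]; z <- M[, 3]
  # centre/scale for conditioning; undone after the fit
  mu <- colMeans(M); sc <- mean(sqrt(rowSums(sweep(M, 2, mu)^2)))
  if (sc < .Machine$double.eps) stop("degenerate magnetometer coverage (all samples identical)")
  xs <- (x - mu[1]) / sc; ys <- (y - mu[2]) / sc; zs <- (z - mu[3]) / sc

  if (mode == "ellipsoid") {
    D <- cbind(xs^2, ys^2, zs^2, xs * ys, xs * zs, ys * zs, xs, ys, zs, 1)
  } else {
    D <- cbind(xs^2 + ys^2 + zs^2, xs, ys, zs, 1)
  }
  sv <- svd(D)
  # degenerate coverage (e.g. coplanar samples) leaves more than one
  # near-null direction in the design matrix
  if (sv$d[1] < .Machine$double.eps || sv$d[ncol(D) - 1] / sv$d[1] < 1e-8)
    stop("degenerate magnetometer coverage: quadric fit is rank-deficient")
  v <- sv$v[, ncol(D)]

  if (mode == "ellipsoid") {
    A <- matrix(c(v[1], v[4] / 2, v[5] / 2,
                  v[4] / 2, v[2], v[6] / 2,
                  v[5] / 2, v[6] / 2, v[3]), 3, 3)
    b <- v[7:9]; cc <- v[10]
  } else {
    A <- diag(3) * v[1]
    b <- v[2:4]; cc <- v[5]
  }
  eA <- eigen(A, symmetric = TRUE)
  if (any(eA$values * sign(sum(eA$values)) <= 0))
    stop("degenerate magnetometer coverage: fitted quadric is not an ellipsoid")
  if (sum(eA$values) < 0) { A <- -A; b <- -b; cc <- -cc; eA$values <- -eA$values }

  centre_s <- as.numeric(solve(A, -b / 2))
  centre <- unname(centre_s * sc + mu)
  # unit-determinant SPD square root of A
  W <- eA$vectors %*% diag(sqrt(eA$values / prod(eA$values)^(1 / 3))) %*% t(eA$vectors)
  W <- (W + t(W)) / 2

  corrected <- sweep(M, 2, centre) %*% W
  radii <- sqrt(rowSums(corrected^2))
  structure(list(
    hard_iron = centre,
    soft_iron = W,
    field_magnitude = mean(radii),
    rms_residual = sqrt(mean((radii - mean(radii))^2)),
    mode = mode
  ), class = "mag_calibration")
}

mag_sample_matrix <- function(samples) {
  if (is.matrix(samples)) {
    stopifnot(ncol(samples) == 3)
    return(samples)
  }
  nm <- if (all(c("mx", "my", "mz") %in% names(samples))) c("mx", "my", "mz")
        else if (all(c("x", "y", "z") %in% names(samples))) c("x", "y", "z")
        else stop("magnetometer samples need columns mx/my/mz (or x/y/z)")
  as.matrix(samples[, nm])
}

#' Identity magnetometer calibration
#'
#' @param field_magnitude Nominal field magnitude in gauss.
#' @return A `mag_calibration` that leaves samples unchanged.
#' @export
identity_mag_calibration <- function(field_magnitude = 0.5) {
  structure(list(hard_iron = c(0, 0, 0), soft_iron = diag(3),
                 field_magnitude = field_magnitude, rms_residual = 0,
                 mode = "identity"), class = "mag_calibration")
}

#' Apply a magnetometer calibration
#'
#' Corrects raw readings as `soft_iron %*% (sample - hard_iron)`.
#'
#' @param samples Data frame with `mx, my, mz` columns, a 3-column matrix,
#'   or a single length-3 vector.
#' @param cal A `mag_calibration` object.
#' @return Same shape as the input, corrected.
#' @export
apply_mag_calibration <- function(samples, cal) {
  stopifnot(inherits(cal, "mag_calibration"))
  if (is.numeric(samples) && is.null(dim(samples)) && length(samples) == 3) {
    return(as.numeric(cal$soft_iron %*% (samples - cal$hard_iron)))
  }
  M <- mag_sample_matrix(samples)
  corrected <- sweep(M, 2, cal$hard_iron) %*% t(cal$soft_iron)
  if (is.matrix(samples)) return(corrected)
  out <- samples
  nm <- if (all(c("mx", "my", "mz") %in% names(samples))) c("mx", "my", "mz") else c("x", "y", "z")
  out[[nm[1]]] <- corrected[, 1]; out[[nm[2]]] <- corrected[, 2]; out[[nm[3]]] <- corrected[, 3]
  out
}

#' @export
print.mag_calibration <- function(x, ...) {
  cat("<mag_calibration> mode:", x$mode, "\n")
  cat("  hard iron (gauss): ", paste(signif(x$hard_iron, 4), collapse = ", "), "\n")
  cat("  field magnitude  : ", signif(x$field_magnitude, 4), "gauss\n")
  cat("  rms residual     : ", signif(x$rms_residual, 4), "gauss\n")
  invisible(x)
}

#' Read / write magnetometer calibrations as JSON
#'
#' @param cal A `mag_calibration`.
#' @param path File path.
#' @return `read_mag_calibration` returns a `mag_calibration`;
#'   `write_mag_calibration` returns `path` invisibly.
#' @export
write_mag_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "mag_calibration"))
  obj <- list(hard_iron = cal$hard_iron,
              soft_iron = as.numeric(cal$soft_iron),
              field_magnitude = cal$field_magnitude,
              rms_residual = cal$rms_residual,
              mode = cal$mode)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mag_calibration
#' @export
read_mag_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(hard_iron = as.numeric(obj$hard_iron),
                 soft_iron = matrix(as.numeric(obj$soft_iron), 3, 3),
                 field_magnitude = as.numeric(obj$field_magnitude),
                 rms_residual = as.numeric(obj$rms_residual),
                 mode = obj$mode), class = "mag_calibration")
}
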