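# Unit-quaternion utilities. Quaternions are stored as n x 4 numeric
# matrices with columns (w, x, y, z), scalar part first, Hamilton convention.

#' Quaternion Hamilton product
#'
#' Row-wise product of two quaternion arrays: `out[i, ] = a[i, ] \%q\% b[i, ]`.
#' Either argument may be a single quaternion (one row), which is recycled.
#'
#' @param a,b Numeric matrices with 4 columns `(w, x, y, z)`, or length-4
#'   vectors.
#' @return An n x 4 matrix of products.
#' @export
quat_multiply <- function(a, b) {
  a <- quat_as_matrix(a)
  b <- quat_as_matrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w = w, x = x, y = y, z = z)
}

#' Quaternion conjugate
#'
#' @param q Quaternion matrix (n x 4) or length-4 vector.
#' @return Matrix of conjugates `(w, -x, -y, -z)`.
#' @export
quat_conjugate <- function(q) {
  q <- quat_as_matrix(q)
  cbind(w = q[, 1], x = -q[, 2], y = -q[, 3], z = -q[, 4])
}

#' Axis-angle rotation quaternion
#'
#' Builds unit quaternions for rotations of `angle_deg` degrees about a fixed
#' axis. Vectorised over the angle.
#'
#' @param axis Length-3 unit vector (normalised internally).
#' @param angle_deg Numeric vector of rotation angles in degrees.
#' @return An n x 4 quaternion matrix.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  cbind(w = cos(half),
        x = sin(half) * axis[1],
        y = sin(half) * axis[2],
        z = sin(half) * axis[3])
}

#' Intrinsic X-Y'-Z'' Euler angles of a quaternion array
#'
#' Decomposes each rotation as `R = Rx(roll) Ry(pitch) Rz(yaw)` (intrinsic
#' rotations, column-vector convention). With the mediolateral axis mapped to
#' X, `roll` is the flexion-extension angle. A warning is raised near gimbal
#' lock (pitch within 1e-3 rad of +/- pi/2); values are still returned.
#'
#' @param q Unit-quaternion matrix (n x 4).
#' @return A list with numeric vectors `roll`, `pitch`, `yaw` in degrees.
#' @export
quat_to_euler_xyz <- function(q) {
  q <- quat_as_matrix(q)
  norms <- sqrt(rowSums(q^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("non-unit quaternion: norm deviates from 1 by more than 1e-6")
  }
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  r11 <- 1 - 2 * (y^2 + z^2)
  r12 <- 2 * (x * y - w * z)
  r13 <- 2 * (x * z + w * y)
  r23 <- 2 * (y * z - w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  pitch <- asin(pmin(1, pmax(-1, r13)))
  if (any(abs(abs(pitch) - pi / 2) < 1e-3)) {
    warning("Euler decomposition near gimbal lock (|pitch| ~ pi/2); ",
            "roll/yaw are ill-conditioned")
  }
  roll <- atan2(-r23, r33)
  yaw <- atan2(-r12, r11)
  deg <- 180 / pi
  list(roll = roll * deg, pitch = pitch * deg, yaw = yaw * deg)
}

quat_as_matrix <- function(q) {
  if (is.null(dim(q))) {
    stopifnot(length(q) == 4L)
    q <- matrix(q, nrow = 1L)
  }
  stopifnot(ncol(q) == 4L)
  q
}

quat_normalize <- function(q) {
  q <- quat_as_matrix(q)
  q / sqrt(rowSums(q^2))
}
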