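#' Quaternion to Euler angles (intrinsic Z-Y-X)
#'
#' Decomposes unit orientation quaternions into yaw-pitch-roll Euler angles
#' in the intrinsic Z-Y-X convention, with yaw the rotation about the
#' gravity-aligned vertical axis. Yaw and roll are unwrapped so a trial has
#' no artificial +/-180 degree jumps; this matters because the pelvic
#' component of the model differentiates yaw across a phase.
#'
#' @param quat n-by-4 matrix, columns (w, x, y, z), or a length-4 vector.
#' @param unwrap logical; unwrap the angle series (default `TRUE`).
#' @return data.frame with columns `roll`, `pitch`, `yaw` in degrees.
#' @export
quat_to_euler <- function(quat, unwrap = TRUE) {
  if (is.null(dim(quat))) quat <- matrix(quat, nrow = 1)
  quat <- as.matrix(quat)
  if (ncol(quat) != 4L) stop("quat must have 4 columns (w, x, y, z)")
  nrm <- sqrt(rowSums(quat^2))
  if (any(abs(nrm - 1) > 1e-3)) stop("non-unit quaternion beyond 1e-3 tolerance")
  quat <- quat / nrm
  w <- quat[, 1]; x <- quat[, 2]; y <- quat[, 3]; z <- quat[, 4]

  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  sp <- 2 * (w * y - z * x)
  sp <- pmin(pmax(sp, -1), 1)
  pitch <- asin(sp)
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))

  if (unwrap && length(yaw) > 1L) {
    yaw <- unwrap_angle(yaw); roll <- unwrap_angle(roll)
  }
  data.frame(roll = roll * 180 / pi, pitch = pitch * 180 / pi,
             yaw = yaw * 180 / pi)
}

#' Euler angles to quaternion (intrinsic Z-Y-X)
#'
#' Inverse of [quat_to_euler()]; exact round-trip for pitch in
#' (-90, 90) degrees.
#'
#' @param roll,pitch,yaw angles in degrees (vectors of equal length).
#' @return n-by-4 matrix of unit quaternions (w, x, y, z).
#' @export
euler_to_quat <- function(roll, pitch = 0, yaw = 0) {
  n <- max(length(roll), length(pitch), length(yaw))
  r <- rep_len(roll, n) * pi / 360   # half angles in radians
  p <- rep_len(pitch, n) * pi / 360
  yw <- rep_len(yaw, n) * pi / 360
  cr <- cos(r); sr <- sin(r); cp <- cos(p); sp <- sin(p)
  cy <- cos(yw); sy <- sin(yw)
  cbind(w = cy * cp * cr + sy * sp * sr,
        x = cy * cp * sr - sy * sp * cr,
        y = cy * sp * cr + sy * cp * sr,
        z = sy * cp * cr - cy * sp * sr)
}

#' Unwrap a phase/angle series
#'
#' Removes jumps larger than half a cycle from an angle series so it is
#' continuous; operates in radians.
#' @param x angle series in radians.
#' @param period full cycle, default `2*pi`.
#' @return unwrapped series.
#' @export
unwrap_angle <- function(x, period = 2 * pi) {
  d <- diff(x)
  jump <- round(d / period)
  x - c(0, cumsum(jump)) * period
}
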