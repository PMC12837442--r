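#' IMU recording container
#'
#' Bundles the synchronized sensor streams from a single lower-back IMU into
#' a validated object: 3-axis acceleration split into semantic channels
#' (anteroposterior, vertical, mediolateral), vertical-axis angular velocity,
#' orientation quaternions, and optionally pre-extracted roll/yaw Euler
#' angles. All downstream stages consume this object.
#'
#' @param t numeric vector of sample times in seconds, uniformly spaced.
#'   May be `NULL`, in which case it is derived from `fs`.
#' @param fs sampling rate in Hz (the reference hardware samples at 100 Hz).
#' @param acc_ap anteroposterior acceleration, m/s^2. This is the channel
#'   whose deceleration valleys mark initial contact and which is integrated
#'   to forward velocity.
#' @param acc_v vertical acceleration, m/s^2 (optional, carried for QC).
#' @param acc_ml mediolateral acceleration, m/s^2 (optional).
#' @param gyro_vert angular velocity about the vertical axis, rad/s. Its
#'   sign immediately after an initial contact encodes the stance limb.
#' @param quat n-by-4 matrix of unit quaternions, columns (w, x, y, z).
#' @param roll_deg,yaw_deg optional pre-extracted Euler angles in degrees;
#'   if absent they are derived from `quat` on demand.
#'
#' @return an object of class `imu_recording` (a list with the validated
#'   fields above plus `n`, the sample count).
#' @export
imu_recording <- function(t = NULL, fs, acc_ap, acc_v = NULL, acc_ml = NULL,
                          gyro_vert = NULL, quat = NULL,
                          roll_deg = NULL, yaw_deg = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  acc_ap <- as.numeric(acc_ap)
  n <- length(acc_ap)
  if (n < 2L) stop("recording too short: need at least 2 samples")
  if (is.null(t)) t <- seq(0, by = 1 / fs, length.out = n)
  t <- as.numeric(t)
  if (length(t) != n) stop("t and acc_ap must have equal length")
  dt <- diff(t)
  if (any(abs(dt - 1 / fs) > 1e-9))
    stop("non-uniform sampling: time steps deviate from 1/fs by more than 1e-9 s")

  chk <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != n) stop(sprintf("channel '%s' length (%d) != %d", nm, length(x), n))
    x
  }
  acc_v <- chk(acc_v, "acc_v"); acc_ml <- chk(acc_ml, "acc_ml")
  gyro_vert <- chk(gyro_vert, "gyro_vert")
  roll_deg <- chk(roll_deg, "roll_deg"); yaw_deg <- chk(yaw_deg, "yaw_deg")
  if (!is.null(quat)) {
    quat <- as.matrix(quat)
    if (nrow(quat) != n || ncol(quat) != 4L)
      stop("quat must be an n-by-4 matrix (w, x, y, z)")
    nrm <- sqrt(rowSums(quat^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("quaternions must be unit-norm within 1e-6")
  }

  structure(list(t = t, fs = fs, n = n,
                 acc_ap = acc_ap, acc_v = acc_v, acc_ml = acc_ml,
                 gyro_vert = gyro_vert, quat = quat,
                 roll_deg = roll_deg, yaw_deg = yaw_deg),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.2f s)\n",
              x$n, x$fs, x$n / x$fs))
  have <- names(Filter(Negate(is.null),
                       x[c("acc_ap", "acc_v", "acc_ml", "gyro_vert",
                           "quat", "roll_deg", "yaw_deg")]))
  cat("  channels:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

#' Subject anthropometrics
#'
#' Per-side leg length Lp (greater trochanter to sole, metres) and pelvic
#' radius rp (mid-sacrum to iliac crest, metres): the subject-specific
#' parameters of the step-length model. Warns when rp is not smaller than
#' the leg lengths, which is implausible human geometry.
#'
#' @param lp_right,lp_left leg length per side, m.
#' @param rp pelvic radius, m.
#' @param g gravitational acceleration, m/s^2.
#' @return object of class `subject_anthro`.
#' @export
subject_anthro <- function(lp_right, lp_left = lp_right, rp, g = 9.81) {
  vals <- c(lp_right = lp_right, lp_left = lp_left, rp = rp, g = g)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all anthropometric values must be positive and finite")
  if (rp >= min(lp_right, lp_left))
    warning("pelvic radius rp >= leg length; check units (both in metres)")
  structure(as.list(vals), class = "subject_anthro")
}

#' Read anthropometrics from a JSON sidecar
#'
#' Expects keys `lp_right`, `lp_left`, `rp` and optionally `g`.
#' @param path path to a JSON file.
#' @return `subject_anthro` object.
#' @export
read_anthro <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$lp_right) || is.null(x$rp))
    stop("anthropometrics JSON must contain at least lp_right and rp")
  subject_anthro(lp_right = x$lp_right,
                 lp_left = if (is.null(x$lp_left)) x$lp_right else x$lp_left,
                 rp = x$rp, g = if (is.null(x$g)) 9.81 else x$g)
}

#' Column dialect for recording files
#'
#' Maps file columns to the semantic channels of [imu_recording()]. Any
#' sensor axis layout is supported by naming which file column holds which
#' channel; `acc_unit = "g"` declares accelerations in g so the reader
#' converts to m/s^2. `quat_order` makes the quaternion component order in
#' the file explicit (the internal order is always w, x, y, z).
#'
#' @param time,acc_ap,acc_v,acc_ml,gyro_vert column names in the file
#'   (`NULL` to omit an optional channel).
#' @param quat character vector of 4 column names holding the quaternion.
#' @param quat_order permutation of `c("w","x","y","z")` giving the order
#'   of the `quat` columns.
#' @param roll,yaw optional columns with pre-extracted Euler angles (deg).
#' @param acc_unit `"mps2"` or `"g"`.
#' @param fs declared sampling rate in Hz; used when `time` is `NULL`.
#' @return a list of class `imu_dialect`.
#' @export
imu_dialect <- function(time = "t", acc_ap = "az", acc_v = "ay", acc_ml = "ax",
                        gyro_vert = "gz", quat = c("qw", "qx", "qy", "qz"),
                        quat_order = c("w", "x", "y", "z"),
                        roll = NULL, yaw = NULL,
                        acc_unit = c("mps2", "g"), fs = NULL) {
  acc_unit <- match.arg(acc_unit)
  if (!is.null(quat)) {
    if (length(quat) != 4L || !setequal(quat_order, c("w", "x", "y", "z")))
      stop("quat needs 4 columns and quat_order a permutation of w,x,y,z")
  }
  structure(list(time = time, acc_ap = acc_ap, acc_v = acc_v, acc_ml = acc_ml,
                 gyro_vert = gyro_vert, quat = quat, quat_order = quat_order,
                 roll = roll, yaw = yaw, acc_unit = acc_unit, fs = fs),
            class = "imu_dialect")
}

#' Read an IMU recording from a CSV file
#'
#' One row per sample, columns resolved through an [imu_dialect()]. The time
#' base is taken from the file's time column when present (validated for
#' uniformity; gaps larger than 2/fs are an error), otherwise from the
#' dialect's declared `fs`.
#'
#' @param path CSV path.
#' @param dialect an [imu_dialect()].
#' @return an [imu_recording()].
#' @export
read_recording <- function(path, dialect = imu_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) < 2L) stop("empty or too-short recording: ", path)
  need <- function(col, what) {
    if (is.null(col)) return(NULL)
    if (!col %in% names(df)) stop(sprintf("missing column '%s' (%s)", col, what))
    as.numeric(df[[col]])
  }
  tm <- if (!is.null(dialect$time) && dialect$time %in% names(df))
    as.numeric(df[[dialect$time]]) else NULL
  if (is.null(tm)) {
    if (is.null(dialect$fs)) stop("no time column and no declared fs in dialect")
    fs <- dialect$fs
  } else {
    dt <- diff(tm)
    fs <- 1 / stats::median(dt)
    if (any(dt > 2 / fs)) stop("non-uniform sampling: time gap exceeds 2/fs")
    if (any(abs(dt - 1 / fs) > 1e-6)) stop("non-uniform sampling detected")
    fs <- round(fs, 6)
  }
  conv <- if (dialect$acc_unit == "g") 9.81 else 1
  quat <- NULL
  if (!is.null(dialect$quat) && all(dialect$quat %in% names(df))) {
    quat <- as.matrix(df[dialect$quat])
    colnames(quat) <- dialect$quat_order
    quat <- quat[, c("w", "x", "y", "z"), drop = FALSE]
  }
  imu_recording(t = tm, fs = fs,
                acc_ap = need(dialect$acc_ap, "anteroposterior acceleration") * conv,
                acc_v = if (!is.null(dialect$acc_v) && dialect$acc_v %in% names(df))
                  as.numeric(df[[dialect$acc_v]]) * conv else NULL,
                acc_ml = if (!is.null(dialect$acc_ml) && dialect$acc_ml %in% names(df))
                  as.numeric(df[[dialect$acc_ml]]) * conv else NULL,
                gyro_vert = if (!is.null(dialect$gyro_vert) && dialect$gyro_vert %in% names(df))
                  as.numeric(df[[dialect$gyro_vert]]) else NULL,
                quat = quat,
                roll_deg = if (!is.null(dialect$roll)) need(dialect$roll, "roll") else NULL,
                yaw_deg = if (!is.null(dialect$yaw)) need(dialect$yaw, "yaw") else NULL)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_recording()] under the default dialect; round-trips all
#' channels losslessly (values printed at full double precision).
#' @param rec an [imu_recording()].
#' @param path output CSV path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(t = rec$t, az = rec$acc_ap)
  if (!is.null(rec$acc_v)) df$ay <- rec$acc_v
  if (!is.null(rec$acc_ml)) df$ax <- rec$acc_ml
  if (!is.null(rec$gyro_vert)) df$gz <- rec$gyro_vert
  if (!is.null(rec$quat)) {
    df$qw <- rec$quat[, 1]; df$qx <- rec$quat[, 2]
    df$qy <- rec$quat[, 3]; df$qz <- rec$quat[, 4]
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write step estimates to CSV
#'
#' One row per step with the pendular/pelvic decomposition per phase.
#' Round-trips losslessly with [read_steps()]. An empty table writes a
#' header-only file with a warning.
#'
#' @param steps data.frame of step estimates (as produced by
#'   [estimate_steps()] / [run_pipeline()]).
#' @param path output CSV path.
#' @export
write_steps <- function(steps, path) {
  cols <- c("step_index", "side", "t_ic", "t_ms", "t_ic_next",
            "L_pendular_E1", "L_pendular_E2", "L_pelvic_E1", "L_pelvic_E2",
            "L_total")
  if (nrow(steps) == 0L) warning("writing empty step table (header only)")
  miss <- setdiff(cols, names(steps))
  if (length(miss)) stop("step table missing columns: ", paste(miss, collapse = ", "))
  out <- steps[cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read step estimates written by [write_steps()]
#' @param path CSV path.
#' @return data.frame of steps.
#' @export
read_steps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$side <- as.character(df$side)
  df
}
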