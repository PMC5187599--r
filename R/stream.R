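# SensorStream container and CSV I/O.

#' Construct a synchronized sensor stream
#'
#' A `sensor_stream` bundles the raw channels of one walking trial: a time
#' base sampled at a constant rate, body->world orientation quaternions,
#' body-frame accelerometer readings, and the two foot-switch (FSR) contact
#' channels. Either the quaternion + body acceleration pair or the pre-rotated
#' reduced pair (`accel_z_world`, `pitch_deg`) may be supplied.
#'
#' @param t time stamps in seconds, strictly increasing with constant spacing.
#' @param fs sampling rate in Hz; inferred from `t` when missing.
#' @param quat `n x 4` matrix of unit quaternions `(w, x, y, z)`, or `NULL`.
#' @param accel_body `n x 3` matrix of body-frame accelerations (m/s^2), or
#'   `NULL`.
#' @param accel_z_world world-frame vertical acceleration (m/s^2), or `NULL`
#'   when `quat`/`accel_body` are given.
#' @param pitch_deg foot pitch in degrees, or `NULL` when `quat` is given.
#' @param fsr_heel,fsr_toe logical contact state per sample.
#' @return object of class `sensor_stream`.
#' @export
sensor_stream <- function(t, fs = NULL, quat = NULL, accel_body = NULL,
                          accel_z_world = NULL, pitch_deg = NULL,
                          fsr_heel, fsr_toe) {
  n <- length(t)
  if (n < 1L) stop("stream length must be >= 1", call. = FALSE)
  if (is.null(fs)) {
    if (n < 2L) stop("cannot infer fs from a single sample", call. = FALSE)
    fs <- 1 / mean(diff(t))
  }
  if (n > 1L) {
    dt <- diff(t)
    if (any(dt <= 0) || any(abs(dt - 1 / fs) > 1e-9))
      stop("t must be strictly increasing with constant spacing 1/fs",
           call. = FALSE)
  }
  if (!is.null(quat)) {
    quat <- .check_unit_quat(.quat_as_matrix(quat))
    if (nrow(quat) != n) stop("quat length mismatch", call. = FALSE)
  }
  if (!is.null(accel_body)) {
    accel_body <- as.matrix(accel_body)
    if (nrow(accel_body) != n || ncol(accel_body) != 3L)
      stop("accel_body must be n x 3", call. = FALSE)
  }
  has_raw <- !is.null(quat) && !is.null(accel_body)
  has_reduced <- !is.null(accel_z_world) && !is.null(pitch_deg)
  if (!has_raw && !has_reduced)
    stop("need quat + accel_body, or accel_z_world + pitch_deg", call. = FALSE)
  if (!is.null(accel_z_world) && length(accel_z_world) != n)
    stop("accel_z_world length mismatch", call. = FALSE)
  if (!is.null(pitch_deg) && length(pitch_deg) != n)
    stop("pitch_deg length mismatch", call. = FALSE)
  fsr_heel <- as.logical(fsr_heel); fsr_toe <- as.logical(fsr_toe)
  if (length(fsr_heel) != n || length(fsr_toe) != n)
    stop("FSR channel length mismatch", call. = FALSE)
  structure(list(t = as.numeric(t), fs = fs, quat = quat,
                 accel_body = accel_body,
                 accel_z_world = if (is.null(accel_z_world)) NULL
                                 else as.numeric(accel_z_world),
                 pitch_deg = if (is.null(pitch_deg)) NULL
                             else as.numeric(pitch_deg),
                 fsr_heel = fsr_heel, fsr_toe = fsr_toe),
            class = "sensor_stream")
}

#' @export
length.sensor_stream <- function(x) length(x$t)

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d samples @ %.6g Hz (%.2f s), %s dialect\n",
              length(x$t), x$fs, length(x$t) / x$fs,
              if (!is.null(x$quat)) "quaternion" else "reduced"))
  invisible(x)
}

#' Read / write sensor streams as CSV
#'
#' Two dialects are supported. Full: columns
#' `t,qw,qx,qy,qz,ax,ay,az,fsr_heel,fsr_toe` (quaternion + body-frame
#' accelerometer). Reduced, for pre-rotated data:
#' `t,accel_z_world,pitch_deg,fsr_heel,fsr_toe`. The dialect is detected from
#' the header on read and chosen from the available channels on write.
#'
#' @param path CSV file path (UTF-8, '.' decimal, header required).
#' @param fs sampling rate; inferred from the time column when missing.
#' @return `read_sensor_csv`: a [sensor_stream()]; `write_sensor_csv`: `path`,
#'   invisibly.
#' @export
read_sensor_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  full <- c("t", "qw", "qx", "qy", "qz", "ax", "ay", "az",
            "fsr_heel", "fsr_toe")
  reduced <- c("t", "accel_z_world", "pitch_deg", "fsr_heel", "fsr_toe")
  if (all(full %in% names(df))) {
    sensor_stream(t = df$t, fs = fs,
                  quat = as.matrix(df[, c("qw", "qx", "qy", "qz")]),
                  accel_body = as.matrix(df[, c("ax", "ay", "az")]),
                  fsr_heel = df$fsr_heel > 0, fsr_toe = df$fsr_toe > 0)
  } else if (all(reduced %in% names(df))) {
    sensor_stream(t = df$t, fs = fs,
                  accel_z_world = df$accel_z_world, pitch_deg = df$pitch_deg,
                  fsr_heel = df$fsr_heel > 0, fsr_toe = df$fsr_toe > 0)
  } else {
    stop("unrecognized sensor CSV header in ", path,
         ": need columns ", paste(full, collapse = ","),
         " or ", paste(reduced, collapse = ","), call. = FALSE)
  }
}

#' @rdname read_sensor_csv
#' @param stream a [sensor_stream()].
#' @export
write_sensor_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (!is.null(stream$quat) && !is.null(stream$accel_body)) {
    df <- data.frame(t = stream$t,
                     qw = stream$quat[, 1L], qx = stream$quat[, 2L],
                     qy = stream$quat[, 3L], qz = stream$quat[, 4L],
                     ax = stream$accel_body[, 1L],
                     ay = stream$accel_body[, 2L],
                     az = stream$accel_body[, 3L],
                     fsr_heel = as.integer(stream$fsr_heel),
                     fsr_toe = as.integer(stream$fsr_toe))
  } else {
    df <- data.frame(t = stream$t,
                     accel_z_world = stream$accel_z_world,
                     pitch_deg = stream$pitch_deg,
                     fsr_heel = as.integer(stream$fsr_heel),
                     fsr_toe = as.integer(stream$fsr_toe))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
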