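# Zero-velocity-update (ZUPT) vertical velocity estimation.
#
# Direct integration of vertical acceleration drifts; the foot is stationary
# in mid-stance, so velocity is re-anchored to zero at every detected
# zero-acceleration instance |a_z - g| < eps_g, with the two foot switches as
# a fail-safe detector when noise masks the primary rule.

#' ZUPT configuration
#'
#' @param eps_g zero-acceleration threshold (m/s^2): a sample is a candidate
#'   zero instance when `|a_z - g| < eps_g`. Tune on training data with
#'   [tune_eps_g()] so detections occur only in mid-stance.
#' @param g gravitational acceleration, m/s^2.
#' @param min_dwell minimum number of consecutive samples the condition must
#'   hold (25 ms at 200 Hz by default), rejecting single-sample noise
#'   crossings.
#' @param drift_mode `"linear_detrend"` distributes each zero-instance
#'   correction linearly over the interval since the previous instance
#'   (standard ZUPT practice); `"reset"` discards the accumulated velocity at
#'   the instance.
#' @return object of class `zupt_config`.
#' @export
zupt_config <- function(eps_g = 0.5, g = 9.81, min_dwell = 5L,
                        drift_mode = c("linear_detrend", "reset")) {
  drift_mode <- match.arg(drift_mode)
  if (!is.finite(eps_g) || eps_g <= 0) stop("eps_g must be > 0", call. = FALSE)
  if (min_dwell < 1L) stop("min_dwell must be >= 1", call. = FALSE)
  structure(list(eps_g = eps_g, g = g, min_dwell = as.integer(min_dwell),
                 drift_mode = drift_mode),
            class = "zupt_config")
}

# maximal runs of TRUE in a logical vector -> 2-col matrix [start, end]
.true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect zero-acceleration instances
#'
#' Primary rule: indices where `|a_z - g| < eps_g` holds for at least
#' `min_dwell` consecutive samples. Fail-safe: any stance period (both heel
#' and toe FSR ON) that contains no primary index contributes the midpoint
#' sample of its both-ON interval, so every stance period anchors the velocity
#' at least once.
#'
#' @param accel_z_world world-frame vertical acceleration series (m/s^2).
#' @param fsr_heel,fsr_toe logical contact series, same length.
#' @param cfg a [zupt_config()].
#' @return list with `indices` (sorted integer vector of all zero instances),
#'   `events` (list of integer vectors, one per contiguous instance group) and
#'   `failsafe` (logical per event: detected by the FSR fail-safe rather than
#'   the primary rule).
#' @export
detect_zero_accel_instances <- function(accel_z_world, fsr_heel, fsr_toe, cfg) {
  stopifnot(inherits(cfg, "zupt_config"))
  n <- length(accel_z_world)
  if (length(fsr_heel) != n || length(fsr_toe) != n)
    stop("series lengths differ", call. = FALSE)
  quiet <- abs(accel_z_world - cfg$g) < cfg$eps_g
  runs <- .true_runs(quiet)
  runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= cfg$min_dwell, ,
               drop = FALSE]
  primary <- if (nrow(runs)) {
    sort(unlist(lapply(seq_len(nrow(runs)),
                       function(i) runs[i, 1L]:runs[i, 2L])))
  } else integer(0)

  stance <- .true_runs(as.logical(fsr_heel) & as.logical(fsr_toe))
  failsafe_idx <- integer(0)
  if (nrow(stance)) {
    for (i in seq_len(nrow(stance))) {
      s <- stance[i, 1L]; e <- stance[i, 2L]
      if (!any(primary >= s & primary <= e))
        failsafe_idx <- c(failsafe_idx, as.integer(floor((s + e) / 2)))
    }
  }
  idx <- sort(unique(c(primary, failsafe_idx)))
  if (!length(idx))
    stop("no zero-velocity instance found: no primary detection and no ",
         "both-FSR-ON stance period; velocity cannot be anchored",
         call. = FALSE)
  grp <- cumsum(c(1L, diff(idx) > 1L))
  events <- split(idx, grp)
  names(events) <- NULL
  list(indices = idx, events = events,
       failsafe = vapply(events, function(ev)
         all(ev %in% failsafe_idx), logical(1)))
}

# cumulative trapezoidal integral of y sampled at spacing dt, starting at 0
.cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n == 1L) return(0)
  c(0, cumsum((y[-1L] + y[-n]) / 2)) * dt
}

#' Estimate vertical foot velocity with zero-velocity updates
#'
#' Integrates `a_z - g` by the trapezoidal rule and re-anchors the result to
#' exactly zero at every zero-acceleration instance. Between consecutive
#' instances the accumulated drift is either removed as a linear ramp
#' (`drift_mode = "linear_detrend"`, default) or discarded at the instance
#' (`"reset"`). Samples before the first instance are anchored by
#' back-propagating the first instance's correction.
#'
#' @param accel_z_world world-frame vertical acceleration (m/s^2).
#' @param zero_instances integer index vector (or the result of
#'   [detect_zero_accel_instances()]).
#' @param fs sampling rate, Hz.
#' @param cfg a [zupt_config()].
#' @return vertical velocity series, m/s, exactly 0 at every zero instance.
#' @export
estimate_vertical_velocity <- function(accel_z_world, zero_instances, fs, cfg) {
  stopifnot(inherits(cfg, "zupt_config"))
  if (is.list(zero_instances)) zero_instances <- zero_instances$indices
  zero_instances <- sort(unique(as.integer(zero_instances)))
  if (!length(zero_instances))
    stop("no zero-velocity instance: velocity cannot be anchored",
         call. = FALSE)
  n <- length(accel_z_world)
  if (any(zero_instances < 1L | zero_instances > n))
    stop("zero instance index out of range", call. = FALSE)
  v_raw <- .cumtrapz(accel_z_world - cfg$g, 1 / fs)
  v <- v_raw
  z <- zero_instances
  # before (and at) the first instance: subtract the first anchor value
  v[seq_len(z[1L])] <- v_raw[seq_len(z[1L])] - v_raw[z[1L]]
  if (length(z) > 1L) {
    for (k in seq_len(length(z) - 1L)) {
      a <- z[k]; b <- z[k + 1L]
      if (b == a + 1L) { v[b] <- 0; next }
      seg <- (a + 1L):b
      d <- v_raw[b] - v_raw[a]
      if (cfg$drift_mode == "linear_detrend") {
        v[seg] <- v_raw[seg] - v_raw[a] - d * (seg - a) / (b - a)
      } else {
        v[seg] <- v_raw[seg] - v_raw[a]
        v[b] <- 0
      }
    }
  }
  zl <- z[length(z)]
  if (zl < n) {
    seg <- (zl + 1L):n
    v[seg] <- v_raw[seg] - v_raw[zl]
  }
  v[z] <- 0
  v
}

#' Tune the zero-acceleration threshold on training data
#'
#' Scans a logarithmic grid of candidate thresholds from the largest down and
#' returns the largest `eps_g` whose primary detections (with the configured
#' dwell) all fall inside known stance windows. If no grid value qualifies the
#' grid minimum is returned with attribute `warning = TRUE`.
#'
#' @param accel_z_world world-frame vertical acceleration (m/s^2).
#' @param stance_windows 2-column matrix (or list of length-2 vectors) of
#'   `[start, end]` sample-index intervals known to be stance.
#' @param cfg a [zupt_config()]; its `eps_g` is ignored.
#' @param grid candidate thresholds, m/s^2.
#' @return tuned `eps_g` (m/s^2), with attribute `warning` set to `TRUE` when
#'   no candidate kept all detections inside stance.
#' @export
tune_eps_g <- function(accel_z_world, stance_windows, cfg = zupt_config(),
                       grid = exp(seq(log(0.01), log(2.0), length.out = 30L))) {
  if (is.list(stance_windows))
    stance_windows <- do.call(rbind, stance_windows)
  if (is.null(stance_windows) || nrow(stance_windows) == 0L)
    stop("empty stance windows", call. = FALSE)
  in_stance <- rep(FALSE, length(accel_z_world))
  for (i in seq_len(nrow(stance_windows)))
    in_stance[stance_windows[i, 1L]:stance_windows[i, 2L]] <- TRUE
  for (eps in sort(grid, decreasing = TRUE)) {
    quiet <- abs(accel_z_world - cfg$g) < eps
    runs <- .true_runs(quiet)
    runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= cfg$min_dwell, ,
                 drop = FALSE]
    if (!nrow(runs)) next
    idx <- unlist(lapply(seq_len(nrow(runs)),
                         function(i) runs[i, 1L]:runs[i, 2L]))
    if (all(in_stance[idx])) return(eps)
  }
  out <- min(grid)
  attr(out, "warning") <- TRUE
  warning("no grid threshold confined detections to stance; ",
          "returning grid minimum", call. = FALSE)
  out
}

#' Derive the two network inputs from a raw sensor stream
#'
#' Produces the processed signals the classifier consumes: world-frame
#' vertical foot velocity (ZUPT-corrected integration of vertical
#' acceleration) and foot pitch angle. Streams in the reduced dialect use the
#' supplied `accel_z_world`/`pitch_deg` directly; quaternion streams are
#' rotated sample-by-sample first.
#'
#' @param stream a [sensor_stream()].
#' @param cfg a [zupt_config()].
#' @return list of class `processed_signals` with `v_z` (m/s), `theta`
#'   (degrees), `zero_instances` (integer indices) and `fs`.
#' @export
process_signals <- function(stream, cfg = zupt_config()) {
  stopifnot(inherits(stream, "sensor_stream"), inherits(cfg, "zupt_config"))
  if (!is.null(stream$quat) && !is.null(stream$accel_body)) {
    aw <- rotate_to_world(stream$quat, stream$accel_body)
    az <- aw[, 3L]
    theta <- compute_pitch(stream$quat)
  } else {
    az <- stream$accel_z_world
    theta <- stream$pitch_deg
  }
  zi <- detect_zero_accel_instances(az, stream$fsr_heel, stream$fsr_toe, cfg)
  v <- estimate_vertical_velocity(az, zi, stream$fs, cfg)
  structure(list(v_z = v, theta = theta, zero_instances = zi$indices,
                 fs = stream$fs),
            class = "processed_signals")
}
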