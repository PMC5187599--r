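# Seeded synthetic gait simulator.
#
# Emulates a foot-mounted IMU + foot-switch recording of the two walking
# protocols used to exercise the classifier:
#   stairs: 3-4 level steps, 6 ascending (14 cm rise each), 3-4 level,
#           a turn, 3-4 level, 6 descending, 3-4 level;
#   ramp:   3-4 level steps, 8-10 ascending a 6-degree grade, a turn,
#           8-10 descending, 3-4 level.
# Each swing moves the foot along a minimum-jerk vertical arc with a smooth
# clearance bump; mode-specific pitch profiles reflect the qualitative
# differences that make velocity and segment angle informative (toe held up
# on ascent, pointed down on descent, surface-slope offset on the ramp).
# The foot is stationary in stance, so true vertical velocity is exactly
# zero there and the zero-velocity assumption holds by construction.

#' Scenario configuration for the synthetic gait simulator
#'
#' Defaults encode the study conditions: 200 Hz sampling, 14 cm stair rise,
#' 6-degree ramp grade, five subjects with three trials per scenario. Noise
#' defaults (accelerometer SD 0.3 m/s^2, pitch SD 1 degree) are set so that
#' the zero-acceleration threshold needs genuine tuning and the FSR fail-safe
#' occasionally fires.
#'
#' @param scenario `"stairs"` or `"ramp"`.
#' @param fs sampling rate, Hz.
#' @param step_rise stair rise per step, m.
#' @param ramp_grade ramp grade, degrees.
#' @param stride_time nominal gait-cycle duration, s (jittered per subject).
#' @param stride_length nominal stride length, m (sets the per-step rise on
#'   the ramp via `stride_length * tan(grade)`).
#' @param swing_fraction fraction of the gait cycle spent in swing.
#' @param clearance peak extra foot clearance during swing, m.
#' @param noise_accel_sd accelerometer white-noise SD, m/s^2.
#' @param noise_pitch_sd pitch measurement noise SD, degrees.
#' @param n_subjects,n_trials study size per scenario.
#' @param seed base seed; all subject/trial substreams derive from it.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("stairs", "ramp"), fs = 200,
                            step_rise = 0.14, ramp_grade = 6,
                            stride_time = 1.1, stride_length = 1.3,
                            swing_fraction = 0.4, clearance = 0.05,
                            noise_accel_sd = 0.3, noise_pitch_sd = 1.0,
                            n_subjects = 5L, n_trials = 3L, seed = 42L) {
  scenario <- match.arg(scenario)
  stopifnot(fs > 0, step_rise >= 0, swing_fraction > 0, swing_fraction < 1,
            stride_time > 0, stride_length > 0, noise_accel_sd >= 0,
            noise_pitch_sd >= 0, n_subjects >= 1, n_trials >= 1)
  structure(list(scenario = scenario, fs = fs, step_rise = step_rise,
                 ramp_grade = ramp_grade, stride_time = stride_time,
                 stride_length = stride_length,
                 swing_fraction = swing_fraction, clearance = clearance,
                 noise_accel_sd = noise_accel_sd,
                 noise_pitch_sd = noise_pitch_sd,
                 n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "scenario_config")
}

# smooth basis on tau in [0,1]: minimum-jerk reach s (0->1, zero vel/acc at
# ends) and clearance bump c (0 at ends, peak 1 at tau=0.5, zero vel/acc at
# ends), with first and second derivatives.
.mj_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
.mj_s1 <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
.mj_s2 <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3
.cl_c <- function(tau) 64 * (tau^3 - 3 * tau^4 + 3 * tau^5 - tau^6)
.cl_c1 <- function(tau) 64 * (3 * tau^2 - 12 * tau^3 + 15 * tau^4 -
                                6 * tau^5)
.cl_c2 <- function(tau) 64 * (6 * tau - 36 * tau^2 + 60 * tau^3 -
                                30 * tau^4)

# swing pitch shapes: an early lobe peaking around 25% swing (push-off
# plantarflexion) and a sustained plateau over mid-swing (toe held up/down);
# both are smooth and vanish with zero slope at the swing boundaries.
.pitch_lobe <- function(tau) .cl_c(pmin(tau / 0.5, 1))
.pitch_plateau <- function(tau)
  .mj_s(pmin(tau / 0.3, 1)) * .mj_s(pmin((1 - tau) / 0.3, 1))

# deterministic substream seeds (< 2^31)
.sub_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

# step plan for one trial: data.frame(kind, mode, stride_scale)
.step_plan <- function(cfg) {
  nl <- function() sample(3:4, 1L)
  if (cfg$scenario == "stairs") {
    kinds <- c(rep("level", nl()), rep("stair_up", 6L), rep("level", nl()),
               rep("turn", 2L), rep("level", nl()), rep("stair_down", 6L),
               rep("level", nl()))
  } else {
    n_ramp <- sample(8:10, 1L)
    kinds <- c(rep("level", nl()), rep("ramp_up", n_ramp), rep("turn", 2L),
               rep("ramp_down", n_ramp), rep("level", nl()))
  }
  mode <- c(level = "Level", turn = "Level", stair_up = "Ascent",
            stair_down = "Descent", ramp_up = "Ascent",
            ramp_down = "Descent")[kinds]
  data.frame(kind = kinds, mode = unname(mode),
             stride_scale = ifelse(kinds == "turn", 1.4, 1.0))
}

#' Generate one synthetic walking trial
#'
#' Builds the step sequence for the scenario, synthesizes noise-free vertical
#' kinematics and pitch, adds measurement noise, and emits a quaternion-dialect
#' [sensor_stream()] together with the ground truth. Deterministic for a given
#' `(cfg$seed, subject_id, trial_id)`; subject-level kinematic jitter (stride
#' time/length, amplitude) is constant across that subject's trials.
#'
#' @param cfg a [scenario_config()].
#' @param subject_id,trial_id positive integers.
#' @return list with `stream` (a [sensor_stream()]) and `truth`: per-sample
#'   `v_z`, `theta`, `mode`, `stance` (all noise-free), and `steps`
#'   (data.frame with `heel_strike`, `swing_start`, `next_heel_strike`,
#'   `mode`, `rise` per step) plus `midstance` windows (both-FSR-ON
#'   intervals).
#' @export
generate_trial <- function(cfg, subject_id = 1L, trial_id = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  # subject-level kinematic jitter, constant across trials
  set.seed(.sub_seed(cfg$seed, subject_id))
  subj_stride_t <- cfg$stride_time * stats::runif(1, 0.9, 1.1)
  subj_stride_l <- cfg$stride_length * stats::runif(1, 0.9, 1.1)
  subj_amp <- stats::runif(1, 0.9, 1.1)

  set.seed(.sub_seed(cfg$seed, subject_id, trial_id,
                     match(cfg$scenario, c("stairs", "ramp"))))
  plan <- .step_plan(cfg)
  fs <- cfg$fs
  # (plantarflexion dip, sustained sweep) per step kind, degrees: level
  # walking is biphasic (toe-down push-off, mild dorsiflexion for clearance);
  # stair/ramp swings hold the toe up (ascent) or down (descent).
  dip_amp <- c(level = -15, turn = -10, stair_up = 0, stair_down = 0,
               ramp_up = -5, ramp_down = -5) * subj_amp
  plat_amp <- c(level = 6, turn = 4, stair_up = 25, stair_down = -25,
                ramp_up = 15, ramp_down = -15) * subj_amp
  stance_off <- c(level = 0, turn = 0, stair_up = 0, stair_down = 0,
                  ramp_up = cfg$ramp_grade, ramp_down = -cfg$ramp_grade)
  rise_of <- function(kind) switch(kind,
    stair_up = cfg$step_rise, stair_down = -cfg$step_rise,
    ramp_up = subj_stride_l * tan(cfg$ramp_grade * pi / 180),
    ramp_down = -subj_stride_l * tan(cfg$ramp_grade * pi / 180),
    0)

  lead <- round(1.0 * fs); tail <- round(1.0 * fs)
  v <- a <- th <- numeric(0)
  heel <- toe <- logical(0)
  mode_lab <- character(0)
  stance_flag <- logical(0)
  steps <- data.frame(heel_strike = integer(0), swing_start = integer(0),
                      next_heel_strike = integer(0), mode = character(0),
                      rise = numeric(0))
  midstance <- NULL

  append_stance <- function(n_st, off, both_from, both_to) {
    v <<- c(v, rep(0, n_st)); a <<- c(a, rep(0, n_st))
    th <<- c(th, rep(off, n_st))
    h <- rep(FALSE, n_st); h[seq_len(round(0.75 * n_st))] <- TRUE
    tt <- rep(FALSE, n_st)
    tt[max(1L, round(0.15 * n_st)):n_st] <- TRUE
    heel <<- c(heel, h); toe <<- c(toe, tt)
    stance_flag <<- c(stance_flag, rep(TRUE, n_st))
  }

  # standing lead-in (both switches on, foot flat on level ground)
  v <- rep(0, lead); a <- rep(0, lead); th <- rep(0, lead)
  heel <- rep(TRUE, lead); toe <- rep(TRUE, lead)
  mode_lab <- rep("Level", lead)
  stance_flag <- rep(TRUE, lead)
  midstance <- rbind(midstance, c(1L, lead))

  off_prev <- 0
  for (i in seq_len(nrow(plan))) {
    kind <- plan$kind[i]
    T_step <- subj_stride_t * plan$stride_scale[i]
    n_st <- round(T_step * (1 - cfg$swing_fraction) * fs)
    n_sw <- round(T_step * cfg$swing_fraction * fs)
    hs_idx <- length(v) + 1L
    off <- off_prev
    # stance: foot flat and stationary
    append_stance(n_st, off, NA, NA)
    ms_from <- hs_idx + max(1L, round(0.15 * n_st)) - 1L
    ms_to <- hs_idx + round(0.75 * n_st) - 1L
    midstance <- rbind(midstance, c(ms_from, ms_to))
    # swing: minimum-jerk rise + clearance arc, mode-specific pitch sweep
    sw_idx <- length(v) + 1L
    tau <- (seq_len(n_sw)) / (n_sw + 1L)
    T_sw <- (n_sw + 1L) / fs  # swing spans n_sw samples between two stance samples
    rise <- rise_of(kind)
    off_next <- stance_off[[kind]]
    v_sw <- (rise * .mj_s1(tau) + cfg$clearance * .cl_c1(tau)) / T_sw
    a_sw <- (rise * .mj_s2(tau) + cfg$clearance * .cl_c2(tau)) / T_sw^2
    th_sw <- off * (1 - .mj_s(tau)) + off_next * .mj_s(tau) +
      dip_amp[[kind]] * .pitch_lobe(tau) +
      plat_amp[[kind]] * .pitch_plateau(tau)
    v <- c(v, v_sw); a <- c(a, a_sw); th <- c(th, th_sw)
    heel <- c(heel, rep(FALSE, n_sw)); toe <- c(toe, rep(FALSE, n_sw))
    stance_flag <- c(stance_flag, rep(FALSE, n_sw))
    mode_lab <- c(mode_lab, rep(plan$mode[i], n_st + n_sw))
    steps <- rbind(steps, data.frame(heel_strike = hs_idx,
                                     swing_start = sw_idx,
                                     next_heel_strike = length(v) + 1L,
                                     mode = plan$mode[i], rise = rise))
    off_prev <- off_next
  }
  # landing stance + standing tail
  tail_from <- length(v) + 1L
  v <- c(v, rep(0, tail)); a <- c(a, rep(0, tail))
  th <- c(th, rep(off_prev, tail))
  heel <- c(heel, rep(TRUE, tail)); toe <- c(toe, rep(TRUE, tail))
  mode_lab <- c(mode_lab, rep(plan$mode[nrow(plan)], tail))
  stance_flag <- c(stance_flag, rep(TRUE, tail))
  midstance <- rbind(midstance, c(tail_from, length(v)))

  n <- length(v)
  az_true <- 9.81 + a
  az_meas <- az_true + stats::rnorm(n, 0, cfg$noise_accel_sd)
  th_meas <- th + stats::rnorm(n, 0, cfg$noise_pitch_sd)
  quat <- quat_from_pitch(th_meas)
  # body-frame accelerometer reading: rotate the measured world vector back
  conj <- cbind(quat[, 1L], -quat[, 2L], -quat[, 3L], -quat[, 4L])
  accel_body <- rotate_to_world(conj, cbind(0, 0, az_meas))

  stream <- sensor_stream(t = (seq_len(n) - 1L) / fs, fs = fs, quat = quat,
                          accel_body = accel_body, fsr_heel = heel,
                          fsr_toe = toe)
  truth <- list(v_z = v, theta = th, mode = mode_lab, stance = stance_flag,
                steps = steps, midstance = midstance,
                subject = subject_id, trial = trial_id,
                scenario = cfg$scenario)
  list(stream = stream, truth = truth)
}

#' Generate a full synthetic study
#'
#' `n_subjects x n_trials` trials for the configured scenario, trial 1 of
#' each subject flagged as the training split. Optionally writes each trial's
#' sensor CSV, a `_truth.csv` per-sample label track, and a manifest.
#'
#' @param cfg a [scenario_config()].
#' @param dir output directory; `NULL` (default) keeps everything in memory.
#' @return list with `trials` (nested `[[subject]][[trial]]` results of
#'   [generate_trial()]) and `manifest` (data.frame with subject, trial,
#'   scenario, role).
#' @export
generate_study <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  trials <- list()
  manifest <- NULL
  for (s in seq_len(cfg$n_subjects)) {
    trials[[s]] <- list()
    for (tr in seq_len(cfg$n_trials)) {
      trials[[s]][[tr]] <- generate_trial(cfg, s, tr)
      row <- data.frame(subject = s, trial = tr, scenario = cfg$scenario,
                        role = if (tr == 1L) "train" else "test")
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        base <- sprintf("%s_sub%02d_trial%d", cfg$scenario, s, tr)
        row$file <- file.path(dir, paste0(base, ".csv"))
        write_sensor_csv(trials[[s]][[tr]]$stream, row$file)
        tru <- trials[[s]][[tr]]$truth
        utils::write.csv(data.frame(v_z = tru$v_z, theta = tru$theta,
                                    mode = tru$mode,
                                    stance = as.integer(tru$stance)),
                         file.path(dir, paste0(base, "_truth.csv")),
                         row.names = FALSE, quote = FALSE)
      }
      manifest <- rbind(manifest, row)
    }
  }
  if (!is.null(dir)) {
    if (requireNamespace("yaml", quietly = TRUE)) {
      yaml::write_yaml(list(seed = cfg$seed, scenario = cfg$scenario,
                            trials = lapply(seq_len(nrow(manifest)),
                                            function(i) as.list(manifest[i, ]))),
                       file.path(dir, "manifest.yaml"))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(trials = trials, manifest = manifest)
}
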