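# Step-level evaluation: gait-cycle segmentation from the foot switches,
# per-step predicted mode, success rate, and detection delay in percent gait
# cycle from the start of the swing phase.

# debounce a logical contact series: a state change only takes effect when
# the new state persists >= debounce samples; shorter glitch runs keep the
# preceding state.
.debounced <- function(x, debounce) {
  r <- rle(as.logical(x))
  vals <- r$values
  cur <- vals[1L]
  for (i in seq_along(vals)) {
    if (i == 1L || r$lengths[i] >= debounce) cur <- vals[i]
    vals[i] <- cur
  }
  rep(vals, r$lengths)
}

#' Segment gait cycles from the foot switches
#'
#' Heel strikes are debounced OFF->ON transitions of the heel FSR; each step
#' spans consecutive heel strikes. The swing start (toe-off) is the last
#' debounced ON->OFF transition of the toe FSR before the next heel strike.
#' Contact glitches shorter than `debounce` samples are ignored.
#'
#' @param fsr_heel,fsr_toe logical contact series of equal length.
#' @param debounce minimum persistence of a new contact state, samples.
#' @return data.frame of class `step_table` with columns `heel_strike`,
#'   `swing_start`, `next_heel_strike` (sample indices).
#' @export
segment_steps <- function(fsr_heel, fsr_toe, debounce = 10L) {
  stopifnot(length(fsr_heel) == length(fsr_toe))
  heel <- .debounced(fsr_heel, debounce)
  toe <- .debounced(fsr_toe, debounce)
  n <- length(heel)
  hs <- which(diff(c(heel[1L], heel)) == 1L)
  if (length(hs) < 2L)
    stop("too few steps: need at least 2 heel strikes", call. = FALSE)
  toe_off <- which(diff(c(toe, toe[n])) == -1L) + 1L # first OFF sample
  steps <- data.frame(heel_strike = hs[-length(hs)],
                      next_heel_strike = hs[-1L])
  steps$swing_start <- NA_integer_
  for (i in seq_len(nrow(steps))) {
    cand <- toe_off[toe_off > steps$heel_strike[i] &
                      toe_off < steps$next_heel_strike[i]]
    if (length(cand)) steps$swing_start[i] <- max(cand)
  }
  steps <- steps[!is.na(steps$swing_start), , drop = FALSE]
  if (nrow(steps) < 1L)
    stop("too few steps: no complete heel-strike/toe-off/heel-strike cycle",
         call. = FALSE)
  steps <- steps[, c("heel_strike", "swing_start", "next_heel_strike")]
  rownames(steps) <- NULL
  class(steps) <- c("step_table", "data.frame")
  steps
}

#' Assign a predicted mode and detection sample to one step
#'
#' Within the step's decision window `[swing_start, next_heel_strike)` the
#' predicted mode is the label of the longest run of identical determined
#' (non-Undetermined) samples, ties going to the later run. The detection
#' sample is the first sample in the window from which the prediction equals
#' that mode and never switches to a different determined label before the
#' next heel strike. An all-Undetermined window yields
#' `("Undetermined", NA)`.
#'
#' @param pred per-sample predicted labels for the whole trial.
#' @param step one row of a [segment_steps()] table (list-like with
#'   `swing_start`, `next_heel_strike`).
#' @return list with `pred_mode` and `detect_sample` (trial sample index or
#'   `NA`).
#' @export
step_mode <- function(pred, step) {
  win <- step$swing_start:(step$next_heel_strike - 1L)
  lab <- pred[win]
  det <- lab != "Undetermined"
  if (!any(det)) return(list(pred_mode = "Undetermined",
                             detect_sample = NA_integer_))
  r <- rle(lab)
  runs <- data.frame(label = r$values, len = r$lengths,
                     end = cumsum(r$lengths))
  runs$start <- runs$end - runs$len + 1L
  runs <- runs[runs$label != "Undetermined", , drop = FALSE]
  best_len <- max(runs$len)
  best <- runs[runs$len == best_len, , drop = FALSE]
  pred_mode <- best$label[nrow(best)] # tie -> later run
  # first sample from which the label stays in {pred_mode, Undetermined}
  other <- which(det & lab != pred_mode)
  from <- if (length(other)) max(other) + 1L else 1L
  cand <- which(lab == pred_mode & seq_along(lab) >= from)
  detect <- if (length(cand)) win[min(cand)] else NA_integer_
  list(pred_mode = pred_mode, detect_sample = detect)
}

#' Per-step success rate
#'
#' `100 * (# steps whose predicted mode equals the true mode) / (# steps)`,
#' optionally restricted to steps of one true mode. An Undetermined
#' prediction counts as incorrect.
#'
#' @param steps a step table with `true_mode` and `pred_mode` columns.
#' @param mode_filter a mode label, or `"all"`.
#' @return success rate in percent.
#' @export
success_rate <- function(steps, mode_filter = "all") {
  if (!identical(mode_filter, "all"))
    steps <- steps[steps$true_mode == mode_filter, , drop = FALSE]
  if (nrow(steps) == 0L)
    stop("undefined success rate: no steps after filtering", call. = FALSE)
  100 * mean(steps$pred_mode == steps$true_mode)
}

#' Detection delay of one step in percent gait cycle
#'
#' `100 * (detect_sample - swing_start) / (next_heel_strike - heel_strike)`,
#' the gait cycle being that of the same step. `NA` when the step has no
#' detection sample.
#'
#' @param step list-like with `heel_strike`, `swing_start`,
#'   `next_heel_strike`, `detect_sample`.
#' @return delay in % gait cycle, or `NA`.
#' @export
detection_delay <- function(step) {
  if (is.na(step$detect_sample)) return(NA_real_)
  100 * (step$detect_sample - step$swing_start) /
    (step$next_heel_strike - step$heel_strike)
}

#' Score one classified trial against ground truth
#'
#' Segments steps from the foot switches, assigns each step its true mode
#' (majority truth label over the cycle) and predicted mode (longest
#' determined run in the swing window), and computes per-step detection
#' delays. Transition steps are those whose true mode differs from the
#' previous step's.
#'
#' @param pred per-sample predicted mode labels.
#' @param truth_labels per-sample true mode labels.
#' @param fsr_heel,fsr_toe logical contact series.
#' @return `step_table` data.frame with `true_mode`, `pred_mode`,
#'   `detect_sample`, `delay_pct_gc`, `transition` columns added.
#' @export
score_trial <- function(pred, truth_labels, fsr_heel, fsr_toe) {
  steps <- segment_steps(fsr_heel, fsr_toe)
  steps$true_mode <- NA_character_
  steps$pred_mode <- NA_character_
  steps$detect_sample <- NA_integer_
  steps$delay_pct_gc <- NA_real_
  for (i in seq_len(nrow(steps))) {
    cyc <- steps$heel_strike[i]:(steps$next_heel_strike[i] - 1L)
    tl <- table(truth_labels[cyc])
    steps$true_mode[i] <- names(tl)[which.max(tl)]
    sm <- step_mode(pred, steps[i, ])
    steps$pred_mode[i] <- sm$pred_mode
    steps$detect_sample[i] <- sm$detect_sample
    steps$delay_pct_gc[i] <- detection_delay(steps[i, ])
  }
  steps$transition <- c(FALSE, steps$true_mode[-1L] !=
                          steps$true_mode[-nrow(steps)])
  steps
}

#' Aggregate a set of scored trials into a study report
#'
#' Mirrors the per-subject-by-mode success-rate table layout with an Overall
#' row, plus the mean transition-step detection delay.
#'
#' @param step_tables list of [score_trial()] outputs; each element must
#'   carry a `subject` column (added here from `subjects` when given).
#' @param subjects optional vector of subject ids matching `step_tables`.
#' @return list with `steps` (pooled table), `success` (per-subject x mode
#'   data.frame with an `"Overall"` row) and `mean_transition_delay`
#'   (% gait cycle, `NA` if no transition step was detected).
#' @export
evaluate_trials <- function(step_tables, subjects = NULL) {
  if (length(step_tables) < 1L) stop("need at least one test trial",
                                     call. = FALSE)
  if (!is.null(subjects)) {
    stopifnot(length(subjects) == length(step_tables))
    for (i in seq_along(step_tables))
      step_tables[[i]]$subject <- subjects[[i]]
  }
  steps <- do.call(rbind, step_tables)
  if (is.null(steps$subject)) steps$subject <- "Sub01"
  modes <- intersect(c("Level", "Ascent", "Descent"),
                     unique(steps$true_mode))
  subj <- sort(unique(steps$subject))
  rate <- function(df, m) {
    sel <- df[df$true_mode == m, , drop = FALSE]
    if (!nrow(sel)) NA_real_ else 100 * mean(sel$pred_mode == sel$true_mode)
  }
  success <- do.call(rbind, lapply(c(subj, "Overall"), function(s) {
    df <- if (s == "Overall") steps else steps[steps$subject == s, ,
                                               drop = FALSE]
    out <- data.frame(subject = s)
    for (m in modes) out[[m]] <- rate(df, m)
    out
  }))
  tr <- steps[steps$transition & !is.na(steps$delay_pct_gc) &
                steps$pred_mode == steps$true_mode, , drop = FALSE]
  list(steps = steps, success = success,
       mean_transition_delay = if (nrow(tr)) mean(tr$delay_pct_gc)
       else NA_real_)
}
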