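# End-to-end pipeline: train a subject-specific classifier on labelled
# trials, classify test trials, and run the full synthetic study
# (train on trial 1, test on trials 2..n, per subject and scenario).

#' Train the full gait-mode classifier on labelled trials
#'
#' Tunes the zero-acceleration threshold on the training stream (stance
#' windows taken from the both-FSR-ON intervals), derives the two input
#' signals, trains the network, and fits the decision model (filter +
#' minimum-risk thresholds) on the same data.
#'
#' @param streams a [sensor_stream()] or list of them (training trials).
#' @param labels per-sample true mode labels (list matching `streams`).
#' @param train_cfg a [train_config()].
#' @param zupt_cfg a [zupt_config()]; its `eps_g` is replaced by the tuned
#'   value unless `tune = FALSE`.
#' @param epsilon decision-filter time constant, seconds.
#' @param loss 2x2 loss matrix for the threshold solution.
#' @param stride training-row decimation passed to [build_training_set()].
#' @param tune tune `eps_g` on the training data (default) or keep
#'   `zupt_cfg$eps_g`.
#' @return object of class `gait_classifier`: list with `model`
#'   ([network_model()]), `decision` ([decision_model()]), `zupt`
#'   ([zupt_config()]) and `fs`.
#' @export
train_gait_classifier <- function(streams, labels, train_cfg = train_config(),
                                  zupt_cfg = zupt_config(),
                                  epsilon = 0.02,
                                  loss = matrix(c(0, 0.5, 1.0, 0), 2, 2),
                                  stride = 3L, tune = TRUE) {
  if (inherits(streams, "sensor_stream")) {
    streams <- list(streams); labels <- list(labels)
  }
  stopifnot(length(streams) == length(labels))
  fs <- streams[[1L]]$fs
  if (tune) {
    s1 <- streams[[1L]]
    az <- if (!is.null(s1$quat)) {
      rotate_to_world(s1$quat, s1$accel_body)[, 3L]
    } else s1$accel_z_world
    stance <- .true_runs(s1$fsr_heel | s1$fsr_toe)
    eps <- tune_eps_g(az, stance, zupt_cfg)
    zupt_cfg$eps_g <- as.numeric(eps)
  }
  signals <- lapply(streams, process_signals, cfg = zupt_cfg)
  ts <- build_training_set(signals, labels, n_delays = train_cfg$n_delays,
                           stride = stride)
  model <- ann_train(ts$X, ts$targets, train_cfg)
  decision <- fit_decision_model(model, signals, labels, fs = fs,
                                 epsilon = epsilon, loss = loss)
  structure(list(model = model, decision = decision, zupt = zupt_cfg,
                 fs = fs),
            class = "gait_classifier")
}

#' @export
print.gait_classifier <- function(x, ...) {
  cat("<gait_classifier>\n")
  print(x$model); print(x$decision)
  cat(sprintf("zupt: eps_g=%.4g m/s^2, min_dwell=%d, %s; fs=%g Hz\n",
              x$zupt$eps_g, x$zupt$min_dwell, x$zupt$drift_mode, x$fs))
  invisible(x)
}

#' Classify a trial with a trained classifier
#'
#' @param classifier a [train_gait_classifier()] result.
#' @param stream a [sensor_stream()].
#' @return list with per-sample `labels`, the `signals` used, and the raw
#'   filtered outputs `y_bar`.
#' @export
classify_trial <- function(classifier, stream) {
  stopifnot(inherits(classifier, "gait_classifier"))
  signals <- process_signals(stream, classifier$zupt)
  y <- predict_stream(classifier$model, signals)
  y_bar <- filter_stream(y, classifier$decision$epsilon, classifier$fs)
  labels <- map_mode(binarize(y_bar, classifier$decision$thresholds))
  list(labels = labels, signals = signals, y_bar = y_bar)
}

#' Run the synthetic study for one scenario
#'
#' Generates the study (`n_subjects x n_trials`), trains a subject-specific
#' classifier on each subject's first trial, classifies the remaining trials,
#' and aggregates per-mode success rates (with an Overall row) and the mean
#' transition-step detection delay.
#'
#' @param cfg a [scenario_config()].
#' @param train_cfg a [train_config()]; its seed is re-derived per subject
#'   from `cfg$seed` so the whole study is reproducible from one seed.
#' @param stride training-row decimation (see [build_training_set()]).
#' @return list with `report` (from [evaluate_trials()]), `classifiers`
#'   (per subject) and the generated `study`.
#' @export
run_synthetic_study <- function(cfg, train_cfg = train_config(),
                                stride = 3L) {
  study <- generate_study(cfg)
  classifiers <- list()
  tables <- list(); subjects <- character(0)
  for (s in seq_len(cfg$n_subjects)) {
    tr1 <- study$trials[[s]][[1L]]
    tc <- train_cfg
    tc$seed <- .sub_seed(cfg$seed, s, 777L)
    clf <- train_gait_classifier(tr1$stream, tr1$truth$mode,
                                 train_cfg = tc, stride = stride)
    classifiers[[s]] <- clf
    if (cfg$n_trials < 2L)
      stop("study needs at least 2 trials per subject (train + test)",
           call. = FALSE)
    for (tr in seq(2L, cfg$n_trials)) {
      trial <- study$trials[[s]][[tr]]
      res <- classify_trial(clf, trial$stream)
      tab <- score_trial(res$labels, trial$truth$mode,
                         trial$stream$fsr_heel, trial$stream$fsr_toe)
      tables[[length(tables) + 1L]] <- tab
      subjects <- c(subjects, sprintf("Sub%02d", s))
    }
  }
  list(report = evaluate_trials(tables, subjects),
       classifiers = classifiers, study = study)
}
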