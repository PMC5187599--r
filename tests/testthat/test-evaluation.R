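# square-wave FSR fixture: stride_s per step, stance fraction 0.6,
# heel ON for the first 75% of stance, toe ON from 15% of stance to toe-off
square_gait <- function(n_steps, stride_s = 1, fs = 100) {
  n_st <- round(0.6 * stride_s * fs); n_sw <- round(0.4 * stride_s * fs)
  heel <- toe <- logical(0)
  for (i in seq_len(n_steps)) {
    h <- rep(FALSE, n_st + n_sw); h[1:round(0.75 * n_st)] <- TRUE
    tt <- rep(FALSE, n_st + n_sw); tt[round(0.15 * n_st):n_st] <- TRUE
    heel <- c(heel, h); toe <- c(toe, tt)
  }
  # closing heel strike so the last step is a full cycle
  heel <- c(heel, rep(TRUE, 20)); toe <- c(toe, rep(TRUE, 20))
  list(heel = heel, toe = toe, n_step = n_st + n_sw, n_st = n_st)
}

test_that("segment_steps finds strides at the right spacing and debounces glitches", {
  g <- square_gait(5, stride_s = 1, fs = 100)
  st <- segment_steps(g$heel, g$toe)
  expect_equal(nrow(st), 4)   # first heel strike opens the first full cycle
  expect_true(all(diff(st$heel_strike) == g$n_step))
  expect_equal(st$swing_start - st$heel_strike, rep(g$n_st, 4))
  expect_true(all(st$heel_strike < st$swing_start &
                    st$swing_start < st$next_heel_strike))
  # a 3-sample contact glitch in swing must not create an extra step
  heel2 <- g$heel
  gap <- which(!heel2)[50] + 0:2
  heel2[gap] <- TRUE
  st2 <- segment_steps(heel2, g$toe)
  expect_equal(nrow(st2), nrow(st))
  expect_error(segment_steps(rep(TRUE, 100), rep(TRUE, 100)), "too few")
})

test_that("the synthetic stair protocol contains exactly 6 ascending steps", {
  cfg <- scenario_config("stairs", seed = 23, n_subjects = 1, n_trials = 1)
  tr <- generate_trial(cfg, 1, 1)
  st <- segment_steps(tr$stream$fsr_heel, tr$stream$fsr_toe)
  truemode <- vapply(seq_len(nrow(st)), function(i) {
    cyc <- st$heel_strike[i]:(st$next_heel_strike[i] - 1)
    names(which.max(table(tr$truth$mode[cyc])))
  }, character(1))
  expect_equal(sum(truemode == "Ascent"), 6)
  expect_equal(sum(truemode == "Descent"), 6)
})

test_that("step_mode follows the longest determined run and detection rule", {
  step <- list(swing_start = 101L, next_heel_strike = 201L,
               heel_strike = 1L)
  pred <- rep("Undetermined", 300)
  # uniform window
  pred[101:200] <- "Ascent"
  sm <- step_mode(pred, step)
  expect_equal(sm$pred_mode, "Ascent")
  expect_equal(sm$detect_sample, 101L)
  # all-undetermined window
  sm <- step_mode(rep("Undetermined", 300), step)
  expect_equal(sm$pred_mode, "Undetermined")
  expect_true(is.na(sm$detect_sample))
  # 30% Level then 70% Descent: longest run wins, detection at its start
  pred <- rep("Undetermined", 300)
  pred[101:130] <- "Level"; pred[131:200] <- "Descent"
  sm <- step_mode(pred, step)
  expect_equal(sm$pred_mode, "Descent")
  expect_equal(sm$detect_sample, 131L)
  # undetermined gaps after detection do not push the detection later
  pred <- rep("Undetermined", 300)
  pred[110:140] <- "Descent"; pred[160:200] <- "Descent"
  sm <- step_mode(pred, step)
  expect_equal(sm$detect_sample, 110L)
  # equal-length runs: the later one wins
  pred <- rep("Undetermined", 300)
  pred[101:130] <- "Level"; pred[140:169] <- "Ascent"
  expect_equal(step_mode(pred, step)$pred_mode, "Ascent")
})

test_that("success rate is the percentage of correctly recognized steps", {
  steps <- data.frame(true_mode = rep("Level", 30),
                      pred_mode = c(rep("Level", 29), "Ascent"))
  expect_equal(success_rate(steps), 100 * 29 / 30)
  expect_equal(success_rate(steps), 96.667, tolerance = 1e-4)
  steps$pred_mode <- steps$true_mode
  expect_equal(success_rate(steps), 100)
  steps$pred_mode <- "Undetermined"
  expect_equal(success_rate(steps), 0)
  expect_error(success_rate(steps, "Descent"), "undefined")
})

test_that("detection delay is measured from swing start in % of the gait cycle", {
  step <- list(heel_strike = 1L, swing_start = 121L,
               next_heel_strike = 201L, detect_sample = 121L)
  expect_equal(detection_delay(step), 0)
  # detection halfway from swing start to next heel strike, swing = 40% GC
  step$detect_sample <- 161L
  expect_equal(detection_delay(step), 20)
  # detect at next_heel_strike - 1 with a 200-sample cycle, swing at 120
  step$detect_sample <- 200L
  expect_equal(detection_delay(step), 39.5)
  step$detect_sample <- NA_integer_
  expect_true(is.na(detection_delay(step)))
  # invariance to a uniform index shift
  s1 <- list(heel_strike = 11L, swing_start = 131L,
             next_heel_strike = 211L, detect_sample = 171L)
  expect_equal(detection_delay(s1), 20)
})

test_that("evaluate_trials aggregates per-subject rows plus an Overall row", {
  cfg <- scenario_config("stairs", seed = 33, n_subjects = 1, n_trials = 1)
  tr <- generate_trial(cfg, 1, 1)
  # perfect predictor: feed the truth back in
  tab <- score_trial(tr$truth$mode, tr$truth$mode,
                     tr$stream$fsr_heel, tr$stream$fsr_toe)
  rep2 <- evaluate_trials(list(tab, tab), c("Sub01", "Sub02"))
  expect_equal(rep2$success$subject, c("Sub01", "Sub02", "Overall"))
  expect_true(all(unlist(rep2$success[, c("Level", "Ascent", "Descent")]) ==
                    100))
  expect_false(is.na(rep2$mean_transition_delay))
  expect_gte(rep2$mean_transition_delay, 0)
  # shuffled-label control sits near the chance rate of the label mix
  set.seed(9)
  n <- length(tr$truth$mode)
  reps <- replicate(40, {
    fake <- sample(c("Level", "Ascent", "Descent"), n, replace = TRUE,
                   prob = c(0.5, 0.25, 0.25))
    t2 <- score_trial(fake, tr$truth$mode, tr$stream$fsr_heel,
                      tr$stream$fsr_toe)
    mean(t2$pred_mode == t2$true_mode)
  })
  expect_lt(mean(reps), 0.6)   # far below the trained pipeline's accuracy
})
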