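test_that("output filter has the right fixed point, step response and DC gain", {
  fs <- 200; eps <- 0.02
  # constant input is a fixed point
  expect_equal(filter_stream(rep(3.3, 50), eps, fs), rep(3.3, 50))
  # step response reaches 1 - exp(-1) at t = eps
  y <- c(0, rep(1, 400))
  yb <- filter_stream(y, eps, fs)
  k_eps <- 1 + fs * eps   # sample where (k-1)/fs = eps
  expect_equal(yb[k_eps], 1 - exp(-1), tolerance = 1e-3)
  # DC gain 1
  expect_lt(abs(yb[length(yb)] - 1), 1e-9)
})

test_that("filter output is bounded by the input's running extrema", {
  set.seed(6)
  y <- matrix(rnorm(900), 300, 3)
  yb <- filter_stream(y, 0.05, 100)
  for (k in 1:3) {
    expect_true(all(yb[, k] <= cummax(y[, k]) + 1e-12))
    expect_true(all(yb[, k] >= cummin(y[, k]) - 1e-12))
  }
})

test_that("class Gaussians: arithmetic, floor rule, symmetry, recovery", {
  st <- fit_class_gaussians(c(0, 0, 0.2, -0.2, 1, 1),
                            c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(st["mu1"]), 0)
  expect_equal(unname(st["sigma1"]), sd(c(0, 0, 0.2, -0.2)),
               tolerance = 1e-12)
  expect_equal(unname(st["sigma1"]), 0.163, tolerance = 1e-2)
  expect_equal(unname(st["mu2"]), 1)
  expect_equal(unname(st["sigma2"]), 1e-3)  # floored
  # swapping the labels swaps the class statistics
  sw <- fit_class_gaussians(c(0, 0, 0.2, -0.2, 1, 1),
                            !c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(sw[c("mu2", "sigma2")]), unname(st[c("mu1", "sigma1")]))
  expect_equal(unname(sw[c("mu1", "sigma1")]), unname(st[c("mu2", "sigma2")]))
  # large-sample recovery within 3 standard errors
  set.seed(61)
  n <- 4000
  z <- c(rnorm(n, 0.1, 0.2), rnorm(n, 0.9, 0.3))
  st <- fit_class_gaussians(z, rep(c(FALSE, TRUE), each = n))
  expect_lt(abs(st["mu1"] - 0.1), 3 * 0.2 / sqrt(n))
  expect_lt(abs(st["mu2"] - 0.9), 3 * 0.3 / sqrt(n))
  expect_error(fit_class_gaussians(z, rep(TRUE, 2 * n)), "both classes")
})

test_that("risk threshold: symmetry, the paper's 2:1 loss ratio, closed-form shift", {
  expect_equal(solve_threshold(0, 0.1, 1, 0.1, 1, 1), 0.5)
  # equal sigma, lambda12 = 2*lambda21: midpoint + sigma^2 ln 2 / (mu2-mu1)
  z <- solve_threshold(0, 0.1, 1, 0.1, 1.0, 0.5)
  expect_equal(z, 0.5 + 0.1^2 * log(2), tolerance = 1e-12)
  expect_equal(z, 0.5069, tolerance = 1e-4)
  # independent check by dense grid on |l12 p1 - l21 p2|
  zs <- seq(0, 1, by = 1e-5)
  gap <- abs(1.0 * dnorm(zs, 0, 0.1) - 0.5 * dnorm(zs, 1, 0.1))
  expect_equal(z, zs[which.min(gap)], tolerance = 1e-4)
  # conservative shift holds for any mu2 > mu1 at equal sigma
  for (mu2 in c(0.3, 1, 2.5))
    expect_gt(solve_threshold(0, 0.15, mu2, 0.15, 1.0, 0.5), mu2 / 2)
  # raising lambda12 never lowers the threshold
  zs <- sapply(c(0.5, 1, 2, 4, 8),
               function(l12) solve_threshold(0, 0.1, 1, 0.1, l12, 0.5))
  expect_true(all(diff(zs) >= 0))
})

test_that("risk threshold agrees with the dense-grid risk minimizer on random instances", {
  set.seed(71)
  for (i in 1:100) {
    mu1 <- runif(1, -1, 0.5)
    mu2 <- mu1 + runif(1, 0.5, 1.5)
    s1 <- runif(1, 0.05, 0.3); s2 <- runif(1, 0.05, 0.3)
    l21 <- runif(1, 0.3, 2); l12 <- l21 * runif(1, 0.5, 4)
    z <- solve_threshold(mu1, s1, mu2, s2, l12, l21)
    zg <- grid_threshold(mu1, s1, mu2, s2, l12, l21)
    step <- (mu2 + 2 * s2 - mu1 + 2 * s1) / 20000
    expect_lt(abs(z - zg), 2 * step)
  }
})

test_that("binarization applies per-element thresholds with ties to 1", {
  th <- c(0.5, 0.5, 0.5)
  expect_equal(binarize(c(0.9, 0.1, 0.1), th), c(1, 0, 0))
  expect_equal(binarize(c(0.2, 0.2, 0.2), th), c(0, 0, 0))
  expect_equal(binarize(th, th), c(1, 1, 1))
  expect_equal(binarize(rbind(c(0.9, 0.1, 0.1), c(0.2, 0.6, 0.2)), th),
               rbind(c(1, 0, 0), c(0, 1, 0)))
})

test_that("mode mapping inverts the target coding and defaults to Undetermined", {
  expect_equal(map_mode(c(1, 0, 0)), "Ascent")
  expect_equal(map_mode(c(0, 1, 0)), "Level")
  expect_equal(map_mode(c(0, 0, 1)), "Descent")
  expect_equal(map_mode(c(0, 0, 0)), "Undetermined")
  expect_equal(map_mode(c(1, 1, 0)), "Undetermined")
  expect_equal(map_mode(c(1, 1, 1)), "Undetermined")
  modes <- c("Ascent", "Level", "Descent", "Undetermined")
  expect_equal(map_mode(mode_to_target(modes)), modes)
  expect_error(mode_to_target("Sideways"), "unknown mode")
})

test_that("fit_decision_model produces finite thresholds between the class means", {
  cfg <- scenario_config("stairs", seed = 14, n_subjects = 1, n_trials = 1)
  tr <- generate_trial(cfg, 1, 1)
  sig <- process_signals(tr$stream)
  ts <- build_training_set(sig, tr$truth$mode, stride = 10)
  m <- ann_train(ts$X, ts$targets, train_config(seed = 4, max_epochs = 60))
  d <- fit_decision_model(m, sig, tr$truth$mode, fs = 200)
  expect_length(d$thresholds, 3)
  expect_true(all(is.finite(d$thresholds)))
  expect_true(all(d$thresholds > d$class_stats[, "mu1"] - 0.5))
  expect_true(all(d$thresholds < d$class_stats[, "mu2"] + 0.5))
  expect_equal(d$loss, matrix(c(0, 0.5, 1.0, 0), 2, 2))
  expect_equal(d$loss[1, 2], 2 * d$loss[2, 1])
  # classification of a stream yields one label per sample
  lab <- classify_stream(m, d, sig, fs = 200)
  expect_length(lab, length(sig$v_z))
  expect_true(all(lab %in% c("Ascent", "Level", "Descent", "Undetermined")))
  # fitting with a mode missing from training is an error
  keep <- tr$truth$mode != "Descent"
  sig2 <- list(v_z = sig$v_z[keep], theta = sig$theta[keep])
  class(sig2) <- "processed_signals"
  expect_error(fit_decision_model(m, sig2, tr$truth$mode[keep], fs = 200),
               "all three gait modes")
})
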