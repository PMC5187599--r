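test_that("logsig matches its closed form and symmetry", {
  expect_equal(logsig(0), 0.5)
  expect_equal(logsig(10), 1 / (exp(-10) + 1))
  expect_equal(logsig(10), 0.9999546, tolerance = 1e-7)
  for (n in c(1, 3.7, 50))
    expect_equal(logsig(-n), 1 - logsig(n), tolerance = 1e-15)
  expect_true(logsig(700) <= 1 && logsig(-700) >= 0)
})

test_that("build_input_vector standardizes, concatenates and pads", {
  m <- toy_model()
  # windows equal to the stored means are a standardization fixed point
  x <- build_input_vector(m$input_mean[1:6], m$input_mean[7:12], m)
  expect_equal(unname(x), rep(0, 12))
  # unit scale / zero mean: plain concatenation, velocity block first
  m0 <- network_model(m$w_h, m$b_h, m$w_o, m$b_o)
  x <- build_input_vector(rep(0.1, 6), rep(5, 6), m0)
  expect_equal(unname(x), c(rep(0.1, 6), rep(5, 6)))
  # short window at stream start: repeat earliest sample, flagged
  x <- build_input_vector(c(1, 2, 3), c(4, 5, 6), m0)
  expect_equal(as.numeric(x), c(1, 1, 1, 1, 2, 3, 4, 4, 4, 4, 5, 6))
  expect_true(attr(x, "padded"))
})

test_that("forward pass follows the layer equations", {
  z <- network_model(matrix(0, 10, 12), rep(0, 10), matrix(0, 3, 10),
                     rep(0, 3))
  expect_equal(ann_forward(z, rep(1, 12)), rep(0, 3))
  # one-hidden-unit hand case: y = 2 * logsig(0) + 1 = 2
  m1 <- network_model(matrix(0, 1, 2), 0, matrix(2, 1, 1), 1, n_delays = 1)
  expect_equal(ann_forward(m1, c(0.3, -0.4)), 2)
  expect_error(ann_forward(z, rep(1, 5)), "input size")
})

test_that("forward pass and cost match brute-force oracles", {
  set.seed(21)
  for (i in 1:10) {
    m <- network_model(matrix(rnorm(120), 10, 12), rnorm(10),
                       matrix(rnorm(30), 3, 10), rnorm(3))
    x <- rnorm(12)
    expect_equal(ann_forward(m, x), forward_oracle(m, x),
                 tolerance = 1e-12)
  }
  m <- toy_model()
  X <- matrix(rnorm(20 * 12), 20, 12)
  targets <- mode_to_target(sample(c("Ascent", "Level", "Descent"), 20,
                                   replace = TRUE))
  got <- ann_cost(m, X, targets, alpha = 1.3, beta = 0.2)
  expect_equal(got$E, cost_oracle(m, X, targets, 1.3, 0.2),
               tolerance = 1e-10)
  expect_equal(got$E, 1.3 * got$E_D + 0.2 * got$E_w)
})

test_that("cost arithmetic on the zero model", {
  z <- network_model(matrix(0, 10, 12), rep(0, 10), matrix(0, 3, 10),
                     rep(0, 3))
  X <- matrix(0, 4, 12)
  expect_equal(ann_cost(z, X, mode_to_target(rep("Undetermined", 4)))$E, 0)
  got <- ann_cost(z, X[1, , drop = FALSE], mode_to_target("Level"),
                  alpha = 1, beta = 1)
  expect_equal(got$E_D, 1)
  expect_equal(got$E_w, 0)
  expect_equal(got$E, 1)
})

test_that("predict_stream equals the per-sample windowed forward pass", {
  m <- toy_model()
  set.seed(4)
  n <- 60
  sig <- list(v_z = rnorm(n), theta = rnorm(n, sd = 10))
  Y <- predict_stream(m, sig)
  expect_equal(dim(Y), c(n, 3))
  for (i in c(1, 3, 6, 17, 44, n)) {
    w <- max(1, i - 5):i
    y <- ann_forward(m, as.numeric(build_input_vector(sig$v_z[w],
                                                      sig$theta[w], m)))
    expect_equal(unname(Y[i, ]), y, tolerance = 1e-12)
  }
  # constant signals give constant output
  Yc <- predict_stream(m, list(v_z = rep(0.2, 30), theta = rep(7, 30)))
  expect_true(all(abs(sweep(Yc, 2, Yc[1, ])) < 1e-12))
})

test_that("training separates a noise-free two-class toy problem", {
  set.seed(31)
  X <- rbind(matrix(rnorm(10 * 4, mean = -2, sd = 0.3), 10, 4),
             matrix(rnorm(10 * 4, mean = 2, sd = 0.3), 10, 4))
  targets <- rbind(matrix(rep(c(0, 1, 0), each = 10), 10, 3),
                   matrix(rep(c(1, 0, 0), each = 10), 10, 3))
  cfg <- train_config(seed = 2, n_hidden = 4, n_delays = 2,
                      max_epochs = 150)
  m <- ann_train(X, targets, cfg)
  Y <- ann_forward(m, .std <- sweep(sweep(X, 2, m$input_mean), 2,
                                    m$input_scale, "/"))
  expect_equal(map_mode((Y >= 0.5) + 0), map_mode(targets))
})

test_that("accepted LM steps never increase the cost at the step's alpha, beta", {
  cfg <- scenario_config("ramp", seed = 12, n_subjects = 1, n_trials = 1)
  tr <- generate_trial(cfg, 1, 1)
  sig <- process_signals(tr$stream)
  ts <- build_training_set(sig, tr$truth$mode, stride = 12)
  m <- ann_train(ts$X, ts$targets, train_config(seed = 3, max_epochs = 40))
  h <- attr(m, "history")
  acc <- h[h$accepted, ]
  expect_gt(nrow(acc), 5)
  expect_true(all(acc$E_after <= acc$E_before))
})

test_that("a beta-dominated cost drives the weights toward zero", {
  set.seed(41)
  X <- matrix(rnorm(40 * 4), 40, 4)
  targets <- mode_to_target(sample(c("Ascent", "Level"), 40, replace = TRUE))
  cfg_free <- train_config(seed = 5, n_hidden = 4, n_delays = 2,
                           fixed_hyper = TRUE, alpha_init = 1,
                           beta_init = 1e-8, max_epochs = 80)
  cfg_reg <- train_config(seed = 5, n_hidden = 4, n_delays = 2,
                          fixed_hyper = TRUE, alpha_init = 1,
                          beta_init = 1e6, max_epochs = 80)
  w2 <- function(m) sum(m$w_h^2) + sum(m$b_h^2) + sum(m$w_o^2) + sum(m$b_o^2)
  expect_lt(w2(ann_train(X, targets, cfg_reg)),
            1e-4 * w2(ann_train(X, targets, cfg_free)))
})

test_that("training is deterministic and validates its inputs", {
  set.seed(51)
  X <- matrix(rnorm(30 * 4), 30, 4)
  targets <- mode_to_target(sample(c("Ascent", "Descent"), 30,
                                   replace = TRUE))
  cfg <- train_config(seed = 9, n_hidden = 3, n_delays = 2, max_epochs = 25)
  m1 <- ann_train(X, targets, cfg)
  m2 <- ann_train(X, targets, cfg)
  expect_identical(m1$w_h, m2$w_h)
  expect_identical(m1$b_o, m2$b_o)
  expect_identical(m1$alpha, m2$alpha)
  expect_error(ann_train(X, mode_to_target(rep("Level", 30)), cfg),
               "degenerate")
  expect_error(ann_train(X[1:5, ], targets[1:5, ], cfg), "at least 10")
})
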