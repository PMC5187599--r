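# Independent oracles used across the suite. These deliberately use
# different formulas/code paths than the package implementation.

# quaternion -> rotation matrix (standard direction-cosine construction),
# independent of the cross-product form used by rotate_to_world()
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# brute-force forward pass: explicit loops straight from the layer equations
forward_oracle <- function(model, x) {
  nh <- nrow(model$w_h)
  a <- numeric(nh)
  for (j in seq_len(nh)) {
    n <- model$b_h[j]
    for (i in seq_along(x)) n <- n + model$w_h[j, i] * x[i]
    a[j] <- 1 / (exp(-n) + 1)
  }
  y <- numeric(nrow(model$w_o))
  for (k in seq_along(y)) {
    y[k] <- model$b_o[k]
    for (j in seq_len(nh)) y[k] <- y[k] + model$w_o[k, j] * a[j]
  }
  y
}

# brute-force regularized cost
cost_oracle <- function(model, X, targets, alpha, beta) {
  E_D <- 0
  for (i in seq_len(nrow(X))) {
    y <- forward_oracle(model, X[i, ])
    E_D <- E_D + sum((targets[i, ] - y)^2)
  }
  E_w <- sum(c(model$w_h, model$b_h, model$w_o, model$b_o)^2)
  alpha * E_D + beta * E_w
}

# expected Bayes risk of threshold z (equal priors, zero diagonal losses)
bayes_risk <- function(z, mu1, s1, mu2, s2, l12, l21) {
  l12 * stats::pnorm(z, mu1, s1, lower.tail = FALSE) +
    l21 * stats::pnorm(z, mu2, s2)
}

# dense-grid risk minimizer
grid_threshold <- function(mu1, s1, mu2, s2, l12, l21, n_grid = 20001L) {
  zs <- seq(mu1 - 2 * s1, mu2 + 2 * s2, length.out = n_grid)
  zs[which.min(bayes_risk(zs, mu1, s1, mu2, s2, l12, l21))]
}

# cumulative trapezoid used as an integration oracle
trapz <- function(y, dt) sum((y[-1] + y[-length(y)]) / 2) * dt

# small hand-built network with fixed weights for plumbing tests
toy_model <- function(n_delays = 6L) {
  set.seed(99)
  network_model(w_h = matrix(stats::rnorm(10 * 2 * n_delays, sd = 0.3),
                             10, 2 * n_delays),
                b_h = stats::rnorm(10, sd = 0.3),
                w_o = matrix(stats::rnorm(30, sd = 0.3), 3, 10),
                b_o = stats::rnorm(3, sd = 0.3),
                n_delays = n_delays)
}
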