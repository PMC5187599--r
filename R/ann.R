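# Feed-forward network for gait-mode recognition.
#
# Architecture: 12 inputs (vertical foot velocity and foot pitch, each with
# six tapped delays), one hidden layer of 10 log-sigmoid neurons, and a
# linear output layer of 3 neurons whose target coding is
#   (1,0,0) Ascent, (0,1,0) Level, (0,0,1) Descent, (0,0,0) Undetermined.
# Training minimizes E = alpha * sum||t - y||^2 + beta * E_w (E_w = sum of
# squared weights and biases) by Levenberg-Marquardt with evidence-framework
# re-estimation of alpha and beta (Bayesian regularization). Note the
# convention: alpha multiplies the error term and beta the weight penalty.

#' Log-sigmoid activation
#'
#' `logsig(n) = 1 / (exp(-n) + 1)`, bounded in (0, 1).
#'
#' @param n numeric vector or matrix.
#' @return values in (0, 1), same shape as `n`.
#' @export
logsig <- function(n) 1 / (exp(-n) + 1)

#' Training configuration for the gait-mode network
#'
#' @param max_epochs maximum Levenberg-Marquardt epochs.
#' @param mu_init,mu_inc,mu_dec initial damping and its multiplicative
#'   schedule (increase on a rejected step, decrease on an accepted one).
#' @param mu_max damping ceiling; training stops when no step is accepted
#'   below it.
#' @param tol_grad stop when the cost-gradient norm falls below this.
#' @param tol_cost stop when the relative cost decrease of an accepted epoch
#'   falls below this.
#' @param seed integer seed for weight initialization.
#' @param reestimate_every epochs between evidence updates of `alpha`, `beta`.
#' @param fixed_hyper if `TRUE`, keep `alpha_init`/`beta_init` fixed (no
#'   evidence re-estimation); used mainly for diagnostics.
#' @param alpha_init,beta_init initial cost-function parameters (`alpha` on
#'   the error term, `beta` on the weight penalty).
#' @param n_hidden hidden-layer size.
#' @param n_delays tapped delays per input signal.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 300L, mu_init = 1e-3, mu_inc = 10,
                         mu_dec = 0.1, mu_max = 1e10, tol_grad = 1e-7,
                         tol_cost = 1e-8, seed = 1L, reestimate_every = 1L,
                         fixed_hyper = FALSE, alpha_init = 1,
                         beta_init = 0.005, n_hidden = 10L, n_delays = 6L) {
  stopifnot(max_epochs >= 1, mu_init > 0, mu_inc > 1, mu_dec > 0,
            mu_dec < 1, tol_grad > 0, tol_cost > 0, reestimate_every >= 1,
            alpha_init > 0, beta_init > 0, n_hidden >= 1, n_delays >= 1)
  structure(list(max_epochs = as.integer(max_epochs), mu_init = mu_init,
                 mu_inc = mu_inc, mu_dec = mu_dec, mu_max = mu_max,
                 tol_grad = tol_grad, tol_cost = tol_cost,
                 seed = as.integer(seed),
                 reestimate_every = as.integer(reestimate_every),
                 fixed_hyper = isTRUE(fixed_hyper),
                 alpha_init = alpha_init, beta_init = beta_init,
                 n_hidden = as.integer(n_hidden),
                 n_delays = as.integer(n_delays)),
            class = "train_config")
}

#' Construct a network model
#'
#' Usually produced by [ann_train()]; exposed so hand-built models can be
#' used in tests and examples.
#'
#' @param w_h hidden weights (`n_hidden x n_in`), `b_h` hidden biases.
#' @param b_h,w_o,b_o remaining weights/biases (`w_o` is `n_out x n_hidden`).
#' @param input_mean,input_scale per-element standardization constants
#'   (length `n_in`); inputs are transformed as `(x - mean) / scale`.
#' @param alpha,beta cost-function parameters stored with the fit.
#' @param n_delays tapped delays per signal (`n_in = 2 * n_delays`).
#' @return object of class `network_model`.
#' @export
network_model <- function(w_h, b_h, w_o, b_o,
                          input_mean = rep(0, ncol(w_h)),
                          input_scale = rep(1, ncol(w_h)),
                          alpha = 1, beta = 0.005,
                          n_delays = ncol(w_h) / 2L) {
  w_h <- as.matrix(w_h); w_o <- as.matrix(w_o)
  stopifnot(nrow(w_h) == length(b_h), nrow(w_o) == length(b_o),
            ncol(w_o) == nrow(w_h), length(input_mean) == ncol(w_h),
            length(input_scale) == ncol(w_h), all(input_scale > 0),
            all(is.finite(w_h)), all(is.finite(w_o)),
            all(is.finite(b_h)), all(is.finite(b_o)))
  structure(list(w_h = w_h, b_h = as.numeric(b_h), w_o = w_o,
                 b_o = as.numeric(b_o),
                 input_mean = as.numeric(input_mean),
                 input_scale = as.numeric(input_scale),
                 alpha = alpha, beta = beta,
                 n_delays = as.integer(n_delays),
                 n_hidden = nrow(w_h), n_out = nrow(w_o)),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(paste0("<network_model> %d-%d-%d feed-forward ",
                     "(%d tapped delays/signal), alpha=%.4g beta=%.4g\n"),
              ncol(x$w_h), x$n_hidden, x$n_out, x$n_delays, x$alpha, x$beta))
  invisible(x)
}

#' Assemble one standardized tapped-delay input vector
#'
#' Concatenates the `n_delays` most recent velocity samples and the
#' `n_delays` most recent pitch samples (newest last in each block) and
#' standardizes each element with the model's stored constants. Short windows
#' at the stream start are padded by repeating the earliest sample; the
#' result then carries attribute `padded = TRUE`.
#'
#' @param v_win,theta_win most recent velocity (m/s) and pitch (degrees)
#'   samples, newest last, at most `n_delays` each.
#' @param model a [network_model()].
#' @return standardized numeric vector of length `2 * n_delays`.
#' @export
build_input_vector <- function(v_win, theta_win, model) {
  d <- model$n_delays
  pad <- length(v_win) < d || length(theta_win) < d
  pad_front <- function(w) {
    if (length(w) == 0L) stop("empty input window", call. = FALSE)
    if (length(w) < d) c(rep(w[1L], d - length(w)), w) else utils::tail(w, d)
  }
  x <- c(pad_front(v_win), pad_front(theta_win))
  x <- (x - model$input_mean) / model$input_scale
  if (pad) attr(x, "padded") <- TRUE
  x
}

# Tapped-delay design matrix for whole streams: row i holds
# [v(i-d+1)..v(i), theta(i-d+1)..theta(i)], start padded with sample 1.
.delay_matrix <- function(v, theta, d) {
  n <- length(v)
  vp <- c(rep(v[1L], d - 1L), v)
  tp <- c(rep(theta[1L], d - 1L), theta)
  Xv <- stats::embed(vp, d)[, d:1, drop = FALSE]
  Xt <- stats::embed(tp, d)[, d:1, drop = FALSE]
  X <- cbind(Xv, Xt)
  attr(X, "padded_rows") <- seq_len(min(d - 1L, n))
  X
}

.standardize <- function(X, model) {
  sweep(sweep(X, 2L, model$input_mean, "-"), 2L, model$input_scale, "/")
}

#' Network forward pass
#'
#' Hidden activations `a_h = logsig(w_h x + b_h)`, linear output
#' `y = w_o a_h + b_o`. `x` must already be standardized (see
#' [build_input_vector()]).
#'
#' @param model a [network_model()].
#' @param x standardized input vector, or `n x n_in` matrix of rows.
#' @return output vector of length `n_out` (or `n x n_out` matrix).
#' @export
ann_forward <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != ncol(model$w_h))
      stop("input length ", length(x), " does not match network input size ",
           ncol(model$w_h), call. = FALSE)
    a_h <- logsig(drop(model$w_h %*% x) + model$b_h)
    drop(model$w_o %*% a_h) + model$b_o
  } else {
    if (ncol(x) != ncol(model$w_h))
      stop("input width does not match network input size", call. = FALSE)
    a_h <- logsig(tcrossprod(x, model$w_h) +
                    matrix(model$b_h, nrow(x), model$n_hidden, byrow = TRUE))
    tcrossprod(a_h, model$w_o) +
      matrix(model$b_o, nrow(x), model$n_out, byrow = TRUE)
  }
}

#' Regularized training cost
#'
#' `E = alpha * E_D + beta * E_w` with `E_D` the summed squared output error
#' over the training set and `E_w` the sum of squares of all weights and
#' biases.
#'
#' @param model a [network_model()].
#' @param X standardized input matrix (`n x n_in`).
#' @param targets target matrix (`n x n_out`), rows from the mode coding.
#' @param alpha,beta cost parameters; default to the model's stored values.
#' @return list with `E`, `E_D`, `E_w`.
#' @export
ann_cost <- function(model, X, targets, alpha = model$alpha,
                     beta = model$beta) {
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  Y <- ann_forward(model, X)
  E_D <- sum((targets - Y)^2)
  E_w <- sum(model$w_h^2) + sum(model$b_h^2) +
    sum(model$w_o^2) + sum(model$b_o^2)
  list(E = alpha * E_D + beta * E_w, E_D = E_D, E_w = E_w)
}

# ---- parameter vector plumbing ------------------------------------------

.pack_params <- function(m)
  c(as.vector(m$w_h), m$b_h, as.vector(m$w_o), m$b_o)

.unpack_params <- function(p, n_in, n_h, n_o) {
  i <- 0L
  w_h <- matrix(p[i + seq_len(n_h * n_in)], n_h, n_in); i <- i + n_h * n_in
  b_h <- p[i + seq_len(n_h)]; i <- i + n_h
  w_o <- matrix(p[i + seq_len(n_o * n_h)], n_o, n_h); i <- i + n_o * n_h
  b_o <- p[i + seq_len(n_o)]
  list(w_h = w_h, b_h = b_h, w_o = w_o, b_o = b_o)
}

# Residual Jacobian de/dp for e = t - y, rows stacked output-major
# (rows (k-1)*n + i for output k, sample i), columns in .pack_params order.
.residual_jacobian <- function(X, w_h, b_h, w_o, b_o) {
  n <- nrow(X); n_in <- ncol(X); n_h <- nrow(w_h); n_o <- nrow(w_o)
  A <- logsig(tcrossprod(X, w_h) + matrix(b_h, n, n_h, byrow = TRUE))
  S <- A * (1 - A)
  k_par <- n_h * n_in + n_h + n_o * n_h + n_o
  J <- matrix(0, n * n_o, k_par)
  off_bh <- n_h * n_in
  off_wo <- off_bh + n_h
  off_bo <- off_wo + n_o * n_h
  for (k in seq_len(n_o)) {
    rows <- (k - 1L) * n + seq_len(n)
    for (j in seq_len(n_h)) {
      sj <- w_o[k, j] * S[, j]
      J[rows, (seq_len(n_in) - 1L) * n_h + j] <- -sj * X
      J[rows, off_bh + j] <- -sj
      J[rows, off_wo + (j - 1L) * n_o + k] <- -A[, j]
    }
    J[rows, off_bo + k] <- -1
  }
  list(J = J, A = A)
}

# Nguyen-Widrow-style seeded initialization
.init_params <- function(n_in, n_h, n_o) {
  w_h <- matrix(stats::runif(n_h * n_in, -0.5, 0.5), n_h, n_in)
  target_norm <- 0.7 * n_h^(1 / n_in)
  w_h <- w_h * target_norm / pmax(sqrt(rowSums(w_h^2)), 1e-12)
  b_h <- seq(-1, 1, length.out = n_h) * target_norm *
    sign(stats::runif(n_h) - 0.5)
  w_o <- matrix(stats::runif(n_o * n_h, -0.5, 0.5), n_o, n_h)
  b_o <- stats::runif(n_o, -0.5, 0.5)
  list(w_h = w_h, b_h = b_h, w_o = w_o, b_o = b_o)
}

#' Train the gait-mode network
#'
#' Levenberg-Marquardt minimization of the regularized cost
#' `E = alpha * E_D + beta * E_w` on the Gauss-Newton approximation of its
#' Hessian, with the damping `mu` increased on rejected steps and decreased on
#' accepted ones. Unless `cfg$fixed_hyper`, `alpha` and `beta` are
#' re-estimated every `cfg$reestimate_every` epochs by the evidence framework:
#' with `k` free parameters and Hessian `H = 2 alpha J'J + 2 beta I`, the
#' effective number of parameters is `gamma = k - 2 beta tr(H^-1)`, then
#' `beta = gamma / (2 E_w)` and `alpha = (n_resid - gamma) / (2 E_D)`.
#' Inputs are z-scored by training statistics (stored in the model so
#' inference matches training); mixed units (m/s vs degrees) make this
#' necessary for conditioning.
#'
#' @param X raw (unstandardized) tapped-delay input matrix, `n x (2*n_delays)`
#'   — see [build_training_set()].
#' @param targets `n x 3` target matrix with rows from [mode_to_target()].
#' @param cfg a [train_config()].
#' @return a [network_model()] with attached `history` attribute: one row per
#'   epoch with the cost before/after the accepted step (at that epoch's
#'   `alpha`, `beta`), `E_D`, `E_w`, `mu`, `gamma`, and acceptance flag.
#' @export
ann_train <- function(X, targets, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  X <- as.matrix(X); targets <- as.matrix(targets)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 training samples", call. = FALSE)
  if (nrow(targets) != n) stop("X and targets row counts differ",
                               call. = FALSE)
  if (nrow(unique(targets)) < 2L)
    stop("degenerate training data: fewer than 2 distinct target classes",
         call. = FALSE)
  n_in <- ncol(X); n_h <- cfg$n_hidden; n_o <- ncol(targets)

  mu_x <- colMeans(X)
  sd_x <- apply(X, 2L, stats::sd)
  sd_x[!is.finite(sd_x) | sd_x < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2L, mu_x, "-"), 2L, sd_x, "/")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)
  par0 <- .init_params(n_in, n_h, n_o)
  w_h <- par0$w_h; b_h <- par0$b_h; w_o <- par0$w_o; b_o <- par0$b_o

  alpha <- cfg$alpha_init; beta <- cfg$beta_init
  mu <- cfg$mu_init
  k_par <- n_h * n_in + n_h + n_o * n_h + n_o
  n_res <- n * n_o
  eval_cost <- function(w_h, b_h, w_o, b_o) {
    A <- logsig(tcrossprod(Xs, w_h) + matrix(b_h, n, n_h, byrow = TRUE))
    Y <- tcrossprod(A, w_o) + matrix(b_o, n, n_o, byrow = TRUE)
    E <- targets - Y
    E_D <- sum(E^2)
    E_w <- sum(w_h^2) + sum(b_h^2) + sum(w_o^2) + sum(b_o^2)
    list(E_D = E_D, E_w = E_w, e = as.vector(E))
  }
  cur <- eval_cost(w_h, b_h, w_o, b_o)
  hist <- vector("list", cfg$max_epochs)
  gamma <- NA_real_
  stop_reason <- "max_epochs"

  for (epoch in seq_len(cfg$max_epochs)) {
    jb <- .residual_jacobian(Xs, w_h, b_h, w_o, b_o)
    J <- jb$J
    p <- c(as.vector(w_h), b_h, as.vector(w_o), b_o)
    JtJ <- crossprod(J)
    Jte <- drop(crossprod(J, cur$e))
    grad <- 2 * (alpha * Jte + beta * p)
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < cfg$tol_grad) { stop_reason <- "tol_grad"; break }

    E_before <- alpha * cur$E_D + beta * cur$E_w
    accepted <- FALSE
    while (mu <= cfg$mu_max) {
      Hd <- alpha * JtJ + diag(beta + mu, k_par)
      step <- tryCatch(solve(Hd, alpha * Jte + beta * p),
                       error = function(e) NULL)
      if (is.null(step)) { mu <- mu * cfg$mu_inc; next }
      p_new <- p - step
      cand <- .unpack_params(p_new, n_in, n_h, n_o)
      new <- eval_cost(cand$w_h, cand$b_h, cand$w_o, cand$b_o)
      E_new <- alpha * new$E_D + beta * new$E_w
      if (is.finite(E_new) && E_new < E_before) {
        w_h <- cand$w_h; b_h <- cand$b_h; w_o <- cand$w_o; b_o <- cand$b_o
        cur <- new
        mu <- max(mu * cfg$mu_dec, 1e-20)
        accepted <- TRUE
        break
      }
      mu <- mu * cfg$mu_inc
    }
    E_after <- alpha * cur$E_D + beta * cur$E_w
    if (!accepted) {
      if (!is.finite(E_before))
        stop("training failure: cost diverged", call. = FALSE)
      hist[[epoch]] <- data.frame(epoch = epoch, E_before = E_before,
                                  E_after = E_after, E_D = cur$E_D,
                                  E_w = cur$E_w, alpha = alpha, beta = beta,
                                  mu = mu, gamma = gamma, accepted = FALSE)
      stop_reason <- "mu_max"
      break
    }

    if (!cfg$fixed_hyper && epoch %% cfg$reestimate_every == 0L) {
      jb2 <- .residual_jacobian(Xs, w_h, b_h, w_o, b_o)
      JtJ2 <- crossprod(jb2$J)
      trHinv <- tryCatch(
        sum(diag(solve(alpha * JtJ2 + diag(beta, k_par)))) / 2,
        error = function(e) NA_real_)
      if (is.finite(trHinv)) {
        gamma <- min(max(k_par - 2 * beta * trHinv, 1e-6), k_par)
        beta <- gamma / (2 * max(cur$E_w, 1e-10))
        alpha <- max(n_res - gamma, 1e-6) / (2 * max(cur$E_D, 1e-10))
      }
    }

    hist[[epoch]] <- data.frame(epoch = epoch, E_before = E_before,
                                E_after = E_after, E_D = cur$E_D,
                                E_w = cur$E_w, alpha = alpha, beta = beta,
                                mu = mu, gamma = gamma, accepted = TRUE)
    if (E_before - E_after < cfg$tol_cost * max(E_before, 1e-12)) {
      stop_reason <- "tol_cost"; break
    }
  }

  model <- network_model(w_h, b_h, w_o, b_o, input_mean = mu_x,
                         input_scale = sd_x, alpha = alpha, beta = beta,
                         n_delays = cfg$n_delays)
  attr(model, "history") <- do.call(rbind, hist[!vapply(hist, is.null,
                                                        logical(1))])
  attr(model, "stop_reason") <- stop_reason
  model
}

#' Causal per-sample network outputs for a whole trial
#'
#' Slides the tapped-delay window causally over the processed signals and
#' returns one raw network output per sample; the first `n_delays - 1`
#' samples use the start-padding rule (delay line filled with the first
#' sample).
#'
#' @param model a [network_model()].
#' @param signals a `processed_signals` object from [process_signals()], or
#'   any list with `v_z` and `theta`.
#' @return `n x 3` matrix of raw outputs `y`.
#' @export
predict_stream <- function(model, signals) {
  v <- signals$v_z; theta <- signals$theta
  if (!length(v)) stop("empty signals", call. = FALSE)
  X <- .delay_matrix(v, theta, model$n_delays)
  ann_forward(model, .standardize(X, model))
}

#' Build a tapped-delay training set from processed signals
#'
#' Converts one or more labelled trials into the raw input matrix and target
#' matrix consumed by [ann_train()]. Optionally keeps every `stride`-th
#' sample: neighbouring 200 Hz samples are highly autocorrelated, so modest
#' decimation of training rows loses little information while shrinking the
#' Jacobian.
#'
#' @param signals_list list of `processed_signals` (or a single one).
#' @param labels_list list of per-sample mode-label character vectors
#'   matching `signals_list`.
#' @param n_delays tapped delays per signal.
#' @param stride keep every `stride`-th training row (default 1 = all).
#' @return list with raw `X` (`n x 2*n_delays`) and `targets` (`n x 3`).
#' @export
build_training_set <- function(signals_list, labels_list, n_delays = 6L,
                               stride = 1L) {
  if (inherits(signals_list, "processed_signals"))
    signals_list <- list(signals_list)
  if (is.character(labels_list)) labels_list <- list(labels_list)
  stopifnot(length(signals_list) == length(labels_list))
  Xs <- list(); Ts <- list()
  for (i in seq_along(signals_list)) {
    sg <- signals_list[[i]]
    lab <- labels_list[[i]]
    stopifnot(length(lab) == length(sg$v_z))
    X <- .delay_matrix(sg$v_z, sg$theta, n_delays)
    keep <- seq.int(n_delays, nrow(X), by = stride) # skip padded rows
    Xs[[i]] <- X[keep, , drop = FALSE]
    Ts[[i]] <- mode_to_target(lab[keep])
  }
  list(X = do.call(rbind, Xs), targets = do.call(rbind, Ts))
}
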