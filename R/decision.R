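# Conditioning of the raw network outputs into gait-mode decisions:
# first-order low-pass filtering, per-element minimum-Bayes-risk thresholds
# between two Gaussian classes, binarization, and the mode mapping.

MODE_LEVELS <- c("Ascent", "Level", "Descent", "Undetermined")

.MODE_CODING <- rbind(Ascent = c(1, 0, 0),
                      Level = c(0, 1, 0),
                      Descent = c(0, 0, 1),
                      Undetermined = c(0, 0, 0))

#' Gait-mode target coding
#'
#' The three-element target coding: Ascent `(1,0,0)`, Level `(0,1,0)`,
#' Descent `(0,0,1)`, Undetermined `(0,0,0)`. `mode_to_target` maps labels to
#' coding rows; [map_mode()] is its inverse on binary vectors.
#'
#' @param mode character vector of labels among
#'   `c("Ascent", "Level", "Descent", "Undetermined")`.
#' @return `length(mode) x 3` numeric matrix of target rows.
#' @export
mode_to_target <- function(mode) {
  mode <- as.character(mode)
  bad <- setdiff(unique(mode), rownames(.MODE_CODING))
  if (length(bad))
    stop("unknown mode label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  .MODE_CODING[mode, , drop = FALSE]
}

#' Map a binary output vector to a gait mode
#'
#' `(1,0,0)` -> Ascent, `(0,1,0)` -> Level, `(0,0,1)` -> Descent,
#' `(0,0,0)` -> Undetermined. Any other 0/1 combination (two or three active
#' elements) is not a defined coding and maps to Undetermined.
#'
#' @param y_hat binary 3-vector, or `n x 3` matrix of them.
#' @return character label(s).
#' @export
map_mode <- function(y_hat) {
  if (is.null(dim(y_hat))) y_hat <- matrix(y_hat, nrow = 1L)
  stopifnot(ncol(y_hat) == 3L, all(y_hat %in% c(0, 1)))
  key <- y_hat %*% c(4, 2, 1)
  out <- rep("Undetermined", nrow(y_hat))
  out[key == 4] <- "Ascent"
  out[key == 2] <- "Level"
  out[key == 1] <- "Descent"
  out
}

#' First-order low-pass filter of the network output
#'
#' Discretizes the continuous filter `epsilon * dy_bar/dt + y_bar = y`
#' (initial condition `y_bar(0) = y(0)`) with the exact exponential
#' integrator for piecewise-constant input:
#' `y_bar[k] = y_bar[k-1] + (1 - exp(-1/(fs*epsilon))) * (y[k] - y_bar[k-1])`.
#'
#' @param y `n x m` matrix of raw outputs (or a numeric vector).
#' @param epsilon filter time constant, seconds (default 0.02).
#' @param fs sampling rate, Hz.
#' @return filtered matrix (or vector), same shape as `y`.
#' @export
filter_stream <- function(y, epsilon = 0.02, fs) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  vec <- is.null(dim(y))
  if (vec) y <- matrix(y, ncol = 1L)
  a <- 1 - exp(-1 / (fs * epsilon))
  out <- y
  for (k in seq_len(nrow(y))[-1L])
    out[k, ] <- out[k - 1L, ] + a * (y[k, ] - out[k - 1L, ])
  if (vec) drop(out) else out
}

#' Per-class Gaussian statistics of a filtered output element
#'
#' For each output element two classes are modelled: class 1 where the
#' element's target value is 0 and class 2 where it is 1, each with a
#' Gaussian density. Standard deviations are floored at `sigma_floor` so
#' (near-)noise-free training data cannot produce degenerate densities.
#'
#' @param z filtered element values (numeric vector).
#' @param is_class2 logical vector: `TRUE` where the element's target is 1.
#' @param sigma_floor minimum standard deviation.
#' @return named vector `c(mu1, sigma1, mu2, sigma2)`.
#' @export
fit_class_gaussians <- function(z, is_class2, sigma_floor = 1e-3) {
  stopifnot(length(z) == length(is_class2))
  if (!any(is_class2) || all(is_class2))
    stop("invalid training data: both classes must be present", call. = FALSE)
  z1 <- z[!is_class2]; z2 <- z[is_class2]
  sd_or_floor <- function(x) {
    s <- if (length(x) > 1L) stats::sd(x) else 0
    max(s, sigma_floor)
  }
  c(mu1 = mean(z1), sigma1 = sd_or_floor(z1),
    mu2 = mean(z2), sigma2 = sd_or_floor(z2))
}

#' Minimum-Bayes-risk threshold between two Gaussian classes
#'
#' Solves `lambda12 * p(z | w1) = lambda21 * p(z | w2)` for the decision
#' threshold `z_o`, where class 1 (`mu1 < mu2`) is "element should be 0" and
#' class 2 "element should be 1", and `lambda12` is the loss of calling a
#' class-1 sample class 2. With equal sigmas the closed form is
#' `z_o = (mu1 + mu2)/2 + sigma^2 log(lambda12/lambda21) / (mu2 - mu1)`; with
#' unequal sigmas the quadratic in `z` is solved and the root inside
#' `(mu1 - sigma1, mu2 + sigma2)` nearest the midpoint is returned. If no
#' real root lies there the midpoint `(mu1 + mu2)/2` is returned with a
#' warning.
#'
#' @param mu1,sigma1,mu2,sigma2 class means and standard deviations.
#' @param lambda12,lambda21 off-diagonal losses (defaults
#'   `lambda12 = 2 * lambda21`, the conservative choice).
#' @return threshold `z_o`.
#' @export
solve_threshold <- function(mu1, sigma1, mu2, sigma2,
                            lambda12 = 1.0, lambda21 = 0.5) {
  stopifnot(sigma1 > 0, sigma2 > 0, lambda12 > 0, lambda21 > 0)
  if (!(mu1 < mu2))
    stop("expected mu1 < mu2 (class 1 is the low-mean class)", call. = FALSE)
  mid <- (mu1 + mu2) / 2
  if (abs(sigma1 - sigma2) < 1e-12) {
    return(mid + sigma1^2 * log(lambda12 / lambda21) / (mu2 - mu1))
  }
  # log lambda12 - log sigma1 - (z-mu1)^2/(2 s1^2) =
  #   log lambda21 - log sigma2 - (z-mu2)^2/(2 s2^2)
  a <- 1 / (2 * sigma2^2) - 1 / (2 * sigma1^2)
  b <- mu1 / sigma1^2 - mu2 / sigma2^2
  cc <- mu2^2 / (2 * sigma2^2) - mu1^2 / (2 * sigma1^2) +
    log(lambda12 * sigma2 / (lambda21 * sigma1))
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    warning("no real threshold root; falling back to class-mean midpoint",
            call. = FALSE)
    return(mid)
  }
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > mu1 - sigma1 & roots < mu2 + sigma2]
  if (!length(inside)) {
    warning("no threshold root between the class means; ",
            "falling back to class-mean midpoint", call. = FALSE)
    return(mid)
  }
  inside[which.min(abs(inside - mid))]
}

#' Binarize filtered outputs against per-element thresholds
#'
#' Element `k` maps to 1 when `y_bar[k] >= z_o[k]` (ties to 1) and 0
#' otherwise.
#'
#' @param y_bar filtered output 3-vector or `n x 3` matrix.
#' @param thresholds numeric vector of per-element thresholds.
#' @return binary vector/matrix of 0/1, same shape as `y_bar`.
#' @export
binarize <- function(y_bar, thresholds) {
  vec <- is.null(dim(y_bar))
  if (vec) y_bar <- matrix(y_bar, nrow = 1L)
  stopifnot(ncol(y_bar) == length(thresholds))
  out <- (y_bar >= matrix(thresholds, nrow(y_bar), ncol(y_bar),
                          byrow = TRUE)) + 0
  if (vec) drop(out) else out
}

#' Decision model container
#'
#' @param epsilon filter time constant, seconds.
#' @param class_stats `3 x 4` matrix (rows = output elements, columns
#'   `mu1, sigma1, mu2, sigma2`).
#' @param thresholds per-element thresholds `z_o` (length 3).
#' @param loss 2x2 loss matrix; the diagonal must be zero and the default
#'   off-diagonal losses are `lambda12 = 1.0`, `lambda21 = 0.5` (misclassifying
#'   the "should be 0" class costs twice as much — conservative detection).
#' @return object of class `decision_model`.
#' @export
decision_model <- function(epsilon = 0.02, class_stats, thresholds,
                           loss = matrix(c(0, 0.5, 1.0, 0), 2, 2)) {
  stopifnot(epsilon > 0, all(diag(loss) == 0),
            loss[1, 2] > 0, loss[2, 1] > 0,
            nrow(class_stats) == length(thresholds),
            all(is.finite(thresholds)))
  structure(list(epsilon = epsilon, class_stats = class_stats,
                 thresholds = as.numeric(thresholds), loss = loss),
            class = "decision_model")
}

#' @export
print.decision_model <- function(x, ...) {
  cat(sprintf("<decision_model> epsilon=%g s, lambda12=%g lambda21=%g\n",
              x$epsilon, x$loss[1, 2], x$loss[2, 1]))
  cat("thresholds:", paste(signif(x$thresholds, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fit the decision model on labelled training output
#'
#' Runs the network causally over the training signals, filters the outputs,
#' and for each of the three output elements fits the two class Gaussians
#' (class 2 where the element's target value is 1) and solves the
#' minimum-risk threshold with the configured loss matrix.
#'
#' @param model a [network_model()].
#' @param signals `processed_signals` of the training trial(s); a list is
#'   accepted and concatenated.
#' @param labels per-sample true mode labels (list matching `signals` when a
#'   list is given).
#' @param fs sampling rate, Hz.
#' @param epsilon filter time constant, seconds.
#' @param loss 2x2 loss matrix (see [decision_model()]).
#' @param naive_half if `TRUE`, skip the risk solution and place every
#'   threshold at 0.5 (simple step-function cut, kept for comparison).
#' @return a [decision_model()].
#' @export
fit_decision_model <- function(model, signals, labels, fs, epsilon = 0.02,
                               loss = matrix(c(0, 0.5, 1.0, 0), 2, 2),
                               naive_half = FALSE) {
  if (inherits(signals, "processed_signals")) {
    signals <- list(signals); labels <- list(labels)
  }
  ybar <- list(); targ <- list()
  for (i in seq_along(signals)) {
    y <- predict_stream(model, signals[[i]])
    ybar[[i]] <- filter_stream(y, epsilon, fs)
    targ[[i]] <- mode_to_target(labels[[i]])
  }
  ybar <- do.call(rbind, ybar)
  targ <- do.call(rbind, targ)
  modes_present <- unique(map_mode(targ))
  if (!all(c("Ascent", "Level", "Descent") %in% modes_present))
    stop("invalid training data: all three gait modes must be present",
         call. = FALSE)
  stats <- matrix(NA_real_, 3L, 4L,
                  dimnames = list(paste0("el", 1:3),
                                  c("mu1", "sigma1", "mu2", "sigma2")))
  z_o <- numeric(3L)
  for (k in 1:3) {
    st <- fit_class_gaussians(ybar[, k], targ[, k] == 1)
    stats[k, ] <- st
    z_o[k] <- if (naive_half) 0.5 else
      solve_threshold(st["mu1"], st["sigma1"], st["mu2"], st["sigma2"],
                      lambda12 = loss[1, 2], lambda21 = loss[2, 1])
  }
  decision_model(epsilon = epsilon, class_stats = stats, thresholds = z_o,
                 loss = loss)
}

#' Classify every sample of a trial
#'
#' Causal composition of the full pipeline: tapped-delay network outputs,
#' first-order filtering, per-element thresholding, and mode mapping — one
#' label per sample.
#'
#' @param model a [network_model()].
#' @param decision a [decision_model()].
#' @param signals `processed_signals` from [process_signals()].
#' @param fs sampling rate, Hz.
#' @return character vector of per-sample mode labels.
#' @export
classify_stream <- function(model, decision, signals, fs) {
  y <- predict_stream(model, signals)
  ybar <- filter_stream(y, decision$epsilon, fs)
  map_mode(binarize(ybar, decision$thresholds))
}
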