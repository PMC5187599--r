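# JSON serialization of a trained classifier (network + decision + ZUPT
# settings), version-tagged, weight matrices stored row-major.

.GAITMODE_MODEL_VERSION <- "1.0"

#' Write / read a trained classifier as JSON
#'
#' The document stores every [network_model()] field (weights row-major),
#' the input-standardization constants, the fitted [decision_model()] and the
#' [zupt_config()], under a `version` tag. Numbers are written at full
#' precision so a round trip reproduces the model bit for bit.
#'
#' @param classifier a [train_gait_classifier()] result.
#' @param path JSON file path.
#' @return `write_model_json`: `path`, invisibly. `read_model_json`: a
#'   `gait_classifier`.
#' @export
write_model_json <- function(classifier, path) {
  stopifnot(inherits(classifier, "gait_classifier"))
  m <- classifier$model; d <- classifier$decision; z <- classifier$zupt
  doc <- list(
    version = .GAITMODE_MODEL_VERSION,
    fs = classifier$fs,
    network = list(
      n_delays = m$n_delays, n_hidden = m$n_hidden, n_out = m$n_out,
      w_h = apply(m$w_h, 1L, identity, simplify = FALSE),
      b_h = m$b_h,
      w_o = apply(m$w_o, 1L, identity, simplify = FALSE),
      b_o = m$b_o,
      input_mean = m$input_mean, input_scale = m$input_scale,
      alpha = m$alpha, beta = m$beta),
    decision = list(
      epsilon = d$epsilon,
      loss = apply(d$loss, 1L, identity, simplify = FALSE),
      class_stats = apply(d$class_stats, 1L, identity, simplify = FALSE),
      thresholds = d$thresholds),
    zupt = list(eps_g = z$eps_g, g = z$g, min_dwell = z$min_dwell,
                drift_mode = z$drift_mode))
  # I(17) = 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$version))
    stop("not a gaitmode model file (missing version tag): ", path,
         call. = FALSE)
  nw <- doc$network
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  model <- network_model(as_mat(nw$w_h), nw$b_h, as_mat(nw$w_o), nw$b_o,
                         input_mean = nw$input_mean,
                         input_scale = nw$input_scale,
                         alpha = nw$alpha, beta = nw$beta,
                         n_delays = nw$n_delays)
  cs <- as_mat(doc$decision$class_stats)
  colnames(cs) <- c("mu1", "sigma1", "mu2", "sigma2")
  rownames(cs) <- paste0("el", seq_len(nrow(cs)))
  decision <- decision_model(epsilon = doc$decision$epsilon,
                             class_stats = cs,
                             thresholds = doc$decision$thresholds,
                             loss = as_mat(doc$decision$loss))
  zupt <- zupt_config(eps_g = doc$zupt$eps_g, g = doc$zupt$g,
                      min_dwell = doc$zupt$min_dwell,
                      drift_mode = doc$zupt$drift_mode)
  structure(list(model = model, decision = decision, zupt = zupt,
                 fs = doc$fs),
            class = "gait_classifier")
}
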