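# Compiled-path wrapper around the state-update loop. Accumulates X X' and
# the running state sum so the full state matrix is only materialized when
# asked for. Activation must be a name here (the C++ kernel inlines it).
harvest_fast <- function(signal, weights, alpha = 0.5, activation = "tanh",
                         washout = 0L, return_states = FALSE) {
  s <- weights$spec
  kind_code <- match(s$kind, c("one_way_ring", "two_way_ring", "center",
                               "hybrid", "random")) - 1L
  act_code <- match(activation, c("tanh", "identity", "pwl_tanh")) - 1L
  if (is.na(act_code))
    stop("harvest_fast: activation must be one of tanh/identity/pwl_tanh")
  if (!is.matrix(signal) || ncol(signal) < 1L)
    stop("harvest_fast: 'signal' must be a K x T matrix with T >= 1")
  if (washout < 0 || washout >= ncol(signal))
    stop("harvest_fast: need T > washout >= 0")
  e <- numeric(0)
  em <- matrix(0, 0, 0)
  h <- harvest_accumulate(signal, weights$W_in,
                          weights$W_ring %||% e, weights$W_ring_rev %||% e,
                          weights$W_up %||% e, weights$W_down %||% e,
                          weights$W_x %||% em,
                          kind_code, alpha, act_code, as.integer(washout),
                          return_states)
  h$state_sum <- as.numeric(h$state_sum)
  h$X_last <- as.numeric(h$X_last)
  h
}

# Per-channel |x| scaling factors learned on the training split.
absmax_scale <- function(segments) {
  K <- nrow(segments[[1L]])
  mx <- rep(0, K)
  for (seg in segments) mx <- pmax(mx, apply(abs(seg), 1L, max))
  mx[mx == 0] <- 1
  mx
}

apply_preprocess <- function(seg, preprocess, scale) {
  if (preprocess == "none") return(seg)
  abs(seg) / scale
}

#' Fit an echo state network classifier
#'
#' Builds a fixed random reservoir of the requested topology, drives it with
#' every training segment, and trains the linear readout in closed form by
#' the normal equations `W_out = (Y X')(X X' + ridge I)^-1`. Only the readout
#' is trained; input and reservoir weights stay frozen. Two classification
#' protocols are supported: a per-time-step `"threshold"` protocol for
#' binary tasks (accuracy is the fraction of time the thresholded output is
#' correct) and a per-segment `"wta"` (winner-take-all) protocol for
#' multi-class tasks (each segment gets the class whose output row has the
#' largest time-averaged response).
#'
#' @param data A `"signal_dataset"` (see [gen_eeg_like()], [gen_emg_like()],
#'   [signal_dataset()]) or a list of K x T segment matrices.
#' @param labels Per-segment class labels; taken from `data` when omitted.
#' @param topology Reservoir topology kind (see [topology_spec()]).
#' @param N Reservoir size (number of neurons).
#' @param alpha Leak rate in (0, 1]; the state update blends
#'   `alpha * f(pre) + (1 - alpha) * X_prev`.
#' @param washout Leading time steps of each segment excluded from training.
#' @param ridge Ridge added to `X X'` for conditioning (default 1e-8;
#'   `ridge = 0` gives the plain normal equations).
#' @param protocol `"auto"` (threshold when binary, else wta), `"threshold"`,
#'   or `"wta"`.
#' @param threshold Decision threshold for the threshold protocol.
#' @param preprocess `"absmax"` rescales `|x|` per channel by the
#'   training-split maximum (the normalized-absolute-value front end used for
#'   biosignal amplitudes); `"none"` feeds raw signals.
#' @param mode `"ideal"` (floating point, tanh) or `"digital"` (bit-faithful
#'   fixed-point datapath with piecewise-linear tanh and alpha fixed at 0.5;
#'   see [digital_step()]).
#' @param fmt [fixed_point_format()] for `mode = "digital"`.
#' @param weight_law Weight distribution for the reservoir
#'   (see [topology_spec()]).
#' @param seed Integer seed fixing the reservoir draw.
#' @param ... Passed on to [topology_spec()] (e.g. `connectivity`,
#'   `weight_sd`, `process`).
#' @return An object of class `"esn"`: the reservoir weights, the trained
#'   readout, protocol bookkeeping, and per-segment fitted scores.
#' @examples
#' ds <- gen_eeg_like(n_per_class = 6, duration_s = 2, fs = 173.61, seed = 1)
#' fit <- esn(ds, N = 30, seed = 2)
#' fit
#' predict(fit, ds)$accuracy
#' @export
esn <- function(data, labels = NULL,
                topology = "hybrid", N = 100L, alpha = 0.5, washout = 0L,
                ridge = 1e-8, protocol = c("auto", "threshold", "wta"),
                threshold = 0.5, preprocess = c("absmax", "none"),
                mode = c("ideal", "digital"), fmt = fixed_point_format(),
                weight_law = "uniform_pm1", seed = 1L, ...) {
  protocol <- match.arg(protocol)
  preprocess <- match.arg(preprocess)
  mode <- match.arg(mode)
  ds <- as_signal_dataset(data, labels)
  segments <- ds$segments
  labels <- ds$labels
  if (length(segments) == 0L) stop("esn: no training segments")
  if (is.null(labels) || length(labels) != length(segments))
    stop("esn: need one label per training segment")
  levels <- sort(unique(as.character(labels)))
  n_classes <- length(levels)
  if (n_classes < 2L) stop("esn: need at least two classes, got ", n_classes)
  if (protocol == "auto")
    protocol <- if (n_classes == 2L) "threshold" else "wta"
  if (protocol == "threshold" && n_classes != 2L)
    stop("esn: threshold protocol requires exactly 2 classes")
  M <- if (protocol == "threshold") 1L else n_classes
  K <- nrow(segments[[1L]])

  spec <- topology_spec(kind = topology, N = N, K = K, M = M,
                        weight_law = weight_law, seed = seed, ...)
  weights <- build_topology(spec)
  scale <- if (preprocess == "absmax") absmax_scale(segments) else NULL
  if (mode == "digital") {
    alpha <- 0.5
    weights <- quantize_weights(weights, fmt)
  }

  cls <- match(as.character(labels), levels)
  target_vec <- function(ci) {
    if (protocol == "threshold") ci - 1 else as.numeric(seq_len(M) == ci)
  }
  XXt <- matrix(0, spec$N, spec$N)
  YXt <- matrix(0, M, spec$N)
  seg_means <- matrix(0, spec$N, length(segments))
  for (i in seq_along(segments)) {
    seg <- apply_preprocess(segments[[i]], preprocess, scale)
    h <- if (mode == "digital")
      digital_harvest_moments(seg, weights, fmt, washout)
    else harvest_fast(seg, weights, alpha, "tanh", washout)
    XXt <- XXt + h$XXt
    YXt <- YXt + target_vec(cls[i]) %o% h$state_sum
    seg_means[, i] <- h$state_sum / h$T_kept
  }
  A <- XXt + diag(ridge, spec$N)
  W_out <- tryCatch(t(solve(A, t(YXt))), error = function(e)
    stop("esn: normal-equation system is singular at ridge = ", ridge,
         "; increase 'ridge' (", conditionMessage(e), ")", call. = FALSE))
  fitted_scores <- W_out %*% seg_means

  structure(list(
    weights = weights, W_out = W_out, protocol = protocol, levels = levels,
    alpha = alpha, washout = as.integer(washout), ridge = ridge,
    threshold = threshold, preprocess = preprocess, scale = scale,
    mode = mode, fmt = if (mode == "digital") fmt else NULL,
    fitted_scores = fitted_scores, train_classes = cls,
    n_train = length(segments), seed = as.integer(seed),
    call = match.call()), class = "esn")
}

# Coerce matrices/lists/datasets to a common dataset shape.
as_signal_dataset <- function(x, labels = NULL) {
  if (inherits(x, "signal_dataset")) {
    if (!is.null(labels)) x$labels <- labels
    return(x)
  }
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || !all(vapply(x, is.matrix, logical(1))))
    stop("expected a signal_dataset or a list of K x T segment matrices")
  signal_dataset(x, labels = labels, fs = NA_real_)
}

#' @export
print.esn <- function(x, ...) {
  cat("Echo state network (", x$weights$spec$kind, " topology)\n", sep = "")
  cat("  reservoir size N =", x$weights$spec$N,
      " inputs K =", x$weights$spec$K,
      " outputs M =", nrow(x$W_out), "\n")
  cat("  mode =", x$mode, " protocol =", x$protocol,
      " alpha =", x$alpha, " ridge =", format(x$ridge), "\n")
  cat("  classes:", paste(x$levels, collapse = ", "),
      " (", x$n_train, "training segments )\n")
  invisible(x)
}

#' @export
coef.esn <- function(object, ...) object$W_out

#' Per-segment training residuals
#'
#' Residuals of the time-averaged readout response per training segment
#' against the segment's target (0/1 for the threshold protocol, one-hot for
#' winner-take-all). Because the readout is linear, the time-averaged output
#' equals the output of the time-averaged state.
#'
#' @param object A fitted `"esn"`.
#' @param ... Unused.
#' @return M x n_segments matrix of `target - fitted` values.
#' @export
residuals.esn <- function(object, ...) {
  M <- nrow(object$W_out)
  tgt <- vapply(object$train_classes, function(ci) {
    if (object$protocol == "threshold") ci - 1
    else as.numeric(seq_len(M) == ci)
  }, numeric(M))
  tgt <- matrix(tgt, nrow = M)
  tgt - object$fitted_scores
}

#' Predict classes for new segments
#'
#' Runs each new segment through the frozen reservoir (applying the training
#' preprocessing) and the trained readout. Under the threshold protocol the
#' output is thresholded per time step and accuracy is the fraction of time
#' steps correct; under winner-take-all each segment is assigned the class
#' with the largest time-averaged output and accuracy is the fraction of
#' segments correct.
#'
#' @param object A fitted `"esn"`.
#' @param newdata A `"signal_dataset"` or list of K x T segment matrices.
#' @param labels Optional reference labels (taken from `newdata` if present).
#' @param ... Unused.
#' @return An `"esn_prediction"`: list with per-segment `labels` (class
#'   values on the training label scale), `scores` (M x n_segments mean
#'   outputs), and `accuracy` when reference labels are available (step-level
#'   for threshold, segment-level for wta).
#' @export
predict.esn <- function(object, newdata, labels = NULL, ...) {
  ds <- as_signal_dataset(newdata, labels)
  segments <- ds$segments
  ref <- ds$labels
  if (length(segments) == 0L) stop("predict.esn: no segments")
  M <- nrow(object$W_out)
  scores <- matrix(0, M, length(segments))
  seg_labels <- integer(length(segments))
  correct <- 0; total <- 0
  for (i in seq_along(segments)) {
    seg <- apply_preprocess(segments[[i]], object$preprocess, object$scale)
    h <- if (object$mode == "digital")
      digital_harvest_moments(seg, object$weights, object$fmt,
                              object$washout, return_states = TRUE)
    else harvest_fast(seg, object$weights, object$alpha, "tanh",
                      object$washout, return_states = TRUE)
    y <- object$W_out %*% h$X_all
    scores[, i] <- rowMeans(y)
    if (object$protocol == "threshold") {
      lab_t <- as.integer(y[1L, ] >= object$threshold)
      seg_labels[i] <- as.integer(mean(lab_t) >= 0.5) + 1L
      if (!is.null(ref)) {
        tgt <- match(as.character(ref[i]), object$levels) - 1L
        correct <- correct + sum(lab_t == tgt)
        total <- total + length(lab_t)
      }
    } else {
      seg_labels[i] <- which.max(scores[, i])
    }
  }
  out <- list(labels = object$levels[seg_labels], scores = scores,
              protocol = object$protocol)
  if (!is.null(ref)) {
    out$accuracy <- if (object$protocol == "threshold") correct / total
      else mean(object$levels[seg_labels] == as.character(ref))
    out$reference <- ref
    out$confusion <- table(predicted = object$levels[seg_labels],
                           reference = as.character(ref))
  }
  structure(out, class = "esn_prediction")
}

#' @export
print.esn_prediction <- function(x, ...) {
  cat("ESN prediction (", x$protocol, " protocol, ",
      length(x$labels), " segments)\n", sep = "")
  if (!is.null(x$accuracy))
    cat("  accuracy:", sprintf("%.4f", x$accuracy),
        if (x$protocol == "threshold") "(fraction of time steps correct)"
        else "(fraction of segments correct)", "\n")
  invisible(x)
}

#' @export
summary.esn <- function(object, ...) {
  M <- nrow(object$W_out)
  seg_pred <- if (object$protocol == "threshold")
    as.integer(object$fitted_scores[1L, ] >= object$threshold) + 1L
  else apply(object$fitted_scores, 2L, which.max)
  structure(list(
    spec = object$weights$spec, mode = object$mode,
    protocol = object$protocol, levels = object$levels,
    alpha = object$alpha, ridge = object$ridge,
    n_train = object$n_train,
    train_segment_accuracy = mean(seg_pred == object$train_classes),
    readout_norm = sqrt(sum(object$W_out^2)),
    residual_rms = sqrt(mean(residuals(object)^2))),
    class = "summary.esn")
}

#' @export
print.summary.esn <- function(x, ...) {
  cat("Echo state network fit\n")
  cat("  topology:", x$spec$kind, " N =", x$spec$N, " mode =", x$mode, "\n")
  cat("  protocol:", x$protocol, " classes:",
      paste(x$levels, collapse = ", "), "\n")
  cat("  alpha =", x$alpha, " ridge =", format(x$ridge), "\n")
  cat("  training segments:", x$n_train, "\n")
  cat("  segment-level training accuracy:",
      sprintf("%.4f", x$train_segment_accuracy), "\n")
  cat("  readout |W_out|_F:", sprintf("%.4g", x$readout_norm),
      "  residual RMS:", sprintf("%.4g", x$residual_rms), "\n")
  invisible(x)
}

#' Plot fitted per-segment scores by class
#'
#' Shows the distribution of time-averaged readout responses of the training
#' segments, grouped by their true class: one box per class for the
#' threshold protocol, one box per (output row, class) pair for
#' winner-take-all.
#'
#' @param x A fitted `"esn"`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.esn <- function(x, ...) {
  cls <- factor(x$levels[x$train_classes], levels = x$levels)
  if (x$protocol == "threshold") {
    graphics::boxplot(x$fitted_scores[1L, ] ~ cls,
                      xlab = "class", ylab = "mean readout output", ...)
    graphics::abline(h = x$threshold, lty = 2)
  } else {
    sc <- x$fitted_scores
    df <- data.frame(score = as.vector(sc),
                     output = factor(rep(x$levels, ncol(sc)),
                                     levels = x$levels),
                     class = rep(cls, each = nrow(sc)))
    graphics::boxplot(score ~ output + class, data = df,
                      xlab = "output row . true class",
                      ylab = "mean readout output", las = 2, ...)
  }
  invisible(x)
}
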