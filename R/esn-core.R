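#' Create an empty reservoir state
#'
#' @param N Number of reservoir neurons.
#' @return An object of class `"esn_state"` with the zero activation vector
#'   `X`, zero center-neuron state `Xc`, and time index `t = 0`.
#' @export
esn_state <- function(N) {
  structure(list(X = numeric(N), Xc = 0, t = 0L), class = "esn_state")
}

activation_fun <- function(activation) {
  if (is.function(activation)) return(activation)
  switch(activation,
         tanh = tanh,
         identity = identity,
         pwl_tanh = pwl_tanh,
         stop("unknown activation '", activation, "'"))
}

# Pre-activation for one time step given the previous state. `rot(x)` is the
# left rotation: neuron s sees neuron s-1's previous state (neuron 1 sees N).
esn_preactivation <- function(x_prev, Xc, u, weights) {
  s <- weights$spec
  N <- s$N
  pre <- drop(weights$W_in %*% u)
  if (length(pre) != N)
    stop("step: W_in %*% u has length ", length(pre), ", expected N = ", N)
  rot <- function(x) x[c(N, seq_len(N - 1L))]
  rot_rev <- function(x) x[c(seq_len(N - 1L) + 1L, 1L)]
  switch(s$kind,
    one_way_ring = pre + weights$W_ring * rot(x_prev),
    two_way_ring = pre + weights$W_ring * rot(x_prev) +
                   weights$W_ring_rev * rot_rev(x_prev),
    center = pre + weights$W_down * Xc,
    hybrid = pre + weights$W_down * Xc + weights$W_ring * rot(x_prev),
    random = pre + drop(weights$W_x %*% x_prev))
}

#' Advance the reservoir one time step
#'
#' Applies the topology-specific state update: the linear center-neuron state
#' `Xc = W_up . X[n-1]` is computed first (no activation, and it is excluded
#' from the readout), then the per-neuron pre-activation (input drive, ring
#' neighbour, center broadcast, or dense recurrence depending on topology),
#' the activation function, and finally the leaky blend
#' `X <- alpha * X_new + (1 - alpha) * X_prev`.
#'
#' @param state An `"esn_state"` (see [esn_state()]).
#' @param u Input vector of length K.
#' @param weights A `"reservoir_weights"` object.
#' @param alpha Leak rate in (0, 1]; `alpha = 1` is the memoryless update.
#' @param activation `"tanh"`, `"identity"`, `"pwl_tanh"`, or a function.
#' @return The updated `"esn_state"`.
#' @export
esn_step <- function(state, u, weights, alpha = 0.5, activation = "tanh") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("esn_step: 'alpha' must lie in (0, 1]")
  f <- activation_fun(activation)
  s <- weights$spec
  if (length(u) != s$K)
    stop("esn_step: input u has length ", length(u), ", expected K = ", s$K)
  Xc <- if (s$kind %in% c("center", "hybrid"))
    sum(weights$W_up * state$X) else 0
  pre <- esn_preactivation(state$X, Xc, u, weights)
  x_new <- alpha * f(pre) + (1 - alpha) * state$X
  structure(list(X = x_new, Xc = Xc, t = state$t + 1L), class = "esn_state")
}

#' Harvest reservoir states over a signal
#'
#' Runs the reservoir from the zero state over every column of `signal` and
#' collects the activation vectors into a state matrix, discarding the first
#' `washout` columns. This is the pure-R reference implementation; [esn()]
#' uses an equivalent compiled path for long signals (the two are
#' cross-checked in the test suite).
#'
#' @param signal K x T numeric matrix (one column per time step).
#' @param weights A `"reservoir_weights"` object.
#' @param alpha Leak rate in (0, 1].
#' @param activation Activation function or name.
#' @param washout Number of leading columns to discard (default 0).
#' @return A `"state_matrix"` object: list with `X_all` (N x (T - washout))
#'   and `T_kept`.
#' @export
esn_harvest <- function(signal, weights, alpha = 0.5, activation = "tanh",
                        washout = 0L) {
  if (!is.matrix(signal) || ncol(signal) < 1L)
    stop("esn_harvest: 'signal' must be a K x T matrix with T >= 1")
  T_ <- ncol(signal)
  if (washout < 0 || washout >= T_)
    stop("esn_harvest: need T > washout >= 0 (T = ", T_,
         ", washout = ", washout, ")")
  st <- esn_state(weights$spec$N)
  X_all <- matrix(0, weights$spec$N, T_)
  for (t in seq_len(T_)) {
    st <- esn_step(st, signal[, t], weights, alpha, activation)
    X_all[, t] <- st$X
  }
  if (washout > 0L) X_all <- X_all[, -seq_len(washout), drop = FALSE]
  structure(list(X_all = X_all, T_kept = ncol(X_all)),
            class = "state_matrix")
}

#' Train the linear readout by normal equations
#'
#' Solves `W_out = (Y X')(X X' + ridge I)^-1`. With `ridge = 0` this is the
#' plain normal-equation solution; the small default ridge guards
#' conditioning without visibly perturbing well-posed problems. A singular
#' system at `ridge = 0` raises an error advising a positive ridge.
#'
#' @param sm A `"state_matrix"`, or an N x T numeric matrix of states.
#' @param Y M x T target matrix (a vector is treated as one row).
#' @param ridge Nonnegative ridge parameter (default 0).
#' @return A `"readout_weights"` object wrapping the M x N matrix `W_out`.
#' @export
train_readout <- function(sm, Y, ridge = 0) {
  X <- if (inherits(sm, "state_matrix")) sm$X_all else sm
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  if (ncol(X) != ncol(Y))
    stop("train_readout: X has ", ncol(X), " columns but Y has ", ncol(Y))
  if (ridge < 0) stop("train_readout: 'ridge' must be nonnegative")
  A <- tcrossprod(X) + diag(ridge, nrow(X))
  B <- tcrossprod(X, Y)         # X Y' = (Y X')'
  W_out <- tryCatch(t(solve(A, B)), error = function(e)
    stop("train_readout: X X' is numerically singular at ridge = ", ridge,
         "; retry with ridge > 0 (", conditionMessage(e), ")",
         call. = FALSE))
  structure(list(W_out = W_out), class = "readout_weights")
}

#' Readout layer output
#'
#' Applies the trained linear readout to harvested states:
#' `y = W_out %*% X_all` (the output activation is the identity).
#'
#' @param w A `"readout_weights"` object (or an M x N matrix).
#' @param sm A `"state_matrix"` or N x T state matrix.
#' @return M x T output matrix.
#' @export
readout_output <- function(w, sm) {
  W <- if (inherits(w, "readout_weights")) w$W_out else w
  X <- if (inherits(sm, "state_matrix")) sm$X_all else sm
  if (ncol(W) != nrow(X))
    stop("readout_output: W_out has ", ncol(W), " columns but states have ",
         nrow(X), " rows")
  W %*% X
}

#' Threshold classification of a one-dimensional output track
#'
#' Labels each time step 1 when the output is at or above the threshold,
#' else 0. When a reference track is supplied the accuracy is the fraction
#' of time steps labelled correctly.
#'
#' @param y Numeric output track (single row or vector).
#' @param thr Decision threshold (default 0.5, for targets in \{0, 1\}).
#' @param reference Optional reference \{0, 1\} track of the same length.
#' @return A list with `labels` (integer 0/1 vector) and, when `reference`
#'   is given, `accuracy`.
#' @export
classify_threshold <- function(y, thr = 0.5, reference = NULL) {
  y <- drop(y)
  labels <- as.integer(y >= thr)
  out <- list(labels = labels)
  if (!is.null(reference)) {
    reference <- drop(reference)
    if (length(reference) != length(labels))
      stop("classify_threshold: reference length ", length(reference),
           " does not match output length ", length(labels))
    out$accuracy <- mean(labels == as.integer(reference))
  }
  out
}

#' Winner-take-all classification of multi-output segments
#'
#' For each segment, averages every output row over the segment's time steps
#' and assigns the class whose row attains the largest mean response; ties
#' break toward the lowest row index. With reference labels the accuracy is
#' the fraction of segments classified correctly.
#'
#' @param y M x T output matrix, M >= 2.
#' @param segment_bounds Either an integer vector of segment lengths summing
#'   to T, or a list of column-index vectors.
#' @param reference Optional integer reference classes (1-based rows).
#' @return List with `labels` (class index per segment), `scores` (M x
#'   n_segments matrix of mean responses), and `accuracy` if `reference`
#'   is given.
#' @export
classify_wta <- function(y, segment_bounds, reference = NULL) {
  if (!is.matrix(y) || nrow(y) < 2L)
    stop("classify_wta: 'y' must be an M x T matrix with M >= 2")
  idx <- if (is.list(segment_bounds)) segment_bounds else {
    if (sum(segment_bounds) != ncol(y))
      stop("classify_wta: segment lengths sum to ", sum(segment_bounds),
           " but y has ", ncol(y), " columns")
    split(seq_len(ncol(y)),
          factor(rep(seq_along(segment_bounds), segment_bounds),
                 levels = seq_along(segment_bounds)))
  }
  if (any(lengths(idx) == 0L))
    stop("classify_wta: empty segment")
  scores <- vapply(idx, function(j) rowMeans(y[, j, drop = FALSE]),
                   numeric(nrow(y)))
  labels <- apply(scores, 2L, which.max)  # which.max: lowest index on ties
  out <- list(labels = as.integer(labels), scores = scores)
  if (!is.null(reference)) {
    if (length(reference) != length(labels))
      stop("classify_wta: reference length mismatch")
    out$accuracy <- mean(labels == reference)
  }
  out
}
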