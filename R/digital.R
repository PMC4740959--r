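#' Fixed-point number format
#'
#' Describes the Q(int_bits.frac_bits) two's-complement fixed-point format of
#' the digital datapath: values are integer multiples of `2^-frac_bits` in
#' the range `[-2^(int_bits-1), 2^(int_bits-1) - 2^-frac_bits]`. Rounding is
#' truncation toward negative infinity (floor at the LSB), overflow
#' saturates — the usual RTL behaviour.
#'
#' @param int_bits Integer bits including sign (default 10).
#' @param frac_bits Fractional bits (default 20, i.e. Q(10.20)).
#' @return An object of class `"fixed_point_format"`.
#' @export
fixed_point_format <- function(int_bits = 10L, frac_bits = 20L) {
  if (int_bits < 1 || frac_bits < 0)
    stop("fixed_point_format: need int_bits >= 1 and frac_bits >= 0")
  structure(list(int_bits = as.integer(int_bits),
                 frac_bits = as.integer(frac_bits)),
            class = "fixed_point_format")
}

#' @export
print.fixed_point_format <- function(x, ...) {
  cat(sprintf("Q(%d.%d) fixed point, range [%g, %g], lsb 2^-%d\n",
              x$int_bits, x$frac_bits, -2^(x$int_bits - 1),
              2^(x$int_bits - 1) - 2^(-x$frac_bits), x$frac_bits))
  invisible(x)
}

#' Quantize to a fixed-point format
#'
#' Truncates toward negative infinity at the format's LSB and saturates
#' out-of-range values to the representable bounds. Idempotent: quantizing a
#' quantized value is a no-op.
#'
#' @param x Numeric vector.
#' @param fmt A [fixed_point_format()].
#' @return Quantized values as doubles (all exactly representable).
#' @export
quantize <- function(x, fmt = fixed_point_format()) {
  s <- 2^fmt$frac_bits
  lo <- -2^(fmt$int_bits - 1)
  hi <- 2^(fmt$int_bits - 1) - 1 / s
  pmin(pmax(floor(x * s) / s, lo), hi)
}

#' Piecewise-linear tanh approximation
#'
#' Five-band odd approximation of `tanh` with power-of-two slopes so the
#' hardware needs only shifts: identity on `[-0.5, 0.5]`, slope-1/2 segments
#' `x/2 +/- 0.25` on `0.5 < |x| < 1.5`, and saturation at `+/-1` beyond
#' `|x| >= 1.5`. Continuous at every breakpoint; the worst-case deviation
#' from the true tanh is `1 - tanh(1.5)` (about 0.0949), attained at
#' `x = +/-1.5`.
#'
#' @param x Numeric vector.
#' @return Approximated tanh values in `[-1, 1]`.
#' @export
pwl_tanh <- function(x) {
  ax <- abs(x)
  y <- ifelse(ax >= 1.5, 1, ifelse(ax > 0.5, ax / 2 + 0.25, ax))
  sign(x) * y
}

#' Quantize reservoir weights at load
#'
#' @param weights A `"reservoir_weights"` object.
#' @param fmt A [fixed_point_format()].
#' @return The weights object with every weight array quantized.
#' @export
quantize_weights <- function(weights, fmt = fixed_point_format()) {
  for (f in c("W_in", "W_ring", "W_ring_rev", "W_up", "W_down", "W_x"))
    if (!is.null(weights[[f]])) weights[[f]] <- quantize(weights[[f]], fmt)
  weights
}

# Quantized dot product: each multiply result and each running add is
# truncated to the format, mirroring a sequential MAC datapath.
quantized_dot <- function(a, b, fmt) {
  acc <- 0
  for (i in seq_along(a))
    acc <- quantize(acc + quantize(a[i] * b[i], fmt), fmt)
  acc
}

#' Advance the fixed-point digital reservoir one step
#'
#' Bit-faithful emulation of the RTL datapath: every multiplier and adder
#' output is truncated to the fixed-point format, the activation is the
#' piecewise-linear tanh, the leak is fixed at `alpha = 0.5` realized as an
#' add followed by a right shift, and all inter-neuron values are the
#' previous step's registered outputs.
#'
#' @param state An `"esn_state"` whose `X` is already quantized.
#' @param u Input vector (quantized at entry).
#' @param weights Reservoir weights, pre-quantized via [quantize_weights()].
#' @param fmt A [fixed_point_format()].
#' @return Updated `"esn_state"` with quantized `X` and `Xc`.
#' @export
digital_step <- function(state, u, weights, fmt = fixed_point_format()) {
  s <- weights$spec
  N <- s$N
  q <- function(v) quantize(v, fmt)
  u <- q(u)
  x_prev <- q(state$X)
  Xc <- if (s$kind %in% c("center", "hybrid"))
    quantized_dot(weights$W_up, x_prev, fmt) else 0
  rot <- function(x) x[c(N, seq_len(N - 1L))]
  # products, one per synapse, each truncated as a multiplier output
  p_in <- if (s$K == 1L) q(weights$W_in[, 1L] * u) else
    vapply(seq_len(N), function(i) quantized_dot(weights$W_in[i, ], u, fmt),
           numeric(1))
  acc <- p_in
  if (s$kind %in% c("one_way_ring", "two_way_ring", "hybrid"))
    acc <- q(acc + q(weights$W_ring * rot(x_prev)))
  if (s$kind == "two_way_ring")
    acc <- q(acc + q(weights$W_ring_rev *
                       x_prev[c(seq_len(N - 1L) + 1L, 1L)]))
  if (s$kind %in% c("center", "hybrid"))
    acc <- q(acc + q(weights$W_down * Xc))
  if (s$kind == "random")
    acc <- q(acc + vapply(seq_len(N), function(i)
      quantized_dot(weights$W_x[i, ], x_prev, fmt), numeric(1)))
  act <- q(pwl_tanh(acc))
  # alpha = 0.5 blend: adder output truncated, then arithmetic right shift
  x_new <- q(q(act + x_prev) / 2)
  structure(list(X = x_new, Xc = Xc, t = state$t + 1L), class = "esn_state")
}

# Harvest loop for the digital datapath (R loop; digital configurations are
# small by construction). Returns the same moment structure as
# harvest_fast().
digital_harvest_moments <- function(signal, weights, fmt, washout = 0L,
                                    return_states = FALSE) {
  N <- weights$spec$N
  T_ <- ncol(signal)
  if (washout < 0 || washout >= T_)
    stop("digital_harvest_moments: need T > washout >= 0")
  st <- esn_state(N)
  XXt <- matrix(0, N, N)
  xsum <- numeric(N)
  T_kept <- T_ - washout
  states <- if (return_states) matrix(0, N, T_kept) else NULL
  kept <- 0L
  for (t in seq_len(T_)) {
    st <- digital_step(st, signal[, t], weights, fmt)
    if (t > washout) {
      kept <- kept + 1L
      XXt <- XXt + tcrossprod(st$X)
      xsum <- xsum + st$X
      if (return_states) states[, kept] <- st$X
    }
  }
  out <- list(XXt = XXt, state_sum = xsum, T_kept = T_kept,
              X_last = st$X, Xc_last = st$Xc)
  if (return_states) out$X_all <- states
  out
}

#' Write a fixed-point state trace
#'
#' Runs the digital datapath over a signal and writes the per-step quantized
#' state vectors as delimited text (one row per time step), for cross-checks
#' against RTL simulation.
#'
#' @param signal K x T input matrix.
#' @param weights Pre-quantized reservoir weights.
#' @param fmt A [fixed_point_format()].
#' @param path Output file path (tab-separated, with header).
#' @return Invisibly, the T x N matrix of states.
#' @export
digital_trace <- function(signal, weights, fmt = fixed_point_format(),
                          path) {
  h <- digital_harvest_moments(signal, weights, fmt, washout = 0L,
                               return_states = TRUE)
  tr <- t(h$X_all)
  colnames(tr) <- paste0("x", seq_len(ncol(tr)))
  utils::write.table(tr, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(tr)
}
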