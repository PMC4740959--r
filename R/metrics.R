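#' Kernel quality of a reservoir
#'
#' Numerical rank of the matrix whose columns are the reservoir responses to
#' a set of input cases. A rank equal to the reservoir size means every
#' neuron contributes a response that is not a linear combination of the
#' others — the ideal, maximally separating reservoir.
#'
#' @param states N x m numeric matrix (one column per input case).
#' @param tol Relative singular-value tolerance; singular values above
#'   `tol * max(sv)` are counted. Default is the standard numerical-rank
#'   rule `max(dim) * .Machine$double.eps`.
#' @return Integer rank, between 0 and `min(N, m)`.
#' @export
kernel_quality <- function(states, tol = NULL) {
  if (!is.matrix(states) || length(states) == 0L)
    stop("kernel_quality: 'states' must be a nonempty matrix")
  sv <- svd(states, nu = 0, nv = 0)$d
  if (max(sv) == 0) return(0L)
  if (is.null(tol)) tol <- max(dim(states)) * .Machine$double.eps
  sum(sv > tol * max(sv))
}

#' Nearest-neighbour Lyapunov exponent of a reservoir
#'
#' Expansion measure over a set of test cases: for each input vector the
#' nearest distinct input (Euclidean distance, ties to the lowest index) is
#' found, and the metric is `k_scale` times the sum over cases of the log
#' ratio of the corresponding state distance to the input distance. Zero
#' marks the edge of chaos; negative values indicate contraction,
#' positive values chaotic expansion.
#'
#' @param inputs List of input vectors (or a matrix, one column per case).
#' @param states List of matching reservoir state vectors (or a matrix).
#' @param k_scale Scale factor `k` (default 1).
#' @return The exponent (a single scalar for the evaluation set).
#' @export
lyapunov_exponent <- function(inputs, states, k_scale = 1) {
  as_cols <- function(x) if (is.matrix(x)) x else
    do.call(cbind, lapply(x, as.numeric))
  U <- as_cols(inputs)
  X <- as_cols(states)
  n <- ncol(U)
  if (n < 2L) stop("lyapunov_exponent: need at least 2 cases")
  if (ncol(X) != n)
    stop("lyapunov_exponent: ", n, " inputs but ", ncol(X), " states")
  total <- 0
  for (j in seq_len(n)) {
    d_in <- sqrt(colSums((U - U[, j])^2))
    d_in[j] <- Inf
    nn <- which.min(d_in)   # lowest index on ties
    if (d_in[nn] == 0)
      stop("lyapunov_exponent: inputs ", j, " and ", nn,
           " are exact duplicates (zero nearest-neighbour distance)")
    d_st <- sqrt(sum((X[, j] - X[, nn])^2))
    total <- total + log(d_st / d_in[nn])
  }
  k_scale * total
}

#' Reservoir-quality report
#'
#' Convenience wrapper computing both reservoir metrics for one set of
#' input cases: drive the reservoir with each input case (a K x T segment),
#' take the final state as the case's response, then compute the kernel
#' rank of the response matrix and the nearest-neighbour Lyapunov exponent
#' of (flattened input, final state) pairs.
#'
#' @param weights A `"reservoir_weights"` object.
#' @param cases List of K x T input segments.
#' @param alpha Leak rate.
#' @param k_scale Lyapunov scale factor.
#' @return List with `kernel_quality`, `lyapunov`, and `n_cases`.
#' @export
reservoir_metrics <- function(weights, cases, alpha = 0.5, k_scale = 1) {
  finals <- vapply(cases, function(seg) {
    h <- harvest_fast(seg, weights, alpha, "tanh", 0L)
    h$X_last
  }, numeric(weights$spec$N))
  inputs <- lapply(cases, as.numeric)
  list(kernel_quality = kernel_quality(finals),
       lyapunov = lyapunov_exponent(inputs, finals, k_scale),
       n_cases = length(cases))
}
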