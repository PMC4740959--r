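# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (igraph distances, svd rank, solve-based
# readout) so that each check is a genuine dual route.

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix.
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Reservoir-endpoint diameter/average distance straight from the weights
# object's graph, via Floyd-Warshall over all nodes (center included as a
# possible intermediate hop only).
fw_reservoir_metrics <- function(weights) {
  g <- weights$graph
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- fw_distances(adj)
  N <- weights$spec$N
  keep <- match(as.character(seq_len(N)), rownames(adj))
  d <- d[keep, keep]
  off <- d[row(d) != col(d)]
  list(diameter = max(off), average = mean(off))
}

# Gaussian-elimination rank with partial pivoting.
brute_rank <- function(m, tol = 1e-9) {
  m <- as.matrix(m) * 1.0
  r <- 0L
  for (col in seq_len(ncol(m))) {
    if (r + 1L > nrow(m)) break
    piv <- which.max(abs(m[(r + 1L):nrow(m), col])) + r
    if (abs(m[piv, col]) < tol) next
    m[c(r + 1L, piv), ] <- m[c(piv, r + 1L), ]
    r <- r + 1L
    for (i in seq_len(nrow(m))[-r])
      m[i, ] <- m[i, ] - m[i, col] / m[r, col] * m[r, ]
  }
  r
}

# Normal-equation least squares by explicit inversion (the brute-force
# counterpart of train_readout's solve()-based path).
ls_oracle <- function(X, Y) Y %*% t(X) %*% solve(X %*% t(X))

# Hand-built single-neuron hybrid weights for closed-form step checks.
manual_hybrid_1 <- function(w_in = 1, w_ring = 0, w_up = 0, w_down = 0) {
  spec <- structure(list(kind = "hybrid", N = 1L, K = 1L, M = 1L,
                         connectivity = 0.5, weight_law = "uniform_pm1",
                         weight_sd = 0.1, process = NULL, seed = 1L),
                    class = "topology_spec")
  structure(list(W_in = matrix(w_in, 1, 1), W_ring = w_ring,
                 W_ring_rev = NULL, W_up = w_up, W_down = w_down,
                 W_x = NULL, graph = NULL, spec = spec),
            class = "reservoir_weights")
}
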