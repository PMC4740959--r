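#' Reservoir topology specification
#'
#' Describes the interconnect pattern of the reservoir layer and how its
#' random weights are drawn. Five kinds are supported: a one-way ring (each
#' neuron receives from its predecessor), a two-way ring, a pure center-hub
#' topology, the hybrid topology (one-way ring plus a single linear center
#' neuron connected to and from every reservoir neuron), and a randomly
#' connected reservoir with a given connectivity fraction.
#'
#' @param kind One of `"one_way_ring"`, `"two_way_ring"`, `"center"`,
#'   `"hybrid"`, `"random"`.
#' @param N Number of reservoir neurons (>= 2 for ring-containing kinds).
#' @param K Number of input channels.
#' @param M Number of outputs.
#' @param connectivity Fraction in (0, 1] of nonzero recurrent links; used
#'   only when `kind = "random"`.
#' @param weight_law How random weights are drawn: `"uniform_pm1"` (uniform
#'   on \[-1, 1\]), `"normal"` (mean 0, sd given by `weight_sd`), or
#'   `"lognormal_mismatch"` (signed lognormal magnitudes as produced by
#'   transistor threshold-voltage mismatch; see [sample_mismatch_synapses()]).
#' @param weight_sd Standard deviation for `weight_law = "normal"`.
#' @param process [process_params()] object; used only for
#'   `weight_law = "lognormal_mismatch"`.
#' @param seed Integer seed; the same `(spec, seed)` pair always reproduces
#'   identical weights.
#' @return An object of class `"topology_spec"`.
#' @seealso [build_topology()]
#' @export
topology_spec <- function(kind = c("hybrid", "one_way_ring", "two_way_ring",
                                   "center", "random"),
                          N, K = 1L, M = 1L, connectivity = 0.5,
                          weight_law = c("uniform_pm1", "normal",
                                         "lognormal_mismatch"),
                          weight_sd = 0.1, process = NULL, seed = 1L) {
  kind <- match.arg(kind)
  weight_law <- match.arg(weight_law)
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("topology_spec: 'N' must be a positive integer, got ", deparse(N))
  if (kind %in% c("one_way_ring", "two_way_ring", "hybrid") && N < 2)
    stop("topology_spec: 'N' must be >= 2 for ring-containing kind '",
         kind, "'")
  if (!is.numeric(K) || K < 1 || K != round(K))
    stop("topology_spec: 'K' must be a positive integer")
  if (!is.numeric(M) || M < 1 || M != round(M))
    stop("topology_spec: 'M' must be a positive integer")
  if (kind == "random" &&
      (!is.numeric(connectivity) || connectivity <= 0 || connectivity > 1))
    stop("topology_spec: 'connectivity' must lie in (0, 1]")
  structure(
    list(kind = kind, N = as.integer(N), K = as.integer(K), M = as.integer(M),
         connectivity = connectivity, weight_law = weight_law,
         weight_sd = weight_sd, process = process, seed = as.integer(seed)),
    class = "topology_spec")
}

#' @export
print.topology_spec <- function(x, ...) {
  cat("Reservoir topology spec\n")
  cat("  kind:", x$kind, " N:", x$N, " K:", x$K, " M:", x$M, "\n")
  if (x$kind == "random") cat("  connectivity:", x$connectivity, "\n")
  cat("  weight law:", x$weight_law, " seed:", x$seed, "\n")
  invisible(x)
}

draw_weights <- function(n, spec) {
  switch(spec$weight_law,
    uniform_pm1 = stats::runif(n, -1, 1),
    normal = stats::rnorm(n, 0, spec$weight_sd),
    lognormal_mismatch = {
      p <- spec$process %||% process_params()
      s <- sample_mismatch_synapses(n, p)
      s$sign * s$w
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build reservoir interconnect and weights
#'
#' Generates the fixed random weight sets of an echo state network for the
#' requested topology, together with the directed graph of reservoir links.
#' Reservoir weights are drawn once from the spec's weight law and are never
#' trained afterwards.
#'
#' The hybrid topology combines a one-way ring (neuron `s` receives the state
#' of neuron `s - 1` from the previous time step) with a single linear center
#' neuron: `W_up` carries every reservoir state up to the hub, `W_down`
#' broadcasts the hub state back to every neuron. Its graph has diameter 2 and
#' average distance below 2 regardless of reservoir size, while the one-way
#' ring has diameter `N - 1`.
#'
#' @param spec A [topology_spec()] (or arguments passed on to it).
#' @param ... When `spec` is missing, arguments forwarded to [topology_spec()].
#' @return An object of class `"reservoir_weights"` with components `W_in`
#'   (N x K), `W_ring`, `W_ring_rev` (two-way ring only), `W_up`, `W_down`
#'   (length-N vectors; center/hybrid only), `W_x` (N x N, random kind only;
#'   zeros encode absent links), `graph` (igraph; reservoir nodes `1..N`,
#'   plus node `"c"` for the center neuron where present), and the `spec`.
#' @examples
#' w <- build_topology(topology_spec("hybrid", N = 25, seed = 7))
#' graph_diameter(w)      # 2
#' average_distance(w)    # < 2
#' @export
build_topology <- function(spec, ...) {
  if (missing(spec)) spec <- topology_spec(...)
  if (!inherits(spec, "topology_spec"))
    stop("build_topology: 'spec' must be a topology_spec object")
  N <- spec$N; K <- spec$K
  set.seed(spec$seed)
  W_in <- matrix(draw_weights(N * K, spec), N, K)
  W_ring <- W_ring_rev <- W_up <- W_down <- NULL
  W_x <- NULL
  edges <- NULL  # two-column character matrix from, to
  ring_edges <- function() cbind(as.character(c(N, seq_len(N - 1L))),
                                 as.character(seq_len(N)))
  if (spec$kind %in% c("one_way_ring", "two_way_ring", "hybrid")) {
    W_ring <- draw_weights(N, spec)
    edges <- ring_edges()
  }
  if (spec$kind == "two_way_ring") {
    W_ring_rev <- draw_weights(N, spec)
    edges <- rbind(edges, cbind(as.character(c(seq_len(N - 1L) + 1L, 1L)),
                                as.character(seq_len(N))))
  }
  if (spec$kind %in% c("center", "hybrid")) {
    W_up <- draw_weights(N, spec)
    W_down <- draw_weights(N, spec)
    edges <- rbind(edges,
                   cbind(as.character(seq_len(N)), rep("c", N)),
                   cbind(rep("c", N), as.character(seq_len(N))))
  }
  if (spec$kind == "random") {
    W_x <- matrix(draw_weights(N * N, spec), N, N)
    mask <- matrix(stats::runif(N * N) <= spec$connectivity, N, N)
    diag(mask) <- FALSE  # no self-loops
    W_x[!mask] <- 0
    idx <- which(W_x != 0, arr.ind = TRUE)
    # edge j -> i for W_x[i, j]
    edges <- cbind(as.character(idx[, 2L]), as.character(idx[, 1L]))
  }
  vnames <- c(as.character(seq_len(N)),
              if (spec$kind %in% c("center", "hybrid")) "c")
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = vnames, stringsAsFactors = FALSE))
  structure(
    list(W_in = W_in, W_ring = W_ring, W_ring_rev = W_ring_rev,
         W_up = W_up, W_down = W_down, W_x = W_x, graph = g, spec = spec),
    class = "reservoir_weights")
}

#' @export
print.reservoir_weights <- function(x, ...) {
  s <- x$spec
  cat("Reservoir weights (", s$kind, ", N = ", s$N, ", K = ", s$K, ")\n",
      sep = "")
  cat("  incoming synaptic links per neuron:",
      unique(incoming_links(x)), "\n")
  invisible(x)
}

# Shortest directed distances between reservoir neurons (center node may be
# an intermediate hop but never an endpoint). Inf marks unreachable pairs.
reservoir_distances <- function(weights) {
  stopifnot(inherits(weights, "reservoir_weights"))
  N <- weights$spec$N
  vs <- as.character(seq_len(N))
  d <- igraph::distances(weights$graph, v = vs, to = vs, mode = "out")
  d
}

#' Directed diameter of the reservoir graph
#'
#' Longest shortest directed path over all ordered pairs of distinct
#' reservoir neurons. Paths may route through the center neuron, but the
#' center is not itself an endpoint.
#'
#' @param weights A `"reservoir_weights"` object from [build_topology()].
#' @return A nonnegative integer, or `Inf` when some ordered pair of
#'   reservoir neurons is not connected by any directed path.
#' @export
graph_diameter <- function(weights) {
  d <- reservoir_distances(weights)
  off <- d[row(d) != col(d)]
  if (length(off) == 0L) return(0L)
  m <- max(off)
  if (is.finite(m)) as.integer(m) else Inf
}

#' Mean shortest directed distance between reservoir neurons
#'
#' Mean of shortest directed path lengths over all ordered pairs of distinct
#' reservoir neurons (center node allowed as an intermediate hop only).
#'
#' @inheritParams graph_diameter
#' @return A nonnegative real, `Inf` if the graph is disconnected.
#' @export
average_distance <- function(weights) {
  d <- reservoir_distances(weights)
  off <- d[row(d) != col(d)]
  if (length(off) == 0L) return(0)
  mean(off)
}

#' Per-neuron synaptic link counts
#'
#' Counts the synaptic links attached to each reservoir neuron using the
#' torus-node bookkeeping of the physical architecture: the input synapse,
#' the incoming ring synapse(s), and — for center-bearing kinds — both the
#' center-down and center-up links are counted at the node, while the output
#' tap is outgoing and not counted. A hybrid neuron therefore has 4 links,
#' a one-way-ring neuron 2, the difference being the two extra center-neuron
#' synapses of the hybrid topology.
#'
#' @inheritParams graph_diameter
#' @return Integer vector of length N.
#' @export
incoming_links <- function(weights) {
  s <- weights$spec
  N <- s$N
  base <- rep(1L, N)  # input synapse
  n_ring <- switch(s$kind,
                   one_way_ring = 1L, two_way_ring = 2L, hybrid = 1L,
                   center = 0L, random = NA_integer_)
  if (s$kind == "random") {
    # W_x[i, j] != 0 means j -> i: incoming count per neuron i is rowSums
    return(base + as.integer(rowSums(weights$W_x != 0)))
  }
  extra <- if (s$kind %in% c("center", "hybrid")) 2L else 0L
  base + n_ring + extra
}

#' Torus link-assignment report for the hybrid topology
#'
#' Maps each reservoir neuron of a hybrid topology onto a rows x cols doubly
#' twisted toroidal node and labels the node's eight links (four incoming,
#' four outgoing) with the ring they implement: the input ring, the
#' reservoir ring, and the center-neuron up/down rings, plus the output tap.
#' The report is purely descriptive — no physical routing is performed.
#'
#' @inheritParams graph_diameter
#' @param rows,cols Torus grid dimensions; `rows * cols` must equal N.
#' @return A data frame with one row per link: neuron id, its torus (row,
#'   col) position, the link label and its direction (`"in"`/`"out"`).
#' @export
toroidal_report <- function(weights, rows, cols) {
  s <- weights$spec
  if (s$kind != "hybrid")
    stop("toroidal_report: only defined for the hybrid topology")
  if (rows * cols != s$N)
    stop("toroidal_report: rows * cols = ", rows * cols,
         " does not equal N = ", s$N)
  N <- s$N
  neuron <- seq_len(N)
  r <- ((neuron - 1L) %/% cols) + 1L
  c_ <- ((neuron - 1L) %% cols) + 1L
  links <- data.frame(
    neuron = rep(neuron, each = 8L),
    row = rep(r, each = 8L),
    col = rep(c_, each = 8L),
    ring = rep(c("input", "ring", "center_down", "center_up",
                 "input", "ring", "center_up", "output"), N),
    direction = rep(c("in", "in", "in", "in", "out", "out", "out", "out"), N),
    stringsAsFactors = FALSE)
  links
}
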