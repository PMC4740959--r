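test_that("hybrid link bookkeeping matches the four-ring node structure", {
  h <- build_topology(topology_spec("hybrid", N = 25, seed = 7))
  expect_true(all(incoming_links(h) == 4L))
  r <- build_topology(topology_spec("one_way_ring", N = 25, seed = 7))
  expect_true(all(incoming_links(r) == 2L))
  expect_true(all(incoming_links(h) - incoming_links(r) == 2L))
})

test_that("graph diameter and average distance match the analytic values", {
  expect_identical(
    graph_diameter(build_topology(topology_spec("hybrid", N = 25,
                                                seed = 7))), 2L)
  expect_identical(
    graph_diameter(build_topology(topology_spec("one_way_ring", N = 10,
                                                seed = 1))), 9L)
  expect_identical(
    graph_diameter(build_topology(topology_spec("one_way_ring", N = 2,
                                                seed = 1))), 1L)
  expect_equal(
    average_distance(build_topology(topology_spec("one_way_ring", N = 3,
                                                  seed = 1))), 1.5)
  # full connectivity (minus self-loops) is a complete digraph
  complete5 <- build_topology(topology_spec("random", N = 5,
                                            connectivity = 1, seed = 2))
  expect_equal(average_distance(complete5), 1.0)
  h100 <- build_topology(topology_spec("hybrid", N = 100, seed = 3))
  expect_lt(average_distance(h100), 2)
})

test_that("metrics agree with a Floyd-Warshall oracle on small graphs", {
  cases <- expand.grid(kind = c("one_way_ring", "two_way_ring", "hybrid",
                                "random"),
                       N = c(4L, 7L, 12L), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    w <- build_topology(topology_spec(cases$kind[i], N = cases$N[i],
                                      connectivity = 0.6,
                                      seed = 40 + i))
    fw <- fw_reservoir_metrics(w)
    if (is.infinite(fw$diameter)) {
      expect_identical(graph_diameter(w), Inf)
    } else {
      expect_identical(graph_diameter(w), as.integer(fw$diameter))
      expect_equal(average_distance(w), fw$average)
    }
  }
})

test_that("ring diameter is N - 1 and hybrid metrics are size-independent", {
  for (N in 2:50)
    expect_identical(
      graph_diameter(build_topology(topology_spec("one_way_ring", N = N,
                                                  seed = N))),
      N - 1L)
  for (N in c(3:12, 30L, 60L)) {
    w <- build_topology(topology_spec("hybrid", N = N, seed = N))
    expect_identical(graph_diameter(w), 2L)
    expect_lt(average_distance(w), 2)
  }
})

test_that("identical seeds reproduce identical weights", {
  for (kind in c("hybrid", "random", "two_way_ring")) {
    a <- build_topology(topology_spec(kind, N = 15, K = 3, seed = 99))
    b <- build_topology(topology_spec(kind, N = 15, K = 3, seed = 99))
    for (f in c("W_in", "W_ring", "W_ring_rev", "W_up", "W_down", "W_x"))
      expect_identical(a[[f]], b[[f]])
    c_ <- build_topology(topology_spec(kind, N = 15, K = 3, seed = 100))
    expect_false(identical(a$W_in, c_$W_in))
  }
})

test_that("random kind honours connectivity with self-loops excluded", {
  full <- build_topology(topology_spec("random", N = 10, connectivity = 1,
                                       seed = 5))
  expect_identical(sum(full$W_x != 0), 90L)   # N(N-1), no self-loops
  expect_true(all(diag(full$W_x) == 0))
  half <- build_topology(topology_spec("random", N = 40,
                                       connectivity = 0.5, seed = 6))
  frac <- sum(half$W_x != 0) / (40 * 39)
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.6)
})

test_that("invalid topology specifications are rejected by name", {
  expect_error(topology_spec("hybrid", N = 1), "'N'")
  expect_error(topology_spec("mesh", N = 10), "arg")
  expect_error(topology_spec("random", N = 10, connectivity = 0),
               "connectivity")
  expect_error(topology_spec("hybrid", N = 10, K = 0), "'K'")
})

test_that("toroidal report labels eight links per node, four incoming", {
  w <- build_topology(topology_spec("hybrid", N = 25, seed = 7))
  rep5 <- toroidal_report(w, 5, 5)
  expect_identical(nrow(rep5), 25L * 8L)
  per_node <- table(rep5$neuron, rep5$direction)
  expect_true(all(per_node[, "in"] == 4L))
  expect_true(all(per_node[, "out"] == 4L))
  w6 <- build_topology(topology_spec("hybrid", N = 6, seed = 7))
  expect_identical(nrow(toroidal_report(w6, 2, 3)), 48L)
  expect_error(toroidal_report(w, 4, 5), "does not equal N")
  expect_error(toroidal_report(
    build_topology(topology_spec("one_way_ring", N = 25, seed = 1)), 5, 5),
    "hybrid")
})
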