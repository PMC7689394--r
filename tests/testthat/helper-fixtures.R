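# Small graphs and networks shared across tests.

# path A - B - C as an edge matrix
path3_edges <- function() rbind(c(1L, 2L), c(2L, 3L))

triangle_edges <- function() rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))

# 6 nodes: two triangles bridged by one edge (7 edges)
two_triangles_edges <- function() {
  rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L),
        c(4L, 5L), c(5L, 6L), c(4L, 6L),
        c(3L, 4L))
}

# 5-node graph with a cycle and a pendant, 6 edges
cycle_pendant_edges <- function() {
  rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L), c(2L, 4L), c(4L, 5L))
}

small_params <- function() model_params(20, 10, 3, 0.02)

small_net <- function(seed = 1L) build_network(small_params(), seed)

# wrap an edge matrix as a spatial_network-like object for run_sir via a
# degenerate 1-community network is overkill; tests on arbitrary graphs use
# sir_reach_mc() instead.

expect_run_invariants <- function(run, N) {
  expect_true(all(run$series$S + run$series$I + run$series$R == N))
  expect_true(all(diff(run$series$R) >= 0))
  expect_equal(run$series$I[nrow(run$series)], 0)
  expect_true(all(diff(run$rmax_series) >= -1e-12))
  expect_equal(run$final_R, run$series$R[nrow(run$series)] / N)
}
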