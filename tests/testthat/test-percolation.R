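test_that("degenerate bond probabilities behave exactly", {
  t0 <- bond_percolation_trial(16, 0, seed = 1)
  expect_false(t0$wraps)
  expect_equal(t0$largest_frac, 1 / 256)
  t1 <- bond_percolation_trial(16, 1, seed = 1)
  expect_true(t1$wraps)
  expect_equal(t1$largest_frac, 1)
})

test_that("trials are deterministic given (size, p, seed)", {
  a <- bond_percolation_trial(32, 0.5, seed = 7)
  b <- bond_percolation_trial(32, 0.5, seed = 7)
  expect_identical(a[c("wraps", "wraps_x", "wraps_y", "largest_frac")],
                   b[c("wraps", "wraps_x", "wraps_y", "largest_frac")])
})

test_that("wrapping frequency at p = 1/2 sits in the critical band", {
  # near criticality the either-axis wrapping probability is strictly
  # between the off-critical extremes
  hits <- sum(vapply(1:60, function(s) {
    bond_percolation_trial(64, 0.5, seed = s)$wraps
  }, logical(1)))
  expect_gt(hits / 60, 0.2)
  expect_lt(hits / 60, 0.95)
})

test_that("wrapping probability is monotone in p under paired seeds", {
  freq <- vapply(c(0.35, 0.45, 0.5, 0.55, 0.65), function(p) {
    mean(vapply(1:40, function(s) {
      bond_percolation_trial(32, p, seed = s)$wraps
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(freq) >= -0.05))
  expect_lt(freq[1], 0.2)
  expect_gt(freq[5], 0.9)
})

test_that("cluster detection agrees with an independent component count", {
  skip_if_not_installed("igraph")
  # rebuild one seeded trial's bond configuration in R and compare the
  # largest-component fraction with igraph
  size <- 24; p <- 0.45; seed <- 99
  trial <- bond_percolation_trial(size, p, seed)
  set.seed(seed)
  n <- size * size
  edges <- NULL
  for (yy in 0:(size - 1)) for (xx in 0:(size - 1)) {
    u <- yy * size + xx + 1
    for (d in 1:2) { # right then down, matching the compiled kernel
      open <- runif(1) < p
      if (open) {
        dx <- if (d == 1) 1 else 0; dy <- if (d == 1) 0 else 1
        v <- ((yy + dy) %% size) * size + (xx + dx) %% size + 1
        edges <- rbind(edges, c(u, v))
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  expect_equal(trial$largest_frac, max(igraph::components(g)$csize) / n)
})

test_that("the exhaustive reach distribution matches hand enumeration", {
  # single edge: P({A}) = 1 - beta, P({A,B}) = beta
  d1 <- sir_reach_distribution_exhaustive(rbind(c(1L, 2L)), 1, 0.3)
  expect_equal(d1$prob[d1$set == "1"], 0.7)
  expect_equal(d1$prob[d1$set == "1,2"], 0.3)

  # triangle at beta = 1: everything reached surely
  d2 <- sir_reach_distribution_exhaustive(triangle_edges(), 1, 1)
  expect_equal(d2$set, "1,2,3")
  expect_equal(d2$prob, 1)

  # path: B gates C
  d3 <- sir_reach_distribution_exhaustive(path3_edges(), 1, 0.5)
  expect_equal(d3$prob[d3$set == "1"], 0.5)
  expect_equal(d3$prob[d3$set == "1,2"], 0.25)
  expect_equal(d3$prob[d3$set == "1,2,3"], 0.25)

  # probabilities always sum to one
  d4 <- sir_reach_distribution_exhaustive(two_triangles_edges(), 2, 0.37)
  expect_equal(sum(d4$prob), 1, tolerance = 1e-12)

  expect_error(sir_reach_distribution_exhaustive(
    cbind(1:13, 2:14), 1, 0.5), "12 edges")
})

test_that("SIR Monte-Carlo matches exhaustive enumeration on small graphs", {
  # the central correctness oracle tying the simulator to bond percolation
  fixtures <- list(
    list(edges = path3_edges(), origin = 1L, beta = 0.5),
    list(edges = triangle_edges(), origin = 1L, beta = 0.6),
    list(edges = two_triangles_edges(), origin = 2L, beta = 0.4),
    list(edges = cycle_pendant_edges(), origin = 1L, beta = 0.55)
  )
  reps <- 3e4
  for (f in fixtures) {
    exact <- sir_reach_distribution_exhaustive(f$edges, f$origin, f$beta)
    mc <- sir_reach_mc(f$edges, f$origin, f$beta, reps = reps,
                       seed = 1000 + f$origin)
    freq <- setNames(mc$freq, mc$set)
    for (i in seq_len(nrow(exact))) {
      p <- exact$prob[i]
      fhat <- if (exact$set[i] %in% names(freq)) freq[[exact$set[i]]] else 0
      band <- 4 * sqrt(p * (1 - p) / reps) + 1 / reps
      expect_lt(abs(fhat - p), band + 1e-12)
    }
    # no impossible sets observed
    expect_true(all(mc$set %in% exact$set))
  }
})

test_that("pc estimation recovers the square-lattice bond threshold", {
  est <- estimate_pc_square(size = 64, replicates = 80, seed = 5)
  expect_lt(abs(est$estimate - 0.5), 0.02)
  expect_true(is.finite(est$stderr))
  expect_error(estimate_pc_square(size = 16, replicates = 80, seed = 1),
               "at least 32")
  expect_error(estimate_pc_square(size = 64, replicates = 10, seed = 1),
               "replicates")
})
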