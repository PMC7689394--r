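test_that("periodic distance uses the minimal image", {
  expect_equal(periodic_distance(c(0, 0), c(0, 0), 10), 0)
  expect_equal(periodic_distance(c(0, 0), c(9, 0), 10), 1)
  expect_equal(periodic_distance(c(0, 0), c(3, 4), 1000), 5)
  # symmetry and vectorization
  a <- cbind(c(1, 5), c(2, 7))
  b <- cbind(c(9, 0), c(2, 1))
  expect_equal(periodic_distance(a, b, 10), periodic_distance(b, a, 10))
})

test_that("beta = 0 infects nobody beyond the origin", {
  net <- small_net(2)
  run <- run_sir(net, 0, seed = 5)
  expect_equal(run$final_R, 1 / net$params$N)
  expect_equal(run$final_extent, 0)
  expect_run_invariants(run, net$params$N)
})

test_that("beta = 1 floods the origin component in eccentricity + 1 steps", {
  skip_if_not_installed("igraph")
  net <- build_network(model_params(20, 20, 6, 0), seed = 8) # one community
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, net$params$N - igraph::vcount(g)))
  comp <- igraph::components(g)
  run <- run_sir(net, 1, origin = 17, seed = 3)
  members <- which(comp$membership == comp$membership[17])
  expect_equal(run$final_R, length(members) / net$params$N)
  sub <- igraph::induced_subgraph(g, members)
  ecc <- igraph::eccentricity(sub, vids = which(members == 17))
  expect_equal(run$steps, unname(ecc) + 1)
  expect_run_invariants(run, net$params$N)
})

test_that("conservation and monotonicity hold across a beta range", {
  net <- small_net(4)
  for (beta in c(0.1, 0.35, 0.6, 0.9)) {
    run <- run_sir(net, beta, seed = round(beta * 100))
    expect_run_invariants(run, net$params$N)
  }
})

test_that("mean final size is non-decreasing in beta with paired seeds", {
  net <- build_network(model_params(30, 10, 4, 0.05), seed = 10)
  betas <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  mR <- vapply(betas, function(b) {
    mean(vapply(1:40, function(r) {
      run_sir(net, b, seed = r, record_events = FALSE)$final_R
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mR) > -0.02)) # monotone up to MC noise
})

test_that("quarantine thinning hits the target retention and restores exactly", {
  net <- build_network(model_params(40, 10, 4, 0.1), seed = 13)
  m_intra <- sum(net$kind == "intra")

  same <- apply_quarantine(net, "intra", degree_summary(net)$mean_intra,
                           seed = 1)
  expect_equal(nrow(same$net$edges), nrow(net$edges))

  none <- apply_quarantine(net, "inter", 0, seed = 1)
  expect_equal(sum(none$net$kind == "inter"), 0)
  expect_equal(sum(none$net$kind == "intra"), m_intra)

  # K = 4 -> K' = 3: each intra edge kept with probability 3/4
  q <- apply_quarantine(net, "intra", 3 * degree_summary(net)$mean_intra / 4,
                        seed = 7)
  kept <- sum(q$net$kind == "intra")
  p_keep <- 3 / 4
  expect_lt(abs(kept - m_intra * p_keep),
            3 * sqrt(m_intra * p_keep * (1 - p_keep)))

  restored <- restore_edges(q$net, q$removed)
  expect_identical(restored$edges, net$edges)
  expect_identical(restored$kind, net$kind)

  expect_error(apply_quarantine(net, "intra", 100, seed = 1), "exceeds")
})

test_that("interventions change the dynamics only after t_x", {
  net <- build_network(model_params(30, 10, 4, 0.1), seed = 20)
  base <- run_sir(net, 0.5, seed = 31, max_steps = 100)
  iv <- intervention("social", t_x = 4, new_value = 0)
  cut <- run_sir(net, 0.5, interventions = list(iv), seed = 31,
                 max_steps = 100)
  # identical trajectory before the intervention step
  shared <- 1:min(4, nrow(base$series), nrow(cut$series))
  expect_equal(cut$series[shared, ], base$series[shared, ])
  # beta' = 0 stops all further infections: everyone infected by t_x recovers
  expect_lte(cut$final_R, base$final_R)
  expect_lte(cut$steps, 6)
})

test_that("intervention at t_x = 0 with beta' = 0 confines the run to the origin", {
  net <- small_net(3)
  iv <- intervention("social", t_x = 0, new_value = 0)
  run <- run_sir(net, 0.9, interventions = list(iv), seed = 2)
  expect_equal(run$final_R, 1 / net$params$N)
  expect_equal(run$final_extent, 0)
})

test_that("temporal quarantine restores the edge set bit-exactly mid-run", {
  net <- build_network(model_params(30, 10, 4, 0.2), seed = 22)
  iv <- intervention("quarantine_inter", t_x = 2, new_value = 0, t_q = 3)
  run <- run_sir(net, 0.6, interventions = list(iv), seed = 40,
                 max_steps = 200)
  expect_run_invariants(run, net$params$N)
  # the run object never mutates the network
  net2 <- build_network(model_params(30, 10, 4, 0.2), seed = 22)
  expect_identical(net$edges, net2$edges)
})

test_that("unsorted intervention schedules are rejected", {
  net <- small_net(5)
  ivs <- list(intervention("social", 10, 0.1),
              intervention("social", 5, 0.2))
  expect_error(run_sir(net, 0.5, interventions = ivs, seed = 1), "sorted")
})

test_that("social interventions cannot raise beta", {
  net <- small_net(5)
  iv <- intervention("social", 5, 0.9)
  expect_error(run_sir(net, 0.5, interventions = list(iv), seed = 1),
               "reduce")
})

test_that("path A-B-C at beta = 1/2 matches the exact outbreak law", {
  # enumerating the two edges: P({A}) = 1/2, P({A,B}) = 1/4, P({A,B,C}) = 1/4
  mc <- sir_reach_mc(path3_edges(), origin = 1, beta = 0.5, reps = 4e4,
                     seed = 77)
  p <- setNames(mc$freq, mc$set)
  se <- 3 * sqrt(0.25 / 4e4)
  expect_lt(abs(p[["1"]] - 0.5), 2 * se)
  expect_lt(abs(p[["1,2"]] - 0.25), 2 * se)
  expect_lt(abs(p[["1,2,3"]] - 0.25), 2 * se)
})

test_that("runs are reproducible given the seed and differ across seeds", {
  net <- small_net(30)
  a <- run_sir(net, 0.5, seed = 123)
  b <- run_sir(net, 0.5, seed = 123)
  expect_identical(a$series, b$series)
  expect_identical(a$rmax_series, b$rmax_series)
  c <- run_sir(net, 0.5, seed = 124)
  expect_false(identical(a$series, c$series))
})

test_that("unwrapped and minimal extent metrics agree before any winding", {
  net <- build_network(model_params(40, 10, 4, 0.05), seed = 15)
  a <- run_sir(net, 0.3, seed = 9, extent_metric = "unwrapped")
  b <- run_sir(net, 0.3, seed = 9, extent_metric = "minimal")
  # small outbreak: no wrap, identical series
  if (a$final_R * net$params$N < 50) {
    expect_equal(a$rmax_series, b$rmax_series)
  }
  # unwrapped extent always dominates the minimal-image one
  full <- run_sir(net, 1, seed = 9, extent_metric = "unwrapped")
  fullm <- run_sir(net, 1, seed = 9, extent_metric = "minimal")
  expect_true(all(full$rmax_series - fullm$rmax_series >= -1e-9))
})
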