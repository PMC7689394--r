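test_that("model parameters validate and derive the documented quantities", {
  p <- model_params(100, 10, 4, 1e-3)
  expect_equal(p$N, 1e4)
  expect_equal(p$N_c, 100)
  expect_equal(p$n_comm, 100)
  expect_equal(p$Q, 0.1)

  # Q = k_inter * zeta^2 at the reference parameters
  expect_equal(model_params(1000, 100, 4, 1e-3)$Q, 10)

  expect_error(model_params(100, 30, 4, 0), "multiple")
  expect_error(model_params(100, 10, 120, 0), "k_intra")
  expect_error(model_params(100, 10, -1, 0), "k_intra")
})

test_that("community grid neighbours wrap periodically", {
  p <- model_params(30, 10, 1, 0) # 3 x 3 grid
  expect_setequal(community_grid_neighbors(1, p), c(2, 3, 4, 7))
  expect_setequal(community_grid_neighbors(5, p), c(2, 4, 6, 8))
  # 1 x 1 grid: all four neighbours are the community itself
  p1 <- model_params(10, 10, 1, 0)
  expect_equal(unname(community_grid_neighbors(1, p1)), rep(1L, 4))
  expect_error(community_grid_neighbors(10, p), "range")
})

test_that("zero wiring gives an empty network and empty degree summary", {
  net <- build_network(model_params(4, 4, 0, 0), seed = 1)
  expect_equal(nrow(net$edges), 0)
  ds <- degree_summary(net)
  expect_equal(ds$mean_intra, 0)
  expect_equal(ds$mean_inter, 0)
  expect_true(all(ds$community_inter_counts == 0))
})

test_that("network edges are canonical, unique and type-pure", {
  net <- build_network(model_params(40, 10, 4, 0.05), seed = 3)
  u <- net$edges[, 1L]; v <- net$edges[, 2L]
  expect_true(all(u < v)) # canonical low-high order, no self-loops
  expect_false(any(duplicated(u * 1e6 + v)))
  # re-derive the kind tag from endpoint communities
  same <- net$community[u] == net$community[v]
  expect_equal(ifelse(same, "intra", "inter"), net$kind)
  # inter edges join lattice-adjacent communities (periodic)
  inter <- which(!same)
  p <- net$params
  ok <- vapply(inter, function(i) {
    net$community[v[i]] %in%
      community_grid_neighbors(net$community[u[i]], p)
  }, logical(1))
  expect_true(all(ok))
})

test_that("empirical degrees match K and k_inter within binomial bands", {
  # N = 1e4, K = 4: binomial degree sd per node ~ 2, 3 sigma band on the
  # mean is 4 +/- 0.06... use the spec's wider 0.3 band for robustness
  net <- build_network(model_params(100, 10, 4, 1e-3), seed = 11)
  ds <- degree_summary(net)
  expect_lt(abs(ds$mean_intra - 4), 0.3)

  # zeta = 100, k_inter = 1e-3: per-community inter count averages to Q = 10
  net2 <- build_network(model_params(1000, 100, 4, 1e-3), seed = 12)
  ds2 <- degree_summary(net2)
  expect_lt(abs(ds2$mean_inter - 1e-3), 5 * sqrt(1e-3 / 1e6))
  expect_lt(abs(mean(ds2$community_inter_counts) - 10), 2)
})

test_that("zeta = L yields a single Erdos-Renyi community, no inter links", {
  net <- build_network(model_params(30, 30, 5, 0.1), seed = 4)
  expect_equal(unique(net$community), 1L)
  expect_equal(sum(net$kind == "inter"), 0)
  expect_gt(sum(net$kind == "intra"), 0)
})

test_that("inter-link directions are isotropic over seeds", {
  # count inter links on horizontal vs vertical community-lattice edges
  p <- model_params(60, 10, 0, 0.2) # Q = 20, 36 communities
  h <- v <- 0
  for (s in 1:30) {
    net <- build_network(p, seed = 100 + s)
    u <- net$edges[, 1L]; vv <- net$edges[, 2L]
    dx <- abs(net$coords[u, 1L] %/% 10 - net$coords[vv, 1L] %/% 10)
    horiz <- dx == 1 | dx == 5 # adjacent or wrapped in x
    h <- h + sum(horiz)
    v <- v + sum(!horiz)
  }
  expect_gt(stats::chisq.test(c(h, v))$p.value, 1e-4)
})

test_that("generation is deterministic given the seed", {
  a <- build_network(model_params(40, 10, 3, 0.05), seed = 9)
  b <- build_network(model_params(40, 10, 3, 0.05), seed = 9)
  expect_identical(a$edges, b$edges)
  expect_identical(a$kind, b$kind)
  c <- build_network(model_params(40, 10, 3, 0.05), seed = 10)
  expect_false(identical(a$edges, c$edges))
})

test_that("networks round-trip through the TSV/JSON representation", {
  net <- small_net(6)
  prefix <- file.path(tempdir(), "net-roundtrip")
  write_network(net, prefix)
  back <- read_network(prefix)
  expect_equal(back$edges, net$edges)
  expect_equal(back$kind, net$kind)
  expect_equal(back$community, net$community)
  expect_equal(back$coords, net$coords)
  expect_equal(back$seed, net$seed)
  expect_equal(back$params$Q, net$params$Q)
})

test_that("intra wiring matches an independent Erdos-Renyi reference", {
  skip_if_not_installed("igraph")
  # mean degree and clustering of a zeta = L community vs igraph's G(n, p)
  p <- model_params(50, 50, 6, 0)
  net <- build_network(p, seed = 21)
  deg_mine <- degree_summary(net)$mean_intra
  g <- igraph::sample_gnp(2500, 6 / 2499)
  expect_lt(abs(deg_mine - mean(igraph::degree(g))), 0.4)
})
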