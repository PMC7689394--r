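test_that("the ER outbreak size solves its self-consistency equation", {
  expect_equal(er_outbreak_size(4, 0.2), 0)   # K beta = 0.8 subcritical
  expect_equal(er_outbreak_size(4, 0.25), 0)  # exactly critical
  S <- er_outbreak_size(4, 0.40740)
  expect_equal(S, 1 - exp(-4 * 0.40740 * S), tolerance = 1e-9)
  expect_equal(S, 0.65748, tolerance = 1e-4)
  expect_gt(er_outbreak_size(50, 1), 0.999999) # K beta -> infinity: S -> 1
})

test_that("the inter-link pmf is the stated binomial", {
  expect_equal(inter_link_count_pmf(0, 0), 1)
  expect_equal(inter_link_count_pmf(2, 1), 2 * (1 / 4) * (3 / 4))
  # against the explicit factorial formula
  for (Q in c(1, 5, 10)) {
    k <- 0:Q
    direct <- factorial(Q) / (factorial(k) * factorial(Q - k)) *
      (1 / 4)^k * (3 / 4)^(Q - k)
    expect_equal(inter_link_count_pmf(Q, k), direct)
    expect_equal(sum(inter_link_count_pmf(Q, k)), 1)
  }
  expect_error(inter_link_count_pmf(2, 3), "0..Q")
  expect_error(inter_link_count_pmf(2.5, 1), "integer")
})

test_that("the non-spread probability has its closed form and limits", {
  expect_equal(no_spread_prob(10, 0, 0.5), 1)
  expect_equal(no_spread_prob(10, 0.5, 0), 1)
  expect_equal(no_spread_prob(0, 0.9, 0.9), 1)
  # closed form equals the pmf average for integer Q
  Q <- 7; S <- 0.6; beta <- 0.45
  avg <- sum(inter_link_count_pmf(Q, 0:Q) * (1 - S * beta)^(0:Q))
  expect_equal(no_spread_prob(Q, S, beta), avg, tolerance = 1e-12)
})

test_that("the two thresholds take their closed-form values", {
  expect_equal(critical_beta_er(4), 0.25)
  expect_equal(critical_beta_er(1), 1)
  expect_error(critical_beta_er(0), "positive")

  expect_equal(round(critical_beta_2d(4, 10), 3), 0.407)
  # Q -> infinity recovers the ER threshold
  expect_equal(critical_beta_2d(4, 1e8), 0.25, tolerance = 1e-6)
  expect_error(critical_beta_2d(-1, 10), "positive")
})

test_that("equations for S at threshold, its limit and the ER root agree", {
  S4 <- outbreak_size_at_threshold(4, 10)
  expect_equal(S4, 0.65752, tolerance = 1e-4)
  expect_equal(S4, er_outbreak_size(4, critical_beta_2d(4, 10), tol = 1e-12),
               tolerance = 1e-8)
  # the large-Q limit formula, exact arithmetic
  expect_equal(outbreak_size_limit(4, 10), 16 * log(2) / 10)
  expect_equal(outbreak_size_limit(1, 1000), 0.0027726, tolerance = 1e-4)
  # relative error of the limit vanishes as Q/K grows
  err <- function(K, Q)
    abs(outbreak_size_limit(K, Q) / outbreak_size_at_threshold(K, Q) - 1)
  expect_lt(err(1, 1e4), err(1, 1e2))
  expect_lt(err(1, 1e4), 1e-3)
})

test_that("critical K and critical Q invert the threshold formula", {
  bc <- critical_beta_2d(4, 10)
  expect_equal(critical_K(bc, 10), 4, tolerance = 1e-6)
  expect_equal(critical_Q(bc, 4), 10, tolerance = 1e-6)
  # roundtrips on a grid
  for (K in c(2, 4, 8)) {
    for (Q in c(1, 5, 50)) {
      b <- critical_beta_2d(K, Q)
      if (b > 1) next # no physical threshold at these (K, Q)
      expect_equal(critical_K(b, Q), K, tolerance = 1e-6)
      if (b > 1 / K + 1e-9)
        expect_equal(critical_Q(b, K), Q, tolerance = 1e-5)
    }
  }
  # infeasibility: beta at or below 4(1 - 2^(-1/Q))
  a4 <- 4 * (1 - 2^(-1 / 10))
  expect_error(critical_K(a4 * 0.99, 10), "infeasible")
  expect_error(critical_Q(0.2, 4), "infeasible") # beta <= 1/K
})

test_that("theory is self-consistent over a (K, Q) grid", {
  Ks <- seq(1.5, 10, length.out = 20)
  Qs <- seq(0.5, 40, length.out = 20)
  for (K in Ks) {
    for (Q in Qs) {
      bc <- critical_beta_2d(K, Q)
      # global threshold never below the local one
      expect_gte(bc, 1 / K - 1e-12)
      if (bc <= 1) { # a physical threshold exists for these (K, Q)
        S <- outbreak_size_at_threshold(K, Q)
        # Eq-consistency: S at threshold is the ER root at the threshold
        expect_equal(S, er_outbreak_size(K, bc, tol = 1e-12),
                     tolerance = 1e-6)
        # non-spread probability at criticality equals the bond threshold
        expect_equal(no_spread_prob(Q, S, bc), 0.5, tolerance = 1e-6)
      }
    }
  }
})

test_that("the global threshold decreases in both K and Q", {
  Qs <- c(1, 2, 5, 10, 20, 50)
  bcs <- vapply(Qs, function(Q) critical_beta_2d(4, Q), numeric(1))
  expect_true(all(diff(bcs) < 0))
  Ks <- c(1.5, 2, 3, 4, 6, 10)
  bcs_K <- vapply(Ks, function(K) critical_beta_2d(K, 10), numeric(1))
  expect_true(all(diff(bcs_K) < 0))
  # coalescence with the ER threshold as Q grows
  expect_lt(critical_beta_2d(4, 1e6) - 0.25, 1e-5)
})

test_that("non-square lattices substitute their own bond threshold", {
  hex <- lattice_spec("hexagonal", p_c = 1 - 2 * sin(pi / 18),
                      neighbor_count = 6)
  bc_hex <- critical_beta_2d(4, 10, hex)
  expect_gt(bc_hex, 1 / 4)
  # self-consistency carries over: non-spread probability equals p_c
  S <- outbreak_size_at_threshold(4, 10, hex)
  a <- 1 - hex$p_c^(1 / 10)
  expect_equal(S, 1 - exp(-6 * 4 * a), tolerance = 1e-12)
  expect_error(lattice_spec("hexagonal"), "supplied")
})

test_that("threshold_set bundles consistent values", {
  ts <- threshold_set(4, 10)
  expect_equal(ts$beta_c_er, 0.25)
  expect_equal(round(ts$beta_c_2d, 3), 0.407)
  expect_lt(ts$beta_c_er, ts$beta_c_2d)
})
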