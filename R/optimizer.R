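#' Pose a control-strategy optimization problem
#'
#' A country sits at \eqn{(K_0, Q_0)} in the structural parameter space and
#' faces an epidemic with infection probability `beta`. If
#' \eqn{\beta > \beta_c^{2D}(K_0, Q_0)} the epidemic percolates and the
#' country must be moved (by quarantine measures, which can only remove
#' links) to a point whose threshold exceeds `beta`. Candidate targets lie
#' on the critical line \eqn{\beta_c^{2D}(K, Q) = \beta(1+\epsilon)}; a
#' weight function over candidate points encodes the cost of the move.
#'
#' @param K0,Q0 Current intra-degree and per-community inter-link count.
#' @param beta Epidemic infection probability.
#' @param lattice A [lattice_spec()].
#' @param epsilon Safety margin above the critical line (default `1e-3`).
#' @param weight Function of `(K, Q)` returning a cost; defaults to the
#'   Euclidean distance from \eqn{(K_0, Q_0)} ([euclidean_weight()]).
#' @return An object of class `strategy_problem`.
#' @export
strategy_problem <- function(K0, Q0, beta, lattice = lattice_spec(),
                             epsilon = 1e-3, weight = NULL) {
  stopifnot(K0 > 0, Q0 > 0, beta > 0, beta <= 1, epsilon > 0)
  if (is.null(weight)) weight <- euclidean_weight(K0, Q0)
  structure(list(K0 = K0, Q0 = Q0, beta = beta, lattice = lattice,
                 epsilon = epsilon, weight = weight),
            class = "strategy_problem")
}

#' Euclidean weight function in the (K, Q) parameter space
#'
#' The default move cost: \eqn{W(K, Q) = \sqrt{(K_0-K)^2 + (Q_0-Q)^2}},
#' whose minimizer on the critical line is the smallest total reduction of
#' intra- and inter-links in raw units.
#'
#' @param K0,Q0 The current position.
#' @return A function of `(K, Q)`.
#' @export
euclidean_weight <- function(K0, Q0) {
  force(K0); force(Q0)
  function(K, Q) sqrt((K0 - K)^2 + (Q0 - Q)^2)
}

#' Discretize the critical line beta_c(K, Q) = beta (1 + epsilon)
#'
#' For each `K` on the grid, solves for the `Q` that puts the country-wide
#' threshold at `beta * (1 + epsilon)` via [critical_Q()]. Values of `K` at
#' or below `1 / (beta (1 + epsilon))` are infeasible (no `Q` reaches the
#' target) and are skipped.
#'
#' @param beta Epidemic infection probability.
#' @param lattice A [lattice_spec()].
#' @param K_range Numeric `c(lo, hi)` range of intra-degrees to scan.
#' @param n_points Number of grid points.
#' @param epsilon Margin above the line.
#' @return Data frame with columns `K` and `Q`; every row satisfies
#'   \eqn{\beta_c^{2D}(K, Q) \ge \beta}.
#' @export
critical_line <- function(beta, lattice = lattice_spec(), K_range,
                          n_points = 100, epsilon = 1e-3) {
  target <- beta * (1 + epsilon)
  if (target > 1) target <- 1
  K_min_feasible <- 1 / target
  Ks <- seq(K_range[1L], K_range[2L], length.out = n_points)
  Ks <- Ks[Ks > K_min_feasible * (1 + 1e-9)]
  if (!length(Ks))
    stop("empty feasible range: every K in K_range is at or below 1/beta, ",
         "no inter-degree reduction can reach the target threshold",
         call. = FALSE)
  Qs <- vapply(Ks, function(K) critical_Q(target, K, lattice), numeric(1))
  data.frame(K = Ks, Q = Qs)
}

#' Optimize the quarantine strategy on the critical line
#'
#' Evaluates the problem's weight function on the discretized critical line,
#' restricted to `K <= K0` and `Q <= Q0` (quarantines only remove links),
#' and returns the minimizer. Ties are broken toward the smaller total
#' relative reduction \eqn{(K_0-K)/K_0 + (Q_0-Q)/Q_0}. The result is
#' labelled `"local"` (only `K` moved), `"global"` (only `Q` moved) or
#' `"mixed"`.
#'
#' If the country is already below threshold, returns strategy `"none"`
#' with zero cost. If no point of the critical line is reachable by removing
#' links alone, errors with a note that only the social strategy (reducing
#' `beta` itself) remains.
#'
#' @param problem A [strategy_problem()].
#' @param n_points Grid resolution along the line.
#' @return List with `K_opt`, `Q_opt`, `W_opt`, `strategy` and the
#'   evaluated `line` data frame.
#' @examples
#' pr <- strategy_problem(K0 = 4, Q0 = 10, beta = 0.45)
#' optimize_strategy(pr, n_points = 200)$strategy
#' @export
optimize_strategy <- function(problem, n_points = 200) {
  stopifnot(inherits(problem, "strategy_problem"))
  K0 <- problem$K0; Q0 <- problem$Q0; beta <- problem$beta
  bc0 <- critical_beta_2d(K0, Q0, problem$lattice)
  if (beta <= bc0) {
    return(list(K_opt = K0, Q_opt = Q0, W_opt = 0, strategy = "none",
                line = NULL,
                message = "already below threshold; nothing to do"))
  }
  target <- beta * (1 + problem$epsilon)
  K_lo <- max(1 / target * (1 + 1e-8), 1e-6)
  if (K_lo >= K0)
    stop("infeasible: even K -> 0 cannot raise the threshold above beta; ",
         "only the social strategy (reducing beta) remains", call. = FALSE)
  line <- critical_line(beta, problem$lattice, c(K_lo, K0),
                        n_points = n_points, epsilon = problem$epsilon)
  line <- line[line$K <= K0 + 1e-12 & line$Q <= Q0 + 1e-12, , drop = FALSE]
  if (!nrow(line))
    stop("infeasible: no point of the critical line is reachable by ",
         "removing links (K <= K0, Q <= Q0); only the social strategy ",
         "remains", call. = FALSE)
  W <- mapply(problem$weight, line$K, line$Q)
  red <- (K0 - line$K) / K0 + (Q0 - line$Q) / Q0
  o <- order(W, red)
  best <- o[1L]
  # relative reductions below 0.1% are discretization artefacts, not moves
  moved_K <- (K0 - line$K[best]) / K0 > 1e-3
  moved_Q <- (Q0 - line$Q[best]) / Q0 > 1e-3
  strategy <- if (moved_K && moved_Q) "mixed"
              else if (moved_K) "local"
              else if (moved_Q) "global"
              else "none"
  list(K_opt = line$K[best], Q_opt = line$Q[best], W_opt = W[best],
       strategy = strategy, line = cbind(line, W = W))
}

#' Is a social-distancing reduction sufficient?
#'
#' A social strategy reduces the infection probability
#' \eqn{\beta \to \beta'}; it suffices when \eqn{\beta'} falls below the
#' country-wide threshold \eqn{\beta_c^{2D}(K, Q)}.
#'
#' @param beta Current infection probability.
#' @param beta_prime Reduced infection probability, in `[0, beta]`.
#' @param K,Q Structural parameters.
#' @param lattice A [lattice_spec()].
#' @return Logical.
#' @examples
#' classify_social_strategy(0.407, 0.3, K = 4, Q = 10) # TRUE
#' @export
classify_social_strategy <- function(beta, beta_prime, K, Q,
                                     lattice = lattice_spec()) {
  stopifnot(beta_prime >= 0, beta_prime <= beta)
  beta_prime < critical_beta_2d(K, Q, lattice)
}

#' Translate an inter-link budget back to a per-node rate
#'
#' The optimizer treats \eqn{Q} as a continuous decision variable; since the
#' city size \eqn{\zeta} rarely changes on epidemic timescales, an
#' implementable target is \eqn{k_{inter}' = Q/\zeta^2}.
#'
#' @param Q Per-community inter-link count.
#' @param zeta Community linear size.
#' @return The per-node inter-degree `k_inter`.
#' @export
k_inter_from_Q <- function(Q, zeta) Q / zeta^2
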