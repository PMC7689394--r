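#' Community-lattice specification for the threshold theory
#'
#' The country-wide epidemic threshold maps the spread between communities
#' onto bond percolation on the lattice the communities tile. The square
#' lattice (bond threshold \eqn{p_c = 1/2}, four neighbours) is the model's
#' default; other tilings substitute their own bond threshold and
#' coordination number. The hexagonal constant is deliberately left
#' user-supplied.
#'
#' @param name `"square"`, `"hexagonal"` or `"custom"`.
#' @param p_c Bond-percolation threshold in `(0, 1)`. Fixed at 1/2 for
#'   `"square"`; required for the other tilings.
#' @param neighbor_count Number of communities adjacent to each community.
#'   Fixed at 4 for `"square"`.
#' @return An object of class `lattice_spec`.
#' @examples
#' lattice_spec() # square lattice
#' @export
lattice_spec <- function(name = c("square", "hexagonal", "custom"),
                         p_c = NULL, neighbor_count = NULL) {
  name <- match.arg(name)
  if (name == "square") {
    p_c <- 0.5
    neighbor_count <- 4L
  } else {
    if (is.null(p_c) || is.null(neighbor_count))
      stop("`p_c` and `neighbor_count` must be supplied for non-square ",
           "lattices", call. = FALSE)
  }
  if (p_c <= 0 || p_c >= 1)
    stop("`p_c` must be in (0, 1)", call. = FALSE)
  if (neighbor_count < 1)
    stop("`neighbor_count` must be a positive integer", call. = FALSE)
  structure(list(name = name, p_c = p_c,
                 neighbor_count = as.integer(neighbor_count)),
            class = "lattice_spec")
}

# a = 1 - p_c^(1/Q), the per-inter-link transmission value at criticality
.lattice_a <- function(Q, lattice) 1 - lattice$p_c^(1 / Q)

#' Final outbreak size of an Erdos-Renyi community
#'
#' The probability that a randomly chosen node joins the local outbreak in a
#' community with mean degree \eqn{K} at infection probability \eqn{\beta}
#' solves the self-consistent equation \eqn{S = 1 - e^{-K\beta S}}. Returns
#' the epidemic (largest) root: 0 when \eqn{K\beta \le 1}, otherwise the
#' unique positive root in `(0, 1]`.
#'
#' @param K Mean intra-community degree, `K >= 0`.
#' @param beta Infection probability in `[0, 1]`.
#' @param tol Absolute root tolerance.
#' @return The outbreak size `S` in `[0, 1]`.
#' @examples
#' er_outbreak_size(4, 0.4074) # about 0.6575
#' @export
er_outbreak_size <- function(K, beta, tol = 1e-10) {
  stopifnot(K >= 0, beta >= 0, beta <= 1, tol > 0)
  if (K * beta <= 1) return(0)
  f <- function(S) S - 1 + exp(-K * beta * S)
  if (f(tol) >= 0) return(0) # root below tol: indistinguishable from 0
  uniroot(f, c(tol, 1), tol = tol)$root
}

#' Binomial distribution of inter-links between two adjacent communities
#'
#' A community's \eqn{Q} inter-links each attach to one of its 4 lattice
#' neighbours with probability 1/4, so the number \eqn{k} of links joining a
#' given adjacent pair is \eqn{P_k(Q) = C_Q^k (1/4)^k (3/4)^{Q-k}}.
#'
#' @param Q Non-negative integer total inter-link count.
#' @param k Integer in `0..Q`.
#' @return The probability \eqn{P_k(Q)}.
#' @export
inter_link_count_pmf <- function(Q, k) {
  if (any(Q != round(Q)) || any(Q < 0))
    stop("`Q` must be a non-negative integer (the continuous extension ",
         "lives in no_spread_prob())", call. = FALSE)
  if (any(k != round(k)) || any(k < 0) || any(k > Q))
    stop("`k` must be an integer in 0..Q", call. = FALSE)
  dbinom(k, size = Q, prob = 1 / 4)
}

#' Probability that a local outbreak does not spread to a neighbour
#'
#' Averaging \eqn{(1 - S\beta)^k} over the binomial inter-link count gives
#' the closed form \eqn{\beta_b = [1 - S\beta/4]^Q}, valid for real `Q`
#' (`Q` is an expectation, \eqn{Q = k_{inter}\zeta^2}). Equals the lattice
#' bond threshold \eqn{p_c} exactly at the country-wide epidemic threshold.
#'
#' @param Q Non-negative real per-community inter-link count.
#' @param S Local outbreak size in `[0, 1]`.
#' @param beta Infection probability in `[0, 1]`.
#' @return The non-spread probability \eqn{\beta_b} in `[0, 1]`.
#' @export
no_spread_prob <- function(Q, S, beta) {
  stopifnot(Q >= 0, S >= 0, S <= 1, beta >= 0, beta <= 1)
  (1 - S * beta / 4)^Q
}

#' Local (within-community) epidemic threshold
#'
#' The Erdos-Renyi epidemic threshold of a single community,
#' \eqn{\beta_c^{ER} = 1/K}.
#'
#' @param K Mean intra-community degree, `K > 0`.
#' @return `1/K`.
#' @export
critical_beta_er <- function(K) {
  if (any(K <= 0)) stop("`K` must be positive", call. = FALSE)
  1 / K
}

#' Country-wide (lattice) epidemic threshold
#'
#' The infection probability above which the epidemic escapes the origin
#' community and percolates through the community lattice. With
#' \eqn{a = 1 - p_c^{1/Q}} (square lattice: \eqn{p_c = 1/2}),
#' \deqn{\beta_c^{2D} = \frac{4a}{1 - \exp(-4Ka)},}
#' the 4s being the square lattice's coordination number (substituted for
#' other tilings). Always at least the local threshold \eqn{1/K}; the two
#' coalesce as \eqn{Q \to \infty}.
#'
#' @param K Mean intra-community degree, `K > 0`.
#' @param Q Per-community inter-link count, `Q > 0` (real).
#' @param lattice A [lattice_spec()]; defaults to the square lattice.
#' @return The threshold \eqn{\beta_c^{2D}}.
#' @examples
#' critical_beta_2d(K = 4, Q = 10) # 0.4074
#' @export
critical_beta_2d <- function(K, Q, lattice = lattice_spec()) {
  if (any(K <= 0) || any(Q <= 0))
    stop("`K` and `Q` must be positive", call. = FALSE)
  nc <- lattice$neighbor_count
  a <- .lattice_a(Q, lattice)
  bc <- nc * a / (1 - exp(-nc * K * a))
  if (any(bc < 1 / K - 1e-12))
    stop("consistency failure: computed beta_c^2D below 1/K", call. = FALSE)
  bc
}

#' Local outbreak size at the country-wide threshold
#'
#' \eqn{S(\beta_c^{2D}) = 1 - \exp(-4K(1 - p_c^{1/Q}))}: finite (not zero)
#' at the second transition because every infected community is already
#' above its local threshold. Equals [er_outbreak_size()] evaluated at
#' [critical_beta_2d()].
#'
#' @inheritParams critical_beta_2d
#' @return The outbreak size at threshold.
#' @export
outbreak_size_at_threshold <- function(K, Q, lattice = lattice_spec()) {
  if (any(K <= 0) || any(Q <= 0))
    stop("`K` and `Q` must be positive", call. = FALSE)
  nc <- lattice$neighbor_count
  a <- .lattice_a(Q, lattice)
  1 - exp(-nc * K * a)
}

#' Large-Q limit of the outbreak size at threshold
#'
#' First-order expansion of [outbreak_size_at_threshold()] for
#' \eqn{Q/K \to \infty}: \eqn{S(\beta_c^{2D}) \simeq 4K\ln 2 / Q} on the
#' square lattice (generally \eqn{-n_c K \ln p_c / Q}). Exceeds 1 outside
#' its asymptotic validity range (e.g. K = 4, Q = 10 gives 1.109).
#'
#' @inheritParams critical_beta_2d
#' @return The limiting expression.
#' @export
outbreak_size_limit <- function(K, Q, lattice = lattice_spec()) {
  if (any(K <= 0) || any(Q <= 0))
    stop("`K` and `Q` must be positive", call. = FALSE)
  -lattice$neighbor_count * K * log(lattice$p_c) / Q
}

#' Critical intra-community degree for a local quarantine
#'
#' Inverts [critical_beta_2d()] in `K`: the intra-degree below which an
#' epidemic with infection probability `beta` no longer percolates through
#' the community lattice,
#' \deqn{K_c = -\frac{1}{4a} \log\left[1 - \frac{4a}{\beta}\right],
#'   \quad a = 1 - p_c^{1/Q}.}
#' Infeasible when \eqn{4a \ge \beta}: no intra-degree reduction alone can
#' raise the threshold above `beta` at this `Q`.
#'
#' @param beta Infection probability in `(0, 1]`.
#' @param Q Per-community inter-link count, `Q > 0`.
#' @param lattice A [lattice_spec()].
#' @return The critical degree \eqn{K_c}.
#' @examples
#' critical_K(critical_beta_2d(4, 10), 10) # recovers 4
#' @export
critical_K <- function(beta, Q, lattice = lattice_spec()) {
  stopifnot(beta > 0, beta <= 1, Q > 0)
  nc <- lattice$neighbor_count
  a <- .lattice_a(Q, lattice)
  arg <- 1 - nc * a / beta
  if (arg <= 0)
    stop("infeasible: beta <= ", signif(nc * a, 6), " = ", nc,
         "*(1 - p_c^(1/Q)); no K puts the lattice threshold above beta at ",
         "this Q - intra-community quarantine alone cannot succeed",
         call. = FALSE)
  -log(arg) / (nc * a)
}

#' Critical inter-link count for a global quarantine
#'
#' Solves \eqn{\beta_c^{2D}(K, Q_c) = \beta} for \eqn{Q_c} numerically
#' (the threshold is monotone decreasing in `Q`). Feasible for
#' `beta` in `(1/K, 1]`.
#'
#' @param beta Infection probability; must exceed the local threshold `1/K`.
#' @param K Mean intra-community degree, `K > 0`.
#' @param lattice A [lattice_spec()].
#' @param tol Root tolerance.
#' @return The critical count \eqn{Q_c}.
#' @examples
#' critical_Q(critical_beta_2d(4, 10), 4) # recovers 10
#' @export
critical_Q <- function(beta, K, lattice = lattice_spec(), tol = 1e-8) {
  stopifnot(K > 0, beta > 0, beta <= 1)
  if (beta <= 1 / K)
    stop("infeasible: beta (", beta, ") <= 1/K (", signif(1 / K, 6),
         "); the lattice threshold exceeds beta for every Q, no ",
         "inter-community reduction is needed or possible", call. = FALSE)
  g <- function(Q) critical_beta_2d(K, Q, lattice) - beta
  lo <- 1e-9
  if (g(lo) < 0)
    stop("infeasible: beta above the Q -> 0 threshold limit", call. = FALSE)
  hi <- 1
  while (g(hi) > 0 && hi < 1e12) hi <- hi * 2
  if (g(hi) > 0)
    stop("failed to bracket Q_c", call. = FALSE)
  uniroot(g, c(lo, hi), tol = tol)$root
}

#' All analytic threshold quantities for one parameter set
#'
#' @inheritParams critical_beta_2d
#' @return An object of class `threshold_result`: list with `beta_c_er`,
#'   `beta_c_2d`, `S_at_threshold` and `S_limit`.
#' @examples
#' threshold_set(K = 4, Q = 10)
#' @export
threshold_set <- function(K, Q, lattice = lattice_spec()) {
  structure(list(
    K = K, Q = Q, lattice = lattice$name,
    beta_c_er = critical_beta_er(K),
    beta_c_2d = critical_beta_2d(K, Q, lattice),
    S_at_threshold = outbreak_size_at_threshold(K, Q, lattice),
    S_limit = outbreak_size_limit(K, Q, lattice)
  ), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Epidemic thresholds (K = %g, Q = %g, %s lattice)\n",
              x$K, x$Q, x$lattice))
  cat(sprintf("  local   beta_c^ER = %.6g\n", x$beta_c_er))
  cat(sprintf("  global  beta_c^2D = %.6g\n", x$beta_c_2d))
  cat(sprintf("  outbreak size at threshold S = %.6g (large-Q limit %.6g)\n",
              x$S_at_threshold, x$S_limit))
  invisible(x)
}
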