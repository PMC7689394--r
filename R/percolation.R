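#' One bond-percolation trial on the periodic square lattice
#'
#' Opens each of the `2 * size^2` bonds of the `size x size` torus
#' independently with probability `p`, finds the clusters by union-find with
#' path compression, and reports whether some cluster wraps the torus
#' (separately per axis, and in either axis) together with the largest
#' cluster fraction. The wrapping (torus-winding) criterion matches the
#' model's periodic boundaries and has sharper finite-size behaviour near
#' \eqn{p_c} than open-boundary spanning.
#'
#' @param size Lattice linear size, `size >= 2`.
#' @param p Bond probability in `[0, 1]`.
#' @param seed Integer seed; the trial is deterministic given
#'   `(size, p, seed)`.
#' @return An object of class `percolation_trial`: list with `size`, `p`,
#'   `seed`, `wraps` (either axis), `wraps_x`, `wraps_y`, `largest_frac`.
#' @examples
#' bond_percolation_trial(16, 0.5, seed = 1)$largest_frac
#' @export
bond_percolation_trial <- function(size, p, seed) {
  stopifnot(size >= 2, p >= 0, p <= 1)
  res <- with_seed(seed, perc_trial_cpp(as.integer(size), p))
  structure(c(list(size = as.integer(size), p = p, seed = as.integer(seed)),
              res),
            class = "percolation_trial")
}

#' Estimate the square-lattice bond-percolation threshold
#'
#' Monte-Carlo bisection on the bond probability of the torus-wrapping
#' frequency against 1/2. The frequency of wrapping around one fixed axis is
#' used as the bisected indicator: at criticality its large-lattice value
#' (about 0.521) is the closest of the wrapping indicators to 1/2, so its
#' 1/2-crossing is a nearly unbiased estimator of \eqn{p_c = 1/2}. The
#' either-axis frequency is recorded alongside.
#'
#' @param size Lattice linear size, at least 32.
#' @param replicates Trials per bisection step, at least 50.
#' @param seed Integer seed.
#' @param p_range Initial bracket for the bisection.
#' @param n_iter Number of bisection steps.
#' @return List with `estimate`, `stderr` (binomial noise at the crossing
#'   divided by the locally fitted slope of the frequency curve),
#'   `replicates`, `size` and the bisection `trace` (data frame with `p`,
#'   `freq_x`, `freq_any`).
#' @examples
#' \donttest{
#' estimate_pc_square(size = 64, replicates = 60, seed = 1)$estimate
#' }
#' @export
estimate_pc_square <- function(size = 128, replicates = 200, seed,
                               p_range = c(0.3, 0.7), n_iter = 12) {
  if (size < 32) stop("`size` must be at least 32", call. = FALSE)
  if (replicates < 50)
    stop("insufficient replicates (need at least 50)", call. = FALSE)
  lo <- p_range[1L]; hi <- p_range[2L]
  trace <- data.frame(p = numeric(0), freq_x = numeric(0),
                      freq_any = numeric(0))
  with_seed(derive_seed(seed, "pc-bisect"), {
    for (i in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      fr <- perc_wrap_freq_cpp(as.integer(size), mid, as.integer(replicates))
      trace[i, ] <- c(mid, fr$freq_x, fr$freq_any)
      if (fr$freq_x < 0.5) lo <- mid else hi <- mid
    }
  })
  est <- (lo + hi) / 2
  # slope of freq vs p from the informative part of the bisection trace
  mid_pts <- trace[trace$freq_x > 0.05 & trace$freq_x < 0.95, , drop = FALSE]
  slope <- if (nrow(mid_pts) >= 2 && length(unique(mid_pts$p)) >= 2) {
    abs(coef(lm(freq_x ~ p, data = mid_pts))[2L])
  } else NA_real_
  se <- if (!is.na(slope) && slope > 0)
    sqrt(0.25 / replicates) / slope else NA_real_
  list(estimate = est, stderr = se, replicates = as.integer(replicates),
       size = as.integer(size), trace = trace)
}

#' Exact distribution of the SIR final recovered set on a small graph
#'
#' Exhaustively enumerates all `2^E` open/closed bond configurations of a
#' graph with at most 12 edges, weights each by
#' \eqn{\beta^{\#open}(1-\beta)^{\#closed}}, and accumulates the probability
#' of each set of nodes reachable from the origin through open bonds. By the
#' SIR-bond-percolation mapping this is exactly the distribution of the
#' final recovered set of [run_sir()] at infection probability `beta`.
#'
#' @param edges Two-column matrix (or data frame) of undirected edges over
#'   integer node labels `1..n`, at most 12 rows.
#' @param origin Origin node label.
#' @param beta Infection (bond) probability in `[0, 1]`.
#' @return Data frame with `set` (comma-separated sorted node labels) and
#'   `prob`; probabilities sum to 1 to within 1e-12.
#' @examples
#' sir_reach_distribution_exhaustive(rbind(c(1, 2), c(2, 3)), 1, 0.5)
#' @export
sir_reach_distribution_exhaustive <- function(edges, origin, beta) {
  edges <- as.matrix(edges)
  E <- nrow(edges)
  if (E > 12) stop("at most 12 edges supported (2^E enumeration)",
                   call. = FALSE)
  stopifnot(beta >= 0, beta <= 1)
  n <- max(edges, origin)
  acc <- new.env(parent = emptyenv())
  for (cfg in 0:(2^E - 1)) {
    open <- if (E > 0) bitwAnd(bitwShiftL(1L, 0:(E - 1)), cfg) > 0 else logical(0)
    k <- sum(open)
    w <- beta^k * (1 - beta)^(E - k)
    if (w == 0) next
    # BFS from origin over open edges
    reach <- origin
    frontier <- origin
    sub <- edges[open, , drop = FALSE]
    while (length(frontier)) {
      nb <- c(sub[sub[, 1L] %in% frontier, 2L],
              sub[sub[, 2L] %in% frontier, 1L])
      frontier <- setdiff(nb, reach)
      reach <- c(reach, frontier)
    }
    key <- paste(sort(reach), collapse = ",")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w
  }
  keys <- ls(acc)
  out <- data.frame(set = keys,
                    prob = vapply(keys, function(k) acc[[k]], numeric(1)))
  rownames(out) <- NULL
  out[order(-out$prob, out$set), , drop = FALSE]
}

#' Monte-Carlo distribution of the SIR final recovered set on a small graph
#'
#' Runs the same compiled SIR dynamics used by [run_sir()] `reps` times on a
#' small graph (at most 16 nodes) and tallies the frequency of every final
#' recovered set, for comparison against
#' [sir_reach_distribution_exhaustive()].
#'
#' @inheritParams sir_reach_distribution_exhaustive
#' @param reps Number of realizations.
#' @param seed Integer seed.
#' @return Data frame with `set`, `count` and `freq`.
#' @export
sir_reach_mc <- function(edges, origin, beta, reps = 1e5, seed) {
  edges <- as.matrix(edges)
  n <- max(edges, origin)
  if (n > 16) stop("at most 16 nodes supported", call. = FALSE)
  m <- nrow(edges)
  ends <- c(edges[, 1L], edges[, 2L])
  other <- c(edges[, 2L], edges[, 1L])
  o <- order(ends)
  off <- c(0L, cumsum(tabulate(ends, n)))
  nbr <- other[o] - 1L
  counts <- with_seed(derive_seed(seed, "reach-mc"),
                      sir_reach_mc_cpp(off, nbr, as.integer(origin) - 1L,
                                       beta, as.integer(reps)))
  hit <- which(counts > 0)
  sets <- vapply(hit, function(i) {
    paste(which(bitwAnd(bitwShiftL(1L, 0:(n - 1)), i - 1L) > 0),
          collapse = ",")
  }, character(1))
  out <- data.frame(set = sets, count = counts[hit],
                    freq = counts[hit] / reps)
  out[order(-out$count, out$set), , drop = FALSE]
}
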