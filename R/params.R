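#' Structural parameters of the spatial modular network
#'
#' Bundles the four structural parameters of the model — lattice linear size
#' `L`, community linear size `zeta`, mean intra-community degree `k_intra`
#' (written \eqn{K}) and mean per-node inter-community degree `k_inter` — and
#' computes the derived quantities: number of nodes \eqn{N = L^2}, community
#' size \eqn{N_c = \zeta^2}, number of communities \eqn{n = N/N_c}, community
#' grid dimension \eqn{g = L/\zeta} and the per-community inter-link budget
#' \eqn{Q = k_{inter}\zeta^2}.
#'
#' @param L Positive integer, lattice linear size in nodes.
#' @param zeta Positive integer, community linear size; must divide `L`.
#' @param k_intra Non-negative mean intra-community degree \eqn{K};
#'   must satisfy `k_intra < zeta^2` so the Erdos-Renyi wiring probability
#'   stays below one.
#' @param k_inter Non-negative mean per-node inter-community degree.
#' @return An object of class `model_params`: a list with fields `L`, `zeta`,
#'   `k_intra`, `k_inter` and derived `N`, `N_c`, `n_comm`, `g`, `Q`.
#' @examples
#' p <- model_params(L = 100, zeta = 10, k_intra = 4, k_inter = 1e-3)
#' p$Q # k_inter * zeta^2
#' @export
model_params <- function(L, zeta, k_intra, k_inter) {
  L <- as.integer(L)
  zeta <- as.integer(zeta)
  if (length(L) != 1L || is.na(L) || L < 1L)
    stop("`L` must be a positive integer", call. = FALSE)
  if (length(zeta) != 1L || is.na(zeta) || zeta < 1L)
    stop("`zeta` must be a positive integer", call. = FALSE)
  if (L %% zeta != 0L)
    stop("`L` must be an exact multiple of `zeta` (got L = ", L,
         ", zeta = ", zeta, ")", call. = FALSE)
  if (!is.numeric(k_intra) || length(k_intra) != 1L || k_intra < 0)
    stop("`k_intra` must be a non-negative number", call. = FALSE)
  if (!is.numeric(k_inter) || length(k_inter) != 1L || k_inter < 0)
    stop("`k_inter` must be a non-negative number", call. = FALSE)
  N_c <- as.numeric(zeta)^2
  if (k_intra >= N_c)
    stop("`k_intra` must be below the community size zeta^2 = ", N_c,
         " (Erdos-Renyi wiring probability must be < 1)", call. = FALSE)
  g <- L %/% zeta
  structure(list(
    L = L, zeta = zeta, k_intra = k_intra, k_inter = k_inter,
    N = as.numeric(L)^2, N_c = N_c, n_comm = as.numeric(g)^2, g = g,
    Q = k_inter * N_c
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Spatial modular network parameters\n")
  cat(sprintf("  L = %d, zeta = %d  (N = %g nodes, %g communities of %g nodes)\n",
              x$L, x$zeta, x$N, x$n_comm, x$N_c))
  cat(sprintf("  K = k_intra = %g, k_inter = %g  (Q = k_inter * zeta^2 = %g)\n",
              x$k_intra, x$k_inter, x$Q))
  invisible(x)
}

#' Neighbouring communities on the periodic community grid
#'
#' Communities tile the lattice as a \eqn{g \times g} grid (\eqn{g = L/\zeta})
#' with periodic wrap; each community has exactly four orthogonal neighbours
#' (with repeats when `g < 3`).
#'
#' @param community_index Integer in `1..g^2`, row-major community index.
#' @param params A [model_params()] object.
#' @return Integer vector of length 4: the up, down, left and right
#'   neighbours (row-major, 1-based) under periodic wrap.
#' @examples
#' p <- model_params(30, 10, 4, 0) # 3 x 3 community grid
#' community_grid_neighbors(1, p)
#' @export
community_grid_neighbors <- function(community_index, params) {
  stopifnot(inherits(params, "model_params"))
  g <- params$g
  ci <- as.integer(community_index)
  if (length(ci) != 1L || is.na(ci) || ci < 1L || ci > g * g)
    stop("`community_index` out of range 1..", g * g, call. = FALSE)
  cx <- (ci - 1L) %% g
  cy <- (ci - 1L) %/% g
  wrap <- function(x) ((x %% g) + g) %% g
  idx <- function(x, y) wrap(y) * g + wrap(x) + 1L
  c(up = idx(cx, cy - 1L), down = idx(cx, cy + 1L),
    left = idx(cx - 1L, cy), right = idx(cx + 1L, cy))
}
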