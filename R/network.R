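#' Build a spatial modular network
#'
#' Generates the two-dimensional spatial modular network: an `L x L` periodic
#' lattice of nodes partitioned into `zeta x zeta` communities. Inside each
#' community every node pair is linked independently with probability
#' \eqn{K/(N_c - 1)} (Erdos-Renyi wiring with mean degree \eqn{K}). Between
#' communities, links connect only the four lattice-adjacent communities
#' (periodic wrap): each ordered adjacency slot (right and down neighbour of
#' every community) carries a Poisson(\eqn{Q/4}) number of links with
#' uniformly chosen endpoints, so a node's inter-degree is Poisson
#' distributed with mean \eqn{k_{inter}} and the number of links joining two
#' adjacent communities has mean \eqn{Q/4}, matching the binomial
#' \eqn{P_k(Q) = C_Q^k (1/4)^k (3/4)^{Q-k}} picture used by the threshold
#' theory. Duplicate node pairs are discarded (collision probability is
#' \eqn{O(k_{inter}^2)}, negligible in the sparse regime).
#'
#' Node ids are 1-based and row-major in the lattice coordinates `(x, y)`,
#' both in `[0, L)`; community indices are 1-based row-major on the
#' \eqn{g \times g} community grid. In the limit `zeta == L` the generator
#' returns a single Erdos-Renyi community with no inter-links.
#'
#' @param params A [model_params()] object.
#' @param seed Integer; generation is deterministic given `(params, seed)`.
#' @return An object of class `spatial_network`: list with `params`, `coords`
#'   (`N x 2` integer matrix of `(x, y)`), `community` (integer vector),
#'   `edges` (`m x 2` integer matrix, canonical low-high order), `kind`
#'   (character vector, `"intra"` or `"inter"`), and `seed`.
#' @examples
#' net <- build_network(model_params(20, 10, 3, 0.01), seed = 1)
#' degree_summary(net)$mean_intra
#' @export
build_network <- function(params, seed) {
  stopifnot(inherits(params, "model_params"))
  seed <- as.integer(seed)
  L <- params$L; zeta <- params$zeta; g <- params$g
  N <- params$N; N_c <- params$N_c; n_comm <- params$n_comm

  ids <- seq_len(N)
  x <- (ids - 1L) %% L
  y <- (ids - 1L) %/% L
  community <- (y %/% zeta) * g + (x %/% zeta) + 1L

  with_seed(seed, {
    intra <- .generate_intra_edges(params)
    inter <- .generate_inter_edges(params)
  })

  edges <- rbind(intra, inter)
  kind <- c(rep("intra", nrow(intra)), rep("inter", nrow(inter)))
  # canonical (low, high) ordering, then drop duplicate node pairs
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  key <- as.numeric(lo) * (N + 1) + as.numeric(hi)
  keep <- !duplicated(key)
  edges <- cbind(u = lo[keep], v = hi[keep])
  kind <- kind[keep]

  structure(list(
    params = params,
    coords = cbind(x = x, y = y),
    community = community,
    edges = edges,
    kind = kind,
    seed = seed
  ), class = "spatial_network")
}

# Erdos-Renyi wiring inside every community: draw the number of present
# pairs ~ Binomial(C(N_c,2), K/(N_c-1)) and sample that many distinct pair
# indices, decoded to (i < j) local indices.
.generate_intra_edges <- function(params) {
  N_c <- params$N_c; zeta <- params$zeta; L <- params$L; g <- params$g
  if (params$k_intra == 0 || N_c < 2) return(matrix(integer(0), 0, 2))
  p <- params$k_intra / (N_c - 1)
  n_pairs <- N_c * (N_c - 1) / 2
  out <- vector("list", params$n_comm)
  for (ci in seq_len(params$n_comm)) {
    m <- rbinom(1L, n_pairs, p)
    if (m == 0L) { out[[ci]] <- matrix(integer(0), 0, 2); next }
    t0 <- sample.int(n_pairs, m) - 1
    # decode pair index t0 (0-based, colex order) -> local 1-based (i, j)
    j <- floor((1 + sqrt(1 + 8 * t0)) / 2) + 1
    base <- (j - 1) * (j - 2) / 2
    over <- t0 < base
    j[over] <- j[over] - 1
    base <- (j - 1) * (j - 2) / 2
    under <- t0 >= j * (j - 1) / 2
    j[under] <- j[under] + 1
    base <- (j - 1) * (j - 2) / 2
    i <- t0 - base + 1
    cx <- (ci - 1L) %% g; cy <- (ci - 1L) %/% g
    out[[ci]] <- cbind(.local_to_id(i, cx, cy, zeta, L),
                       .local_to_id(j, cx, cy, zeta, L))
  }
  do.call(rbind, out)
}

# Inter-community links: the link count on each community-lattice edge
# (right and down neighbour of each community, periodic wrap) follows the
# binomial P_k(Q) = C_Q^k (1/4)^k (3/4)^(Q-k) when Q is a whole number
# (each of a community's Q inter-links picks one of its 4 neighbours), and
# its same-mean Poisson(Q/4) analogue for fractional Q.
.generate_inter_edges <- function(params) {
  g <- params$g; zeta <- params$zeta; L <- params$L; N_c <- params$N_c
  if (g < 2L || params$k_inter == 0) return(matrix(integer(0), 0, 2))
  ci <- seq_len(params$n_comm)
  cx <- (ci - 1L) %% g; cy <- (ci - 1L) %/% g
  slot_a <- rep(ci, 2L)
  ax <- rep(cx, 2L); ay <- rep(cy, 2L)
  bx <- c((cx + 1L) %% g, cx)
  by <- c(cy, (cy + 1L) %% g)
  Q <- params$Q
  counts <- if (abs(Q - round(Q)) < 1e-9) {
    rbinom(length(slot_a), size = round(Q), prob = 1 / 4)
  } else {
    rpois(length(slot_a), Q / 4)
  }
  if (sum(counts) == 0L) return(matrix(integer(0), 0, 2))
  rep_i <- rep.int(seq_along(slot_a), counts)
  m <- length(rep_i)
  lu <- sample.int(N_c, m, replace = TRUE)
  lv <- sample.int(N_c, m, replace = TRUE)
  cbind(.local_to_id(lu, ax[rep_i], ay[rep_i], zeta, L),
        .local_to_id(lv, bx[rep_i], by[rep_i], zeta, L))
}

# local 1-based index within a community -> global 1-based node id
.local_to_id <- function(l, cx, cy, zeta, L) {
  lx <- (l - 1L) %% zeta
  ly <- (l - 1L) %/% zeta
  as.integer((cy * zeta + ly) * L + cx * zeta + lx + 1)
}

#' @export
print.spatial_network <- function(x, ...) {
  print(x$params)
  cat(sprintf("  %d edges (%d intra, %d inter), seed = %d\n",
              nrow(x$edges), sum(x$kind == "intra"), sum(x$kind == "inter"),
              x$seed))
  invisible(x)
}

#' Empirical degree summary of a spatial modular network
#'
#' @param net A [build_network()] result.
#' @return List with `mean_intra` and `mean_inter` (empirical mean degrees
#'   over all nodes) and `community_inter_counts` (number of inter-links
#'   incident to each community; averages to \eqn{Q}).
#' @export
degree_summary <- function(net) {
  stopifnot(inherits(net, "spatial_network"))
  N <- net$params$N
  intra <- net$kind == "intra"
  cc <- net$community[net$edges[net$kind == "inter", , drop = FALSE]]
  counts <- tabulate(cc, nbins = net$params$n_comm)
  list(mean_intra = 2 * sum(intra) / N,
       mean_inter = 2 * sum(!intra) / N,
       community_inter_counts = counts)
}

# Doubled CSR adjacency (0-based offsets/ids for the compiled kernel).
as_adjacency <- function(net) {
  N <- net$params$N
  m <- nrow(net$edges)
  u <- net$edges[, 1L]; v <- net$edges[, 2L]
  ends <- c(u, v); other <- c(v, u)
  eid <- rep.int(seq_len(m), 2L)
  o <- order(ends)
  list(off = c(0L, cumsum(tabulate(ends, N))),
       nbr = other[o] - 1L,
       eid = eid[o] - 1L,
       n = as.integer(N), m = m)
}

#' Write / read a spatial modular network as plain-text tables
#'
#' Writes `<prefix>_nodes.tsv` (columns `id`, `x`, `y`, `community`),
#' `<prefix>_edges.tsv` (columns `u`, `v`, `kind`) and a JSON sidecar
#' `<prefix>_meta.json` holding the structural parameters and generation
#' seed. [read_network()] round-trips the object exactly.
#'
#' @param net A `spatial_network`.
#' @param prefix Path prefix for the three output files.
#' @return `write_network()` returns the three file paths invisibly;
#'   `read_network()` returns the reconstructed `spatial_network`.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "spatial_network"))
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv", "_meta.json"))
  nodes <- data.frame(id = seq_len(net$params$N),
                      x = net$coords[, 1L], y = net$coords[, 2L],
                      community = net$community)
  write.table(nodes, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- data.frame(u = net$edges[, 1L], v = net$edges[, 2L],
                      kind = net$kind)
  write.table(edges, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(L = net$params$L, zeta = net$params$zeta,
               k_intra = net$params$k_intra, k_inter = net$params$k_inter,
               seed = net$seed)
  jsonlite::write_json(meta, paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_network
#' @export
read_network <- function(prefix) {
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv", "_meta.json"))
  meta <- jsonlite::read_json(paths[3L], simplifyVector = TRUE)
  params <- model_params(meta$L, meta$zeta, meta$k_intra, meta$k_inter)
  nodes <- read.table(paths[1L], header = TRUE, sep = "\t")
  edges <- read.table(paths[2L], header = TRUE, sep = "\t",
                      colClasses = c("integer", "integer", "character"))
  structure(list(
    params = params,
    coords = cbind(x = as.integer(nodes$x), y = as.integer(nodes$y)),
    community = as.integer(nodes$community),
    edges = cbind(u = edges$u, v = edges$v),
    kind = edges$kind,
    seed = as.integer(meta$seed)
  ), class = "spatial_network")
}
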