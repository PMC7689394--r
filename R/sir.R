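#' Minimal-image Euclidean distance on the periodic lattice
#'
#' Distance between lattice positions under periodic boundaries: per axis
#' \eqn{\delta = \min(|\Delta|, L - |\Delta|)}, distance
#' \eqn{\sqrt{\delta_x^2 + \delta_y^2}}.
#'
#' @param a,b Numeric vectors of length 2, or matrices with two columns,
#'   of `(x, y)` coordinates in `[0, L)`.
#' @param L Lattice linear size.
#' @return Numeric vector of distances.
#' @examples
#' periodic_distance(c(0, 0), c(9, 0), L = 10) # wraps to 1
#' @export
periodic_distance <- function(a, b, L) {
  a <- matrix(a, ncol = 2L)
  b <- matrix(b, ncol = 2L)
  d <- abs(a - b)
  d <- pmin(d, L - d)
  sqrt(d[, 1L]^2 + d[, 2L]^2)
}

#' Specify a scheduled control intervention
#'
#' Three strategies act on a running epidemic at step `t_x`:
#' * `"social"` — reduce the infection probability \eqn{\beta \to \beta'}
#'   (`new_value` is \eqn{\beta'});
#' * `"quarantine_intra"` — reduce the mean intra-community degree
#'   \eqn{K \to K'} by removing a uniform subset of intra-links;
#' * `"quarantine_inter"` — reduce the mean per-node inter-community degree
#'   \eqn{k_{inter} \to k_{inter}'} (equivalently \eqn{Q \to Q'} at fixed
#'   \eqn{\zeta}) by removing a uniform subset of inter-links.
#'
#' A finite quarantine window `t_q` makes the intervention temporal: removed
#' links are restored bit-exactly (and \eqn{\beta'} reverts) at step
#' `t_x + t_q`.
#'
#' @param strategy One of `"social"`, `"quarantine_intra"`,
#'   `"quarantine_inter"`.
#' @param t_x Non-negative integer intervention step.
#' @param new_value The new parameter value (\eqn{\beta'}, \eqn{K'} or
#'   \eqn{k_{inter}'}).
#' @param t_q Positive integer quarantine window, or `Inf` (permanent).
#' @return An object of class `intervention`.
#' @export
intervention <- function(strategy = c("social", "quarantine_intra",
                                      "quarantine_inter"),
                         t_x, new_value, t_q = Inf) {
  strategy <- match.arg(strategy)
  if (!is.numeric(t_x) || length(t_x) != 1L || t_x < 0)
    stop("`t_x` must be a non-negative integer step", call. = FALSE)
  if (!is.numeric(t_q) || length(t_q) != 1L || t_q < 1)
    stop("`t_q` must be a positive integer or Inf", call. = FALSE)
  if (!is.numeric(new_value) || length(new_value) != 1L || new_value < 0)
    stop("`new_value` must be a non-negative number", call. = FALSE)
  structure(list(strategy = strategy, t_x = as.integer(t_x),
                 new_value = new_value, t_q = t_q),
            class = "intervention")
}

#' Thin a network's edges of one kind to a lower mean degree
#'
#' Removes a uniformly random subset of edges of the given kind so that the
#' expected mean degree of that kind drops to `new_mean_degree`: each such
#' edge is kept independently with probability `new / current`. The removed
#' set is returned so a temporal quarantine can restore it exactly.
#'
#' @param net A `spatial_network`.
#' @param kind `"intra"` or `"inter"`.
#' @param new_mean_degree Target mean degree; must not exceed the current
#'   empirical mean degree of that kind.
#' @param seed Integer seed for the edge selection.
#' @return List with `net` (the thinned network) and `removed` (list with
#'   `indices` into the original edge table, plus the removed `edges` rows
#'   and `kind` tags). Pass to [restore_edges()] to undo.
#' @export
apply_quarantine <- function(net, kind = c("intra", "inter"),
                             new_mean_degree, seed) {
  stopifnot(inherits(net, "spatial_network"))
  kind <- match.arg(kind)
  idx <- which(net$kind == kind)
  cur <- 2 * length(idx) / net$params$N
  if (new_mean_degree > cur + 1e-12)
    stop("`new_mean_degree` (", new_mean_degree,
         ") exceeds the current empirical mean ", kind, " degree (",
         signif(cur, 6), ")", call. = FALSE)
  keep_p <- if (cur > 0) new_mean_degree / cur else 1
  removed_idx <- with_seed(seed, idx[runif(length(idx)) >= keep_p])
  removed <- list(indices = removed_idx,
                  edges = net$edges[removed_idx, , drop = FALSE],
                  kind = net$kind[removed_idx])
  if (length(removed_idx)) {
    net$edges <- net$edges[-removed_idx, , drop = FALSE]
    net$kind <- net$kind[-removed_idx]
  }
  list(net = net, removed = removed)
}

#' @rdname apply_quarantine
#' @param removed The `removed` element returned by [apply_quarantine()].
#' @export
restore_edges <- function(net, removed) {
  stopifnot(inherits(net, "spatial_network"))
  if (!length(removed$indices)) return(net)
  m_new <- nrow(net$edges) + length(removed$indices)
  edges <- matrix(0L, m_new, 2L, dimnames = list(NULL, c("u", "v")))
  kind <- character(m_new)
  edges[removed$indices, ] <- removed$edges
  kind[removed$indices] <- removed$kind
  rest <- setdiff(seq_len(m_new), removed$indices)
  edges[rest, ] <- net$edges
  kind[rest] <- net$kind
  net$edges <- edges
  net$kind <- kind
  net
}

# Compile a list of interventions into the event stream consumed by the
# compiled kernel. Quarantine edge subsets are drawn here, from their own
# seeded streams, so the infection trajectory before t_x is unaffected by
# the presence of scheduled interventions.
.compile_events <- function(net, beta, interventions, seed) {
  ev <- list(time = integer(0), type = integer(0), beta = numeric(0),
             edges = list())
  add <- function(time, type, beta_val = 0, edges = integer(0)) {
    ev$time <<- c(ev$time, as.integer(time))
    ev$type <<- c(ev$type, as.integer(type))
    ev$beta <<- c(ev$beta, beta_val)
    ev$edges <<- c(ev$edges, list(as.integer(edges)))
  }
  active <- rep(TRUE, length(net$kind))
  N <- net$params$N
  for (i in seq_along(interventions)) {
    iv <- interventions[[i]]
    if (iv$strategy == "social") {
      if (iv$new_value > beta + 1e-12)
        stop("social intervention must reduce beta (beta' = ", iv$new_value,
             " > beta = ", beta, ")", call. = FALSE)
      add(iv$t_x, 0L, beta_val = iv$new_value)
      if (is.finite(iv$t_q)) add(iv$t_x + iv$t_q, 0L, beta_val = beta)
    } else {
      kind <- if (iv$strategy == "quarantine_intra") "intra" else "inter"
      # new_value is K' for intra, k_inter' for inter; both are target mean
      # degrees of that edge kind
      idx <- which(net$kind == kind & active)
      cur <- 2 * length(idx) / N
      if (iv$new_value > cur + 1e-12)
        stop("quarantine target mean degree (", iv$new_value,
             ") exceeds current ", kind, " mean degree (", signif(cur, 6),
             ")", call. = FALSE)
      keep_p <- if (cur > 0) iv$new_value / cur else 1
      rm_idx <- with_seed(derive_seed(seed, "quarantine", i),
                          idx[runif(length(idx)) >= keep_p])
      add(iv$t_x, 1L, edges = rm_idx - 1L)
      if (is.finite(iv$t_q)) {
        add(iv$t_x + iv$t_q, 2L, edges = rm_idx - 1L)
      } else {
        active[rm_idx] <- FALSE
      }
    }
  }
  o <- order(ev$time)
  list(time = ev$time[o], type = ev$type[o], beta = ev$beta[o],
       edges = ev$edges[o])
}

#' Run one SIR epidemic realization
#'
#' Synchronous discrete-time SIR dynamics: starting from a single infected
#' origin node, at each step every infected node attempts to infect each
#' susceptible neighbour independently with probability `beta`, then
#' recovers (recovery probability 1). Newly infected nodes become infectious
#' at the next step. The run terminates when no infected nodes remain or
#' `max_steps` is reached (flagged in the result). Scheduled
#' [intervention()]s take effect at the start of step `t_x`; temporal
#' quarantines restore the removed edges at the start of step `t_x + t_q`.
#'
#' @param net A `spatial_network`.
#' @param beta Per-contact, per-step infection probability in `[0, 1]`.
#' @param origin `"random"` (uniform node in a uniformly chosen community),
#'   `"central"` (uniform node in the community at the centre of the grid),
#'   or an explicit node id.
#' @param interventions List of [intervention()] objects, sorted by `t_x`.
#' @param max_steps Maximum number of steps.
#' @param seed Integer seed; the run is deterministic given all seeds.
#'   Origin choice, quarantine edge selection and infection draws use
#'   independently derived streams.
#' @param record_events If `TRUE` (default) keep the per-node recovery steps
#'   and distances from the origin.
#' @param extent_metric Distance metric for the running spatial extent
#'   `rmax_series`: `"unwrapped"` (default) accumulates minimal-image steps
#'   along the infection tree, so the extent keeps growing when the front
#'   winds around the torus; `"minimal"` is the minimal-image distance
#'   (capped near `L/2` per axis). The two agree exactly until the first
#'   winding. `recovery_events$distance` always reports the minimal-image
#'   distance.
#' @param adj Optional precomputed adjacency (internal, for sweeps).
#' @return An object of class `epidemic_run`: list with `series` (data frame
#'   `step`, `S`, `I`, `R`), `final_R` (recovered fraction), `origin`,
#'   `rmax_series` (running maximum distance from the origin of newly
#'   recovered nodes, indexed by step `0..steps`), `recovery_events` (data
#'   frame `step`, `node`, `distance`, if recorded), `steps`, `hit_max`,
#'   `extent_at_intervention` (running-max extent at the first `t_x`, `NA`
#'   when no intervention) and `final_extent`.
#' @examples
#' net <- build_network(model_params(20, 10, 3, 0.02), seed = 1)
#' run <- run_sir(net, beta = 0.5, seed = 2)
#' run$final_R
#' @export
run_sir <- function(net, beta, origin = "random", interventions = list(),
                    max_steps = 10000L, seed, record_events = TRUE,
                    extent_metric = c("unwrapped", "minimal"),
                    adj = NULL) {
  extent_metric <- match.arg(extent_metric)
  stopifnot(inherits(net, "spatial_network"))
  if (!is.numeric(beta) || beta < 0 || beta > 1)
    stop("`beta` must be in [0, 1]", call. = FALSE)
  if (max_steps < 1) stop("`max_steps` must be >= 1", call. = FALSE)
  if (inherits(interventions, "intervention"))
    interventions <- list(interventions)
  if (length(interventions)) {
    txs <- vapply(interventions, `[[`, numeric(1), "t_x")
    if (is.unsorted(txs))
      stop("interventions must be sorted by `t_x`", call. = FALSE)
  }
  N <- net$params$N

  orig <- if (is.numeric(origin)) {
    as.integer(origin)
  } else if (identical(origin, "central")) {
    g <- net$params$g
    ci <- (g %/% 2) * g + (g %/% 2) + 1L
    with_seed(derive_seed(seed, "origin"),
              sample(which(net$community == ci), 1L))
  } else {
    with_seed(derive_seed(seed, "origin"), {
      ci <- sample.int(net$params$n_comm, 1L)
      sample(which(net$community == ci), 1L)
    })
  }
  if (orig < 1L || orig > N) stop("origin node id out of range", call. = FALSE)

  ev <- .compile_events(net, beta, interventions, seed)
  if (is.null(adj)) adj <- as_adjacency(net)

  res <- with_seed(derive_seed(seed, "infection"),
                   sir_run_cpp(adj$off, adj$nbr, adj$eid, adj$m,
                               orig - 1L, beta, as.integer(max_steps),
                               ev$time, ev$type, ev$beta, ev$edges,
                               net$coords[, 1L], net$coords[, 2L],
                               net$params$L))

  steps <- res$steps
  rec_step <- res$rec_step # -1 = never recovered
  i_counts <- res$i_counts
  r_counts <- cumsum(tabulate(rec_step + 1L, nbins = steps + 1L))
  # tabulate bin t+1 counts recoveries at step t; step 0 has none
  series <- data.frame(step = 0:steps, S = N - i_counts - r_counts,
                       I = i_counts, R = r_counts)

  rec_nodes <- which(rec_step >= 0L)
  dist <- periodic_distance(net$coords[rec_nodes, , drop = FALSE],
                            net$coords[rep(orig, length(rec_nodes)), ,
                                       drop = FALSE],
                            net$params$L)
  ext_dist <- if (extent_metric == "unwrapped") {
    sqrt(res$disp_x[rec_nodes]^2 + res$disp_y[rec_nodes]^2)
  } else {
    dist
  }
  step_max <- rep(0, steps + 1L)
  if (length(rec_nodes)) {
    mx <- tapply(ext_dist, rec_step[rec_nodes], max)
    step_max[as.integer(names(mx)) + 1L] <- mx
  }
  rmax_series <- cummax(step_max)

  tx1 <- if (length(interventions)) interventions[[1L]]$t_x else NA_integer_
  extent_x <- if (!is.na(tx1)) rmax_series[min(tx1, steps) + 1L] else NA_real_

  out <- list(
    series = series,
    final_R = r_counts[steps + 1L] / N,
    origin = orig,
    steps = steps,
    hit_max = res$hit_max,
    rmax_series = rmax_series,
    final_extent = rmax_series[steps + 1L],
    extent_at_intervention = extent_x,
    t_x = tx1,
    params = net$params,
    seed = seed,
    beta = beta
  )
  if (record_events) {
    o <- order(rec_step[rec_nodes])
    out$recovery_events <- data.frame(step = rec_step[rec_nodes][o],
                                      node = rec_nodes[o],
                                      distance = dist[o])
    out$rec_step <- rec_step
  }
  structure(out, class = "epidemic_run")
}

#' @export
print.epidemic_run <- function(x, ...) {
  cat(sprintf("SIR run: beta = %g, origin = %d, %d steps, final R = %.4g%s\n",
              x$beta, x$origin, x$steps, x$final_R,
              if (x$hit_max) " (max_steps reached with infections active)"
              else ""))
  invisible(x)
}

#' Serialize an epidemic run to JSON
#'
#' @param run An `epidemic_run`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_run_json <- function(run, path) {
  stopifnot(inherits(run, "epidemic_run"))
  obj <- list(beta = run$beta, seed = run$seed, origin = run$origin,
              steps = run$steps, hit_max = run$hit_max,
              final_R = run$final_R,
              final_extent = run$final_extent,
              extent_at_intervention = run$extent_at_intervention,
              series = run$series, rmax_series = run$rmax_series)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
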