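#' Sweep the infection probability and record final outbreak sizes
#'
#' For each `beta` on the grid, averages the final recovered fraction
#' `final_R` of [run_sir()] over `replicates` realizations on freshly
#' generated networks. With `reuse_networks = TRUE` (default) one network is
#' generated per replicate and swept across all `beta` values with paired
#' epidemic seeds; otherwise every `(beta, replicate)` pair gets a fresh
#' network.
#'
#' @param params A [model_params()] object.
#' @param betas Increasing numeric grid in `[0, 1]`.
#' @param replicates Number of realizations per `beta`, at least 1.
#' @param seed Master seed; all network and epidemic seeds derive from it.
#' @param reuse_networks Reuse one network per replicate across the grid.
#' @param origin Origin rule passed to [run_sir()].
#' @param max_steps Passed to [run_sir()].
#' @return An object of class `sweep_result`: list with `beta`, `mean_R`,
#'   `R` (replicates x beta matrix), `replicates`, `params`, `seed`.
#' @export
beta_sweep <- function(params, betas, replicates, seed,
                       reuse_networks = TRUE, origin = "random",
                       max_steps = 10000L) {
  stopifnot(inherits(params, "model_params"), replicates >= 1,
            all(betas >= 0), all(betas <= 1))
  betas <- sort(betas)
  R <- matrix(NA_real_, replicates, length(betas))
  for (r in seq_len(replicates)) {
    if (reuse_networks) {
      net <- build_network(params, derive_seed(seed, "net", r))
      adj <- as_adjacency(net)
    }
    for (b in seq_along(betas)) {
      if (!reuse_networks) {
        net <- build_network(params,
                             derive_seed(seed, "net", r * 100000L + b))
        adj <- as_adjacency(net)
      }
      run <- run_sir(net, betas[b], origin = origin,
                     max_steps = max_steps,
                     seed = derive_seed(seed, "sir", r * 100000L + b),
                     record_events = FALSE, adj = adj)
      R[r, b] <- run$final_R
    }
  }
  structure(list(beta = betas, mean_R = colMeans(R), R = R,
                 replicates = as.integer(replicates), params = params,
                 seed = seed),
            class = "sweep_result")
}

#' Detect the two epidemic thresholds from a beta sweep
#'
#' Takes the derivative of \eqn{\log \bar R} with respect to \eqn{\beta}
#' (central finite differences after a moving-average smoothing, with
#' \eqn{\bar R} floored at `1/N` to avoid `log 0`) and locates its local
#' maxima. The two largest maxima separated by at least two grid steps are
#' the local (within-community) and country-wide thresholds. When only one
#' maximum exists — expected when \eqn{\zeta \to L} and the two transitions
#' coalesce — it is returned with `single = TRUE`.
#'
#' @param sweep A [beta_sweep()] result.
#' @param smoothing Odd moving-average window length (default 3).
#' @param separation Minimum number of grid steps between the two reported
#'   maxima (default 2). When the approximate threshold positions are known
#'   in advance, setting this near half their separation (in grid steps)
#'   prevents shoulder bumps of one transition from masquerading as the
#'   other.
#' @return List with `beta1`, `beta2` (`NA` when single), `single`, and the
#'   `deriv` data frame (`beta`, `dlogR`).
#' @export
log_derivative_thresholds <- function(sweep, smoothing = 3, separation = 2) {
  stopifnot(inherits(sweep, "sweep_result"))
  b <- sweep$beta
  if (length(b) < 7)
    stop("at least 7 grid points required", call. = FALSE)
  floor_R <- 1 / sweep$params$N
  y <- log(pmax(sweep$mean_R, floor_R))
  if (smoothing > 1) {
    k <- smoothing %/% 2L
    y <- vapply(seq_along(y), function(i) {
      w <- max(1L, i - k):min(length(y), i + k)
      mean(y[w])
    }, numeric(1))
  }
  n <- length(b)
  i <- 2:(n - 1)
  d <- (y[i + 1L] - y[i - 1L]) / (b[i + 1L] - b[i - 1L])
  bi <- b[i]
  # interior local maxima of the derivative
  loc <- which(d >= c(-Inf, d[-length(d)]) & d >= c(d[-1L], -Inf))
  loc <- loc[order(-d[loc])]
  deriv <- data.frame(beta = bi, dlogR = d)
  if (!length(loc))
    return(list(beta1 = NA_real_, beta2 = NA_real_, single = TRUE,
                deriv = deriv))
  # sub-grid refinement: parabola through the three derivative points
  # around a maximum, vertex clamped to one grid step
  refine <- function(j) {
    if (j <= 1L || j >= length(d)) return(bi[j])
    y1 <- d[j - 1L]; y2 <- d[j]; y3 <- d[j + 1L]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) < 1e-12) return(bi[j])
    delta <- 0.5 * (y1 - y3) / denom
    bi[j] + max(-1, min(1, delta)) * (bi[2L] - bi[1L])
  }
  first <- loc[1L]
  rest <- loc[abs(loc - first) >= separation]
  if (!length(rest)) {
    return(list(beta1 = refine(first), beta2 = NA_real_, single = TRUE,
                deriv = deriv))
  }
  second <- rest[1L]
  pair <- sort(c(refine(first), refine(second)))
  list(beta1 = pair[1L], beta2 = pair[2L], single = FALSE, deriv = deriv)
}

#' Mean maximal spatial extent of the epidemic versus time
#'
#' Averages the running maximum distance from the origin of newly recovered
#' nodes, \eqn{\langle r_{max}\rangle(t)}, over replicate runs started from
#' a uniform node of the central community. Three averaging modes:
#' * `"surviving"` (default): averages over the runs still infectious at a
#'   reference time `t_ref` (the last time at least `min_active` runs remain
#'   active), for `t <= t_ref`. This is the standard conditioning for
#'   spreading exponents at criticality: runs approaching extinction stall
#'   before dying, and mixing them in biases the front velocity downward
#'   within any fit window.
#' * `"active"`: averages over runs that still carry infections at each `t`
#'   (the curve ends when none remain); the averaged population changes
#'   along the curve.
#' * `"carry"`: averages over all runs, extinct runs contributing their
#'   final extent thereafter (monotone by construction).
#'
#' @param params A [model_params()] object.
#' @param beta Infection probability; spatial propagation needs
#'   `beta > 1/K`.
#' @param replicates Number of runs.
#' @param seed Master seed.
#' @param max_steps Maximum steps per run.
#' @param extent_average `"surviving"`, `"active"` or `"carry"` (see above).
#' @param min_active Minimum surviving-run count defining the reference
#'   time of the `"surviving"` mode; default `max(5, 10%)` of `replicates`,
#'   so the conditioning tracks a fixed survival quantile as replicates
#'   grow.
#' @return An object of class `propagation_curve`: list with `t`,
#'   `rmax_mean`, `n_active`, `replicates`, `params`, `beta`, `degenerate`
#'   (`TRUE` when no run left the origin community), and for the
#'   `"surviving"` mode `t_ref` and `n_surviving`.
#' @export
propagation_curve <- function(params, beta, replicates, seed,
                              max_steps = 1500L,
                              extent_average = c("surviving", "active",
                                                 "carry"),
                              min_active = NULL,
                              extent_metric = c("unwrapped", "minimal")) {
  extent_metric <- match.arg(extent_metric)
  stopifnot(inherits(params, "model_params"))
  extent_average <- match.arg(extent_average)
  if (is.null(min_active))
    min_active <- max(5L, as.integer(ceiling(0.1 * replicates)))
  if (beta <= critical_beta_er(params$k_intra))
    warning("beta <= 1/K: no local outbreak expected, curve likely ",
            "degenerate")
  series <- vector("list", replicates)
  T_run <- integer(replicates)
  for (r in seq_len(replicates)) {
    net <- build_network(params, derive_seed(seed, "net", r))
    run <- run_sir(net, beta, origin = "central", max_steps = max_steps,
                   seed = derive_seed(seed, "sir", r), record_events = FALSE,
                   extent_metric = extent_metric)
    series[[r]] <- run$rmax_series
    T_run[r] <- run$steps
  }
  t_max <- max(T_run)
  n_active_all <- vapply(0:t_max, function(t) sum(T_run >= t), integer(1))
  t_ref <- NA_integer_
  if (extent_average == "surviving") {
    ok <- which(n_active_all >= min_active)
    t_ref <- if (length(ok)) max(ok) - 1L else 0L
    keep <- which(T_run >= t_ref)
    series <- series[keep]
    t_max <- t_ref
  } else {
    keep <- seq_len(replicates)
  }
  tgrid <- 0:t_max
  rmat <- matrix(NA_real_, length(series), t_max + 1L)
  for (r in seq_along(series)) {
    s <- series[[r]][seq_len(min(length(series[[r]]), t_max + 1L))]
    rmat[r, seq_along(s)] <- s
    if (extent_average == "carry" && length(s) < t_max + 1L)
      rmat[r, (length(s) + 1L):(t_max + 1L)] <- s[length(s)]
  }
  rmax_mean <- colMeans(rmat, na.rm = TRUE)
  degenerate <- max(rmax_mean, na.rm = TRUE) <= params$zeta
  structure(list(t = tgrid, rmax_mean = rmax_mean,
                 n_active = n_active_all[seq_len(t_max + 1L)],
                 replicates = as.integer(replicates), params = params,
                 beta = beta, extent_average = extent_average,
                 extent_metric = extent_metric,
                 t_ref = t_ref, n_surviving = length(series),
                 degenerate = degenerate),
            class = "propagation_curve")
}

#' Circle timescales of the early spatial propagation
#'
#' Early on, the epidemic dwells in concentric "circles" of communities
#' around the origin city: extent \eqn{\approx i\zeta} while spreading in
#' circle `i`. Assigning circle index \eqn{c(t) = \lfloor r(t)/\zeta + 1/2
#' \rfloor} (boundaries at half-integer multiples of \eqn{\zeta}), the
#' timescale \eqn{\tau_i} is the time spent at index `i` before first
#' reaching `i + 1`; \eqn{\tau_x} is the mean duration of the
#' plateau-to-plateau transitions. Plateaus occupied for fewer than 2 steps
#' are reported as `NA` (the circle structure has dissolved).
#'
#' @param curve A [propagation_curve()] (or any list with `t` and
#'   `rmax_mean`).
#' @param zeta Community linear size.
#' @return List with `tau0`, `tau1`, `tau2`, `tau_x` (`NA` where not
#'   identifiable).
#' @export
circle_timescales <- function(curve, zeta) {
  r <- curve$rmax_mean
  t <- curve$t
  ok <- !is.na(r)
  r <- r[ok]; t <- t[ok]
  ci <- floor(r / zeta + 0.5)
  first_t <- function(i) {
    w <- which(ci >= i)
    if (length(w)) t[w[1L]] else NA_real_
  }
  last_at <- function(i) {
    w <- which(ci == i)
    if (length(w)) t[w[length(w)]] else NA_real_
  }
  dwell <- function(i) sum(ci == i)
  tau <- function(i) {
    a <- first_t(i); bnd <- first_t(i + 1)
    if (is.na(a) || is.na(bnd)) return(NA_real_)
    if (dwell(i) < 2) return(NA_real_)
    bnd - a
  }
  trans <- vapply(0:2, function(i) {
    a <- last_at(i); bnd <- first_t(i + 1)
    if (is.na(a) || is.na(bnd) || dwell(i) < 2) NA_real_ else bnd - a
  }, numeric(1))
  list(tau0 = tau(0), tau1 = tau(1), tau2 = tau(2),
       tau_x = if (all(is.na(trans))) NA_real_ else mean(trans, na.rm = TRUE))
}

#' Fit the shortest-path (chemical distance) exponent d_min
#'
#' At the country-wide threshold the late-time extent grows as
#' \eqn{\langle r_{max}\rangle \sim t^{1/d_{min}}} with
#' \eqn{d_{min} \approx 1.13} in two dimensions. Fits the least-squares
#' slope `s` of \eqn{\log\langle r_{max}\rangle} versus \eqn{\log t} over
#' the window and returns `1/s`.
#'
#' The default window excludes the circle regime
#' (\eqn{\langle r_{max}\rangle < 3\zeta}), the regime where finite size
#' distorts the extent (beyond `L` for the unwrapped extent metric, whose
#' growth is limited by the cluster meeting its own periodic images; beyond
#' `0.45 L` for the minimal-image metric, which saturates near `L/2`),
#' times where fewer than 5 runs remain active, and keeps the last decade
#' of the remaining time axis.
#'
#' @param curve A [propagation_curve()] result.
#' @param window Optional numeric `c(t_lo, t_hi)` overriding the default
#'   selection.
#' @return The fitted exponent \eqn{d_{min}} (a single number), with the
#'   fitted window attached as attributes `window` and `n_points`.
#' @export
fit_dmin <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "propagation_curve") ||
              (!is.null(curve$t) && !is.null(curve$rmax_mean)))
  t <- curve$t
  r <- curve$rmax_mean
  keep <- !is.na(r) & t > 0 & r > 0
  if (is.null(window)) {
    zeta <- curve$params$zeta
    L <- curve$params$L
    r_cap <- if (identical(curve$extent_metric, "minimal")) 0.45 * L else 0.5 * L
    keep <- keep & r > 3 * zeta & r < r_cap
    if (!is.null(curve$n_active)) keep <- keep & curve$n_active >= 5
    if (any(keep)) {
      t_hi <- max(t[keep])
      keep <- keep & t >= t_hi / 10
    }
  } else {
    keep <- keep & t >= window[1L] & t <= window[2L]
  }
  if (sum(keep) < 5)
    stop("fit window too short (fewer than 5 usable points)", call. = FALSE)
  fit <- lm(log(r[keep]) ~ log(t[keep]))
  s <- coef(fit)[[2L]]
  structure(1 / s, window = range(t[keep]), n_points = sum(keep))
}

#' Summarize intervention effectiveness over replicate runs
#'
#' Compares the mean epidemic extent at the intervention step,
#' \eqn{\langle r_{max}\rangle_x}, with the mean terminal extent
#' \eqn{\langle r_{max}\rangle_f}, over runs that still carried infections
#' at `t_x`. The intervention counts as having stopped the spatial
#' propagation when the mean additional extent stays below `band`
#' (default \eqn{2\zeta}).
#'
#' @param runs List of [run_sir()] results sharing one intervention
#'   schedule.
#' @param band Stopping band in lattice units; default `2 * zeta`.
#' @return List with `rmax_x`, `rmax_f` (means over runs active at `t_x`),
#'   `stopped` (logical, mean criterion), `stopped_fraction` (per-run
#'   criterion), `n_active_at_tx`.
#' @export
intervention_outcome <- function(runs, band = NULL) {
  stopifnot(length(runs) >= 1, inherits(runs[[1L]], "epidemic_run"))
  zeta <- runs[[1L]]$params$zeta
  if (is.null(band)) band <- 2 * zeta
  tx <- runs[[1L]]$t_x
  active <- vapply(runs, function(r) {
    !is.na(r$t_x) && r$steps >= r$t_x
  }, logical(1))
  if (is.na(tx) || !any(active)) {
    return(list(rmax_x = NA_real_, rmax_f = NA_real_, stopped = NA,
                stopped_fraction = NA_real_, n_active_at_tx = 0L))
  }
  rx <- vapply(runs[active], `[[`, numeric(1), "extent_at_intervention")
  rf <- vapply(runs[active], `[[`, numeric(1), "final_extent")
  list(rmax_x = mean(rx), rmax_f = mean(rf),
       stopped = (mean(rf) - mean(rx)) <= band,
       stopped_fraction = mean((rf - rx) <= band),
       n_active_at_tx = sum(active))
}
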