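#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration (same schema either way), rejects
#' unknown keys by name, validates the model parameters and fills defaults.
#' The schema mirrors the experiment kinds: `theory`, `build`, `simulate`,
#' `sweep`, `propagate`, `intervene`, `percolation`, `optimize`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json", call. = FALSE)
  validate_config(raw)
}

.config_schema <- list(
  top = c("experiment", "seed", "output_prefix", "model", "epidemic",
          "interventions", "sweep", "propagate", "percolation", "optimize"),
  model = c("L", "zeta", "k_intra", "k_inter"),
  epidemic = c("beta", "origin", "max_steps"),
  intervention = c("strategy", "t_x", "new_value", "t_q"),
  sweep = c("beta_min", "beta_max", "n_beta", "betas", "replicates",
            "reuse_networks"),
  propagate = c("replicates", "max_steps", "extent_average"),
  percolation = c("size", "replicates"),
  optimize = c("K0", "Q0", "beta", "epsilon", "n_points")
)

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key", if (length(bad) > 1) "s", " in ", where,
         ": ", paste(bad, collapse = ", "), call. = FALSE)
}

#' @rdname load_config
#' @param config A named list with the raw configuration.
#' @export
validate_config <- function(config) {
  .check_keys(config, .config_schema$top, "top level")
  kinds <- c("theory", "build", "simulate", "sweep", "propagate",
             "intervene", "percolation", "optimize")
  if (is.null(config$experiment) || !(config$experiment %in% kinds))
    stop("`experiment` must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$output_prefix)) config$output_prefix <- config$experiment
  if (!is.null(config$model)) {
    .check_keys(config$model, .config_schema$model, "model")
    # validates L/zeta divisibility and k_intra bound, with named errors
    do.call(model_params, config$model)
  }
  if (!is.null(config$epidemic)) {
    .check_keys(config$epidemic, .config_schema$epidemic, "epidemic")
    if (is.null(config$epidemic$origin)) config$epidemic$origin <- "random"
    if (is.null(config$epidemic$max_steps))
      config$epidemic$max_steps <- 10000L
  }
  for (iv in config$interventions)
    .check_keys(iv, .config_schema$intervention, "interventions")
  for (block in c("sweep", "propagate", "percolation", "optimize"))
    if (!is.null(config[[block]]))
      .check_keys(config[[block]], .config_schema[[block]], block)
  structure(config, class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config` (or plain list) to write.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @export
save_config <- function(config, path) {
  obj <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

# FNV-1a hash of a file's bytes, as hex; used in the run manifest so that
# re-running a config can be checked for byte-reproducibility.
.file_hash <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  p <- 2147483629
  h <- 2166136261 %% p
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 4096))) {
    for (b in chunk) h <- ((h + b) * 16777619) %% p
  }
  sprintf("%08x", h)
}

#' Run a configured experiment and write its outputs
#'
#' Dispatches on `config$experiment`, writes the experiment outputs (TSV
#' network tables, CSV sweep/propagation tables, JSON summaries) next to
#' `out_dir`, and writes a manifest recording the configuration, seeds,
#' package version and output file hashes. Re-running the same
#' configuration reproduces every stochastic output byte-exactly.
#'
#' Numeric outputs are serialized with 17 significant digits.
#'
#' @param config A `run_config` from [load_config()]/[validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of output paths, invisibly.
#' @export
run_experiment <- function(config, out_dir = ".") {
  config <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(out_dir, config$output_prefix)
  seed <- as.integer(config$seed)
  paths <- character(0)
  emit_json <- function(obj, suffix) {
    p <- paste0(prefix, suffix)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    paths <<- c(paths, p)
  }
  emit_csv <- function(df, suffix) {
    p <- paste0(prefix, suffix)
    df[] <- lapply(df, function(col)
      if (is.double(col)) format(col, digits = 17, trim = TRUE) else col)
    write.table(df, p, sep = ",", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  mp <- function() do.call(model_params, config$model)

  switch(config$experiment,
    theory = {
      p <- mp()
      ts <- threshold_set(p$k_intra, p$Q)
      emit_json(unclass(ts), "_theory.json")
    },
    build = {
      net <- build_network(mp(), seed)
      paths <- c(paths, write_network(net, prefix))
      ds <- degree_summary(net)
      emit_json(list(mean_intra = ds$mean_intra, mean_inter = ds$mean_inter),
                "_degrees.json")
    },
    simulate = ,
    intervene = {
      net <- build_network(mp(), derive_seed(seed, "net"))
      ivs <- lapply(config$interventions, function(x)
        intervention(x$strategy, x$t_x, x$new_value,
                     if (is.null(x$t_q)) Inf else x$t_q))
      run <- run_sir(net, config$epidemic$beta,
                     origin = config$epidemic$origin,
                     interventions = ivs,
                     max_steps = config$epidemic$max_steps,
                     seed = derive_seed(seed, "sir"))
      p <- paste0(prefix, "_run.json")
      write_run_json(run, p)
      paths <- c(paths, p)
      emit_csv(run$recovery_events, "_recovery_events.tsv")
    },
    sweep = {
      sw <- config$sweep
      betas <- if (!is.null(sw$betas)) unlist(sw$betas)
               else seq(sw$beta_min, sw$beta_max, length.out = sw$n_beta)
      res <- beta_sweep(mp(), betas, sw$replicates, seed,
                        reuse_networks = !isFALSE(sw$reuse_networks))
      thr <- log_derivative_thresholds(res)
      emit_csv(data.frame(beta = res$beta, mean_R = res$mean_R), "_sweep.csv")
      emit_csv(thr$deriv, "_dlogR.csv")
      emit_json(list(beta1 = thr$beta1, beta2 = thr$beta2,
                     single = thr$single), "_thresholds.json")
    },
    propagate = {
      pg <- config$propagate
      curve <- propagation_curve(mp(), config$epidemic$beta,
                                 pg$replicates, seed,
                                 max_steps = if (is.null(pg$max_steps)) 1500L
                                             else pg$max_steps)
      emit_csv(data.frame(t = curve$t, rmax_mean = curve$rmax_mean,
                          n_active = curve$n_active), "_propagation.csv")
      taus <- circle_timescales(curve, curve$params$zeta)
      dmin <- tryCatch(as.numeric(fit_dmin(curve)), error = function(e) NA)
      emit_json(c(taus, list(d_min = dmin, degenerate = curve$degenerate)),
                "_propagation.json")
    },
    percolation = {
      pc <- config$percolation
      est <- estimate_pc_square(pc$size, pc$replicates, seed)
      emit_json(list(p_c_estimate = est$estimate, stderr = est$stderr,
                     replicates = est$replicates, size = est$size),
                "_percolation.json")
    },
    optimize = {
      op <- config$optimize
      pr <- strategy_problem(op$K0, op$Q0, op$beta,
                             epsilon = if (is.null(op$epsilon)) 1e-3
                                       else op$epsilon)
      res <- optimize_strategy(pr, n_points = if (is.null(op$n_points)) 200
                                              else op$n_points)
      emit_json(res[c("K_opt", "Q_opt", "W_opt", "strategy")],
                "_optimize.json")
    }
  )

  manifest <- list(
    experiment = config$experiment,
    seed = seed,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("spatialsir")),
    outputs = lapply(stats::setNames(paths, basename(paths)), .file_hash)
  )
  mpth <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(manifest, mpth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mpth))
}
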