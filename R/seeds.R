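#' Derive a child seed from a master seed and a stream tag
#'
#' Deterministic fan-out of independent random streams: network generation,
#' epidemic dynamics, quarantine edge selection and per-replicate streams are
#' all seeded from `(master, tag, index)` so that adding replicates or
#' interventions never perturbs existing streams.
#'
#' @param master Integer master seed.
#' @param tag Character stream tag (e.g. `"net"`, `"sir"`).
#' @param index Non-negative integer replicate / sub-stream index.
#' @return A positive integer seed below 2^31.
#' @examples
#' derive_seed(1L, "net", 3L)
#' @export
derive_seed <- function(master, tag, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  p <- 2147483629 # prime below 2^31
  h <- (abs(as.numeric(master)) %% p)
  for (b in utf8ToInt(paste0(tag, ":", format(index)))) {
    h <- (h * 131 + b) %% p # h*131 < 2^53, exact in double
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
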