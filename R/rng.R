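# Seed handling: one root seed spawns independent named streams so that
# textures, trajectories and spiking noise can be regenerated independently.

#' Derive a named sub-seed from a root seed
#'
#' Deterministically maps a (seed, stream-name) pair to a new seed below
#' 2^31, so that independent stimulus/noise components can each own a
#' reproducible stream.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name (e.g. `"trajectory"`, `"spikes"`), or
#'   an integer index.
#' @return A single integer seed in \[0, 2^31).
#' @examples
#' derive_seed(1, "trajectory")
#' @export
derive_seed <- function(seed, stream) {
  if (is.character(stream)) {
    stream <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  }
  # splitmix-style integer scramble in double precision (exact below 2^53)
  m <- 2147483647  # 2^31 - 1
  x <- (as.numeric(seed) %% m) + 1
  y <- (as.numeric(stream) %% m) + 1
  v <- (x * 48271 + y * 69621 + 12345) %% m
  v <- (v * 16807 + 1) %% m
  as.integer(v)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
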