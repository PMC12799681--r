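# Seed plumbing: every stochastic operation takes an explicit seed, runs in
# a locally scoped RNG state, and restores the caller's state afterwards.

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic per-stream seed
#'
#' Mixes a top-level seed with a stream identifier (e.g. a tracer id) so
#' each tracer gets its own reproducible random stream: adding or removing
#' one tracer never perturbs another's results. Arithmetic stays within
#' exact double-precision integers and the result is below 2^31.
#'
#' @param seed top-level integer seed.
#' @param id character stream identifier.
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, id) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (b in utf8ToInt(as.character(id)))
    h <- (h * 31 + b) %% m
  as.integer(h %% (m - 1) + 1)
}
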