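# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without clobbering the caller's RNG
# state.  All user-facing stochastic functions take an explicit `seed`
# argument and route through this, so there is no hidden global state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical id for an unordered taxon pair, e.g. topology_id("B","A") == "A|B".
topology_id <- function(x, y) {
  paste(sort(c(x, y)), collapse = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
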