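`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG
# stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Small stable polynomial hash of a configuration list, for replayable output
# metadata.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
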