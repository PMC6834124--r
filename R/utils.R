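# Small internal utilities.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
# All generator randomness goes through this so fixtures are pure
# functions of (seed, params).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# md5 of a file; empty string when missing
file_md5 <- function(path) {
  if (is.null(path) || !file.exists(path)) return("")
  unname(tools::md5sum(path))
}
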