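# Internal helpers shared across modules.

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never clobber the
# session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# One RNG stream per pipeline stage, derived from the master seed so stages
# can be re-run independently. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(taxonomy = 11L, proteomes = 23L, metadata = 37L, msa = 53L,
               terms = 71L, patterns = 89L, enrichment = 97L, misc = 113L)
  off <- offsets[[stage]] %||% 127L
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
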