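# internal helpers shared across modules

#' @keywords internal
#' @noRd
md5_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeBin(charToRaw(enc2utf8(x)), tf)
  unname(tools::md5sum(tf))
}

# Deterministic 31-bit integer derived from a string; used to give each
# (prompt, seed) pair its own RNG stream without touching the global state.
#' @keywords internal
#' @noRd
string_seed <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Run `expr` under a local RNG seeded by `seed`, restoring the caller's
# .Random.seed afterwards so library code never perturbs user simulations.
#' @keywords internal
#' @noRd
with_local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
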