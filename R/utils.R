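# Internal helpers shared across modules.

# Deterministic polynomial hash of an integer vector onto [1, 2^31 - 2].
# Exact in double arithmetic: intermediate values stay below 2^31 * 131 < 2^53.
hash_ints <- function(v) {
  acc <- 7
  for (x in v) acc <- (acc * 131 + (x %% 2147483647)) %% 2147483647
  acc + 1
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  hash_ints(c(seed, utf8ToInt(as.character(stream))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x) && x >= 1

assert_simmat <- function(sim) {
  if (!is.matrix(sim) || !is.numeric(sim)) {
    stopf("similarity matrix must be a numeric matrix")
  }
  if (nrow(sim) != ncol(sim)) stopf("similarity matrix must be square")
  if (is.null(rownames(sim)) || is.null(colnames(sim))) {
    stopf("similarity matrix must carry compound ids as dimnames")
  }
  if (!identical(rownames(sim), colnames(sim))) {
    stopf("similarity matrix row and column ids differ")
  }
  if (anyNA(sim) || any(sim < -1e-9) || any(sim > 1 + 1e-9)) {
    stopf("similarity values must lie in [0, 1]")
  }
  if (max(abs(sim - t(sim))) > 1e-9) stopf("similarity matrix must be symmetric")
  if (max(abs(diag(sim) - 1)) > 1e-9) stopf("similarity matrix diagonal must be 1")
  invisible(sim)
}
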