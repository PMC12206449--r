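#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Stable polynomial string hash, exact in double arithmetic (modulus < 2^26 so
# intermediate products stay below 2^53). Used to derive reproducible seeds
# from strings across processes; not cryptographic.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  p <- 67108859 # largest prime < 2^26
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% p
  as.integer(h)
}

# Derive a child seed from a parent seed and a string tag, kept < 2^31 - 1.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 2654435 + stable_hash(tag)) %% 2147483647L)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Order-stable checksum of a numeric vector/array (content equality check for
# freezing contracts). Sums position-weighted values so permutations differ.
param_checksum <- function(x) {
  v <- as.numeric(x)
  sum(v * seq_along(v)) + sum(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_mt <- function(msg, class) {
  rlang::abort(msg, class = c(class, "methtransfer_error"))
}
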