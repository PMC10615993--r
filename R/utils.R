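# Internal helpers: deterministic hashing and RNG isolation.
#
# All synthetic backends must be bit-reproducible given a user seed and must
# not disturb the caller's RNG stream.  We therefore hash strings to 31-bit
# integers, mix them with the user seed, and draw from a locally scoped RNG.

# 31-bit FNV-style rolling hash of a UTF-8 string; always in [0, 2^31 - 1].
hash31 <- function(x) {
  codes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (cc in codes) {
    h <- (h * 16777619 + cc) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

# Mix a string hash with a user seed into a valid set.seed() argument.
mix_seed <- function(key, seed) {
  as.integer((hash31(key) + (as.double(seed) %% 2147483647) * 69069) %% 2147483647)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards (or leaving it unset if it was unset).
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Unit-normalize the rows of a matrix; errors on zero rows unless drop = TRUE.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(!is.finite(nrm)) || any(nrm == 0)) {
    stop("embedding matrix contains non-finite or zero-norm rows", call. = FALSE)
  }
  m / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
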