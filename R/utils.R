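# Internal helpers: deterministic string hashing (used by the surrogate
# presenter and by per-cell seed derivation) and small numeric utilities.

# Modulus chosen < 2^26 so all intermediate products stay below 2^53 and are
# exact in double arithmetic.
.HASH_MOD <- 67108859

.hash_env <- new.env(parent = emptyenv())

.pow131 <- function(n) {
  p <- .hash_env$pows
  if (is.null(p) || length(p) < n) {
    m <- max(n, 64L)
    p <- numeric(m)
    p[1] <- 1
    for (i in seq_len(m - 1L)) p[i + 1L] <- (p[i] * 131) %% .HASH_MOD
    .hash_env$pows <- p
  }
  rev(.hash_env$pows[seq_len(n)])
}

# Polynomial rolling hash of each string, mod .HASH_MOD. Pure function of the
# character content; no RNG involved.
str_hash <- function(x) {
  vapply(x, function(s) {
    v <- utf8ToInt(s)
    n <- length(v)
    if (n == 0L) return(0)
    sum((v * .pow131(n)) %% .HASH_MOD) %% .HASH_MOD
  }, numeric(1), USE.NAMES = FALSE)
}

# Mix two hashes into a unit-interval value. Two multiply-add rounds mod a
# prime give adequate equidistribution for the presenter's accept decisions.
hash_unit <- function(h1, h2) {
  x <- (h1 * 40503 + h2 * 69621 + 11) %% .HASH_MOD
  x <- (x * 48271 + 17) %% .HASH_MOD
  x / .HASH_MOD
}

# Deterministic 32-bit-safe seed from a key string.
seed_from_key <- function(key) {
  as.integer(str_hash(key) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lower-middle median: for even n the lower of the two central order
# statistics. Keeps integer scores integer.
median_low <- function(x) {
  x <- sort(x)
  x[[(length(x) + 1L) %/% 2L]]
}

# Centered moving average with a truncated (shrinking) window at the edges.
smooth_truncated <- function(x, halfwidth) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - halfwidth):min(n, i + halfwidth)])
  }, numeric(1))
}

# Standard deviation that is 0 (not NA) for a single observation.
sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
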