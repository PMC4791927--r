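# Bloom filters for memoryless deduplication of canonical SMILES streams.
# Sizing follows the standard closed forms: b = -n ln p / (ln 2)^2 bits and
# h = b ln 2 / n hash functions. Hashing uses two independent polynomial
# string hashes combined by double hashing into h bit positions; a filter
# never yields a false negative, and its false-positive rate is controlled
# by the design p.

#' Required Bloom filter size in bits
#'
#' @param n expected number of insertions (>= 1).
#' @param p target false-positive rate, 0 < p < 1.
#' @return Number of bits, `ceiling(-n * ln(p) / ln(2)^2)`.
#' @export
required_bits <- function(n, p) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(p) || p <= 0 || p >= 1) {
    stop("false-positive rate p must lie in (0, 1)", call. = FALSE)
  }
  ceiling(-n * log(p) / log(2)^2)
}

#' Optimal number of hash functions
#'
#' @param b filter size in bits.
#' @param n expected insertions.
#' @return `round(b * ln 2 / n)`, at least 1.
#' @export
optimal_hashes <- function(b, n) {
  if (b < 1 || n < 1) stop("b and n must be >= 1", call. = FALSE)
  max(1L, as.integer(round(b * log(2) / n)))
}

#' Predicted false-positive rate of a Bloom filter
#'
#' @param b filter size in bits.
#' @param h number of hash functions.
#' @param n number of inserted elements.
#' @return `(1 - exp(-n h / b))^h` (0 for an empty filter).
#' @export
fp_rate <- function(b, h, n) {
  if (n == 0) return(0)
  (1 - exp(-n * h / b))^h
}

.HASH_M1 <- 2147483629
.HASH_M2 <- 2147483587
.HASH_B1 <- 131
.HASH_B2 <- 137

#' @noRd
hash_powers <- function(base, mod, len, cache) {
  nm <- paste0("p", base)
  pw <- cache[[nm]]
  if (is.null(pw) || length(pw) < len) {
    pw <- numeric(max(len, 64L))
    pw[1] <- 1
    for (k in seq_len(length(pw) - 1L)) pw[k + 1L] <- (pw[k] * base) %% mod
    cache[[nm]] <- pw
  }
  pw
}

#' @noRd
string_hashes <- function(key, cache) {
  bytes <- utf8ToInt(key)
  L <- length(bytes)
  if (L == 0L) return(c(0, 1))
  p1 <- hash_powers(.HASH_B1, .HASH_M1, L, cache)
  p2 <- hash_powers(.HASH_B2, .HASH_M2, L, cache)
  h1 <- sum(bytes * p1[L:1]) %% .HASH_M1
  h2 <- sum(bytes * p2[L:1]) %% .HASH_M2
  if (h2 == 0) h2 <- 1
  c(h1, h2)
}

#' Create a Bloom filter
#'
#' Sized by [required_bits()] and [optimal_hashes()] for `n` expected
#' insertions at target false-positive rate `p`.
#'
#' @param n expected insertions.
#' @param p target false-positive rate.
#' @return A `bloom_filter` (mutable environment with fields `b`, `h`, `n`,
#'   `p`, `bits`, `inserted`).
#' @export
bloom_filter <- function(n = 1e7, p = 0.01) {
  b <- required_bits(n, p)
  h <- optimal_hashes(b, n)
  env <- new.env(parent = emptyenv())
  env$b <- b
  env$h <- h
  env$n <- n
  env$p <- p
  env$inserted <- 0
  env$bits <- raw(ceiling(b / 8))
  env$cache <- new.env(parent = emptyenv())
  class(env) <- "bloom_filter"
  env
}

#' @export
print.bloom_filter <- function(x, ...) {
  cat(sprintf("<bloom_filter> b=%g bits, h=%d hashes, %g inserted (design n=%g, p=%g)\n",
              x$b, x$h, x$inserted, x$n, x$p))
  invisible(x)
}

#' @noRd
bloom_positions <- function(filter, key) {
  hh <- string_hashes(key, filter$cache)
  idx0 <- (hh[1] + (0:(filter$h - 1L)) * hh[2]) %% filter$b
  list(byte = idx0 %/% 8 + 1, bit = idx0 %% 8)
}

#' Add a key to a Bloom filter
#'
#' @param filter a `bloom_filter`.
#' @param key character key (canonical SMILES).
#' @return The filter, invisibly (modified in place).
#' @export
bloom_add <- function(filter, key) {
  pos <- bloom_positions(filter, key)
  # two hash positions can land in the same byte; fold masks per byte
  masks <- tapply(bitwShiftL(1L, pos$bit), pos$byte,
                  function(m) Reduce(bitwOr, m))
  bytes <- as.numeric(names(masks))
  cur <- as.integer(filter$bits[bytes])
  filter$bits[bytes] <- as.raw(bitwOr(cur, as.integer(masks)))
  filter$inserted <- filter$inserted + 1
  invisible(filter)
}

#' Query a Bloom filter
#'
#' Always TRUE for a key that was added (no false negatives); FALSE for an
#' absent key except with probability about the design false-positive rate.
#'
#' @param filter a `bloom_filter`.
#' @param key character key.
#' @return logical.
#' @export
bloom_query <- function(filter, key) {
  pos <- bloom_positions(filter, key)
  cur <- as.integer(filter$bits[pos$byte])
  all(bitwAnd(cur, bitwShiftL(1L, pos$bit)) > 0L)
}

#' Create the filter set used during synthesis
#'
#' One global filter F plus one filter per level, all sized identically.
#'
#' @param levels number of levels (MAX).
#' @param n expected insertions per filter.
#' @param p target false-positive rate.
#' @return A `bloom_filter_set`.
#' @export
bloom_filter_set <- function(levels, n = 1e7, p = 0.01) {
  env <- new.env(parent = emptyenv())
  env$global <- bloom_filter(n, p)
  env$level <- lapply(seq_len(levels), function(l) bloom_filter(n, p))
  class(env) <- "bloom_filter_set"
  env
}

#' Accept or reject a synthesized molecule key
#'
#' Accepts the key only if it is new to both the level filter and the global
#' filter; recording in both ensures that molecules with the same SMILES but
#' different fragment counts are filtered as redundant across levels.
#'
#' @param filters a `bloom_filter_set`.
#' @param level synthesis level of the candidate.
#' @param key canonical SMILES key.
#' @return TRUE if the key is new (and now recorded), FALSE otherwise.
#' @export
accept_molecule <- function(filters, level, key) {
  if (level < 1L || level > length(filters$level)) {
    stop("no filter for level ", level, call. = FALSE)
  }
  fl <- filters$level[[level]]
  if (bloom_query(fl, key)) return(FALSE)
  bloom_add(fl, key)
  if (bloom_query(filters$global, key)) return(FALSE)
  bloom_add(filters$global, key)
  TRUE
}
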