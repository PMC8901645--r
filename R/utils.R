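# Internal helpers: stable content hashing, seed derivation, numeric utilities.

# 32-bit FNV-1a over the UTF-8 bytes of a character scalar. R has no native
# 32-bit unsigned arithmetic, so the modular multiply is done in two 16-bit
# halves. Used for vocabulary / grouper / config fingerprints in manifests
# and checkpoints; stability across sessions matters, cryptographic strength
# does not.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)), sprintf("%04x", as.integer(h %% 65536)))
}

# xor for numerics held as 0..2^32-1
bitwXor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

# (a * b) mod 2^32 without exceeding double precision
mulmod32 <- function(a, b) {
  a_lo <- a %% 65536
  a_hi <- a %/% 65536
  # b fits in 25 bits (FNV prime), so a_lo * b < 2^41: exact in doubles
  hi_part <- (((a_hi * b) %% 65536) * 65536) %% 4294967296
  (hi_part + a_lo * b) %% 4294967296
}

#' Derive per-component seeds from one master seed
#'
#' Fans a single master seed out into reproducible, distinct sub-seeds for
#' the independent sources of randomness in a run (simulation, splits,
#' parameter initialisation, shuffling, ...). The derivation is counter-based
#' on the component name, so adding a new component never shifts the seeds of
#' existing ones.
#'
#' @param master_seed Integer master seed.
#' @param components Character vector of component names.
#' @return Named integer vector of seeds, all in `[0, 2^31)`.
#' @examples
#' seed_everything(42, c("simulate", "init", "shuffle"))
#' @export
seed_everything <- function(master_seed,
                            components = c("simulate", "split", "init",
                                           "shuffle", "cohort", "dropout")) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  master_seed <- as.integer(master_seed)
  vapply(components, function(nm) {
    h <- strtoi(substr(fnv1a32(paste0(nm, ":", master_seed)), 1, 7), 16L)
    as.integer(h %% 2147483647)
  }, integer(1))
}

# row-wise maximum, C-fast via max.col (rows must hold at least one finite
# value; masked -Inf entries are never the max of a valid row)
row_max <- function(m) {
  n <- nrow(m)
  m[(max.col(m, ties.method = "first") - 1L) * n + seq_len(n)]
}

# numerically stable row-wise log-softmax of a matrix
row_log_softmax <- function(m) {
  z <- m - row_max(m)
  z - log(rowSums(exp(z)))
}

# row-wise softmax; rows may contain -Inf (masked), never all -Inf
row_softmax <- function(m) {
  e <- exp(m - row_max(m))
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

days_to_date <- function(d) as.Date(d, origin = "1970-01-01")
date_to_days <- function(s) as.integer(as.Date(s))
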