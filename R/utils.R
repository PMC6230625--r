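#' @useDynLib strandmeth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, done in doubles with 16-bit
# splits so the multiplication stays exact.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(x)) {
    h <- (h %/% 1) ; h <- bitwXorDouble(h, b %% 256)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * p) %% 4294967296 + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

# xor of two non-negative doubles < 2^32 (bitwXor only takes 31-bit ints)
bitwXorDouble <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Group-level streams (one per donor/population/region/strand combination)
#' are derived by stable hashing so that adding or reordering groups never
#' perturbs another group's draws. The result is always a valid 31-bit seed.
#'
#' @param master integer master seed.
#' @param key character scalar identifying the stream.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- fnv1a32(key)
  as.integer((h + abs(master)) %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# validate a nucleotide string; returns uppercase string or stops naming the
# first offending position
check_nucleotides <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad != -1L) {
    stop(sprintf("invalid character '%s' in %s at position %d",
                 substr(seq, bad, bad), what, bad), call. = FALSE)
  }
  seq
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]
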