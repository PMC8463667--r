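## Internal helpers shared across modules.

# 1-based wrap of coordinates onto a circle of length n
wrap1 <- function(pos, n) ((pos - 1L) %% n) + 1L

#' Derive a reproducible stream seed
#'
#' Hashes a global seed together with a stage label and replicate index into
#' an integer seed, so that every stochastic stage of a pipeline run gets an
#' independent, reproducible RNG stream without relying on hidden global
#' state. Uses a 32-bit FNV-1a hash reduced modulo 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. "reads", "dpcr").
#' @param index Integer replicate index (default 1).
#' @return A single integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage, index = 1L) {
  key <- paste(as.integer(seed), stage, as.integer(index), sep = "/")
  as.integer(fnv32(utf8ToInt(key)) %% 2147483647)
}

# 32-bit FNV-1a over a byte vector, in double arithmetic (bitwXor on
# 16-bit halves to stay inside R's integer range)
fnv32 <- function(bytes) {
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    h <- (h %/% 65536) * 65536 + lo
    h <- (h * 16777619) %% 4294967296
  }
  h
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# parse a vector of CIGAR strings into per-record op/length lists
parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  lapply(ops, function(x) {
    if (length(x) == 0L) stop("malformed CIGAR string")
    list(len = as.integer(sub("[MIDNSHP=X]$", "", x)),
         op = sub("^\\d+", "", x))
  })
}

# stable content hash of an R object (serialized to canonical text)
fnv_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- fnv32(utf8ToInt(txt))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
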