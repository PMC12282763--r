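#' @importFrom stats rbinom runif rbeta qbeta pbeta fisher.test predict
#'   setNames median var rnorm rpois rexp
#' @importFrom utils read.delim write.table
NULL

# data.table syntax is used through the data.table:: prefix
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `expr`, and restores the previous state, so package functions are
#' deterministic given their `seed` argument without disturbing the session
#' RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# 32-bit FNV-1a over a character scalar; used to freeze the feature schema.
# (A cryptographic digest is unnecessary: the hash only guards against
# accidental train/predict schema drift.)
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); h is kept as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    # h * 16777619 mod 2^32, split to avoid double-precision loss
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

schema_hash <- function(feature_names) {
  fnv1a32(paste(feature_names, collapse = "|"))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
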