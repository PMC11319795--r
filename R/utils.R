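#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test sd var rnorm runif rbinom aov anova lm
#'   residuals pnorm pt qf dhyper setNames qnorm aggregate median
#' @importFrom utils write.csv read.csv packageVersion head combn
NULL

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stream label,
# so independent pipeline stages never share an RNG stream.
derive_seed <- function(seed, label) {
  h <- fnv1a32(paste0(label, ":", as.integer(seed)))
  as.integer(h %% 2147483647)
}

# FNV-1a 32-bit hash of a character string, kept in double arithmetic
# (exact below 2^53).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # bitwXor works on 32-bit ints; keep values in [0, 2^32) via split
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a %/% 65536) %% 65536, (b %/% 65536) %% 65536)
  hi * 65536 + lo
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x) && x >= 0
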