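#' @importFrom rlang %||% abort warn .data
#' @importFrom stats sd median quantile complete.cases pf pt qt t.test
#'   rnorm rlnorm rbinom runif prcomp loess predict hclust dist cutree
#'   lm coef confint model.matrix plogis as.formula var setNames na.omit
#' @importFrom utils head tail
NULL

# Deterministic 32-bit FNV-1a hash of a string; used to derive per-stream
# seeds and config digests without external dependencies.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(as.character(x))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h as a double since it
    # exceeds the integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit multiply by 16777619 with overflow; split into 16-bit halves so
    # every intermediate stays exactly representable in a double
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' streams, so individual stages can be re-run independently and still be
#' reproducible. The derived seed is always a valid R integer (< 2^31).
#'
#' @param seed Master integer seed.
#' @param stream Character stream name (e.g. `"cohort"`, `"acquisition"`).
#' @return An integer seed.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  as.integer((abs(seed) + fnv1a32(stream)) %% 2147483647)
}

# Evaluate `expr` with the RNG seeded from (seed, stream), restoring the
# caller's RNG state afterwards.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# Coefficient of variation in percent; sample sd.
cov_pct <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || mean(x) == 0) return(NA_real_)
  100 * sd(x) / mean(x)
}

# Geometric-style half-minimum imputation used immediately before
# log-transformation: zeros/missings replaced by half the smallest positive
# value of that species.
impute_half_min <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  if (length(pos) == 0L) return(x)
  fill <- min(pos) / 2
  x[!is.finite(x) | x <= 0] <- fill
  x
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
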