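# Internal numeric and RNG helpers shared across modules.

#' Numerically stable log-sum-exp
#'
#' Computes `log(sum(exp(x)))` without overflow or underflow by factoring out
#' the maximum term.
#'
#' @param x Numeric vector of log-scale values (at least one finite).
#' @return A length-one numeric.
#' @keywords internal
log_sum_exp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("log_sum_exp: empty input")
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (or an Inf dominates)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp over the columns of a matrix.
row_log_sum_exp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = TRUE)))
  out <- mx + log(rowSums(exp(m - mx)))
  # rows that are entirely -Inf
  out[!is.finite(mx)] <- -Inf
  out
}

#' Derive a per-operation random seed
#'
#' Combines a user seed with a short operation tag so that each generator in
#' the package draws from its own stream: adding a call to one generator never
#' shifts the output of another run under the same seed.
#'
#' @param seed Integer base seed.
#' @param tag Character operation tag.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, tag) {
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 2654435 + h) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded from (seed, tag), restoring
# the caller's RNG state afterwards.
with_stream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, tag))
  expr
}

# Format x as a base-10 mantissa/exponent pair from its natural log.
# Returns list(mantissa, exponent) with 1 <= |mantissa| < 10.
ln_to_mantissa_exp <- function(ln_x) {
  if (!is.finite(ln_x)) return(list(mantissa = exp(ln_x), exponent = 0L))
  log10x <- ln_x / log(10)
  e <- floor(log10x)
  list(mantissa = 10^(log10x - e), exponent = as.integer(e))
}
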