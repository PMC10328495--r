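# Size-corrected Akaike information criterion model comparison.
#
# All functions are vectorised over models; `aic_compare()` assembles the
# full comparison table (AIC, AICc, delta AICc, Akaike weight) from per-model
# maximum-likelihood fit summaries.

#' Akaike information criterion
#'
#' `AIC = -2 logL + 2K`.
#'
#' @param log_likelihood Maximised log-likelihood(s).
#' @param n_params Number of free parameters `K`.
#' @return Numeric vector of AIC values.
#' @export
aic <- function(log_likelihood, n_params) {
  -2 * log_likelihood + 2 * n_params
}

#' Size-corrected Akaike information criterion
#'
#' `AICc = AIC + 2K(K+1)/(n - K - 1)`, the small-sample correction used when
#' the number of characters `n` is small relative to `K` (see
#' [small_sample_flag()]).
#'
#' @inheritParams aic
#' @param n_sites Sample size (alignment length) `n`; must exceed `K + 1`.
#' @return Numeric vector of AICc values.
#' @export
aicc <- function(log_likelihood, n_params, n_sites) {
  if (any(n_sites <= n_params + 1)) {
    stop("AICc undefined: need n > K + 1 (got n = ",
         paste(n_sites[n_sites <= n_params + 1], collapse = ", "),
         " with K = ",
         paste(n_params[n_sites <= n_params + 1], collapse = ", "), ")")
  }
  aic(log_likelihood, n_params) +
    2 * n_params * (n_params + 1) / (n_sites - n_params - 1)
}

#' Should the size-corrected criterion be reported?
#'
#' Flags fits where `n / K < 40`, the conventional threshold below which AICc
#' rather than AIC is reported.
#'
#' @param n_params Number of free parameters `K` (> 0).
#' @param n_sites Sample size `n`.
#' @return Logical vector.
#' @export
small_sample_flag <- function(n_params, n_sites) {
  if (any(n_params <= 0)) stop("n_params must be positive")
  n_sites / n_params < 40
}

#' Akaike weights from delta-AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`, computed in log space
#' so that very large deltas (likelihood-unit gaps in the hundreds) underflow
#' gracefully instead of producing 0/0.
#'
#' @param delta Numeric vector of AICc (or AIC) differences from the best
#'   model; any common constant cancels, so raw AICc values work too.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' akaike_weights(c(11.41, 0))   # -> 0.003 / 0.997
#' @export
akaike_weights <- function(delta) {
  if (!length(delta)) stop("no models supplied")
  lw <- -delta / 2
  exp(lw - log_sum_exp(lw))
}

#' Model comparison table from maximum-likelihood fit summaries
#'
#' Builds the standard information-criterion comparison: AIC, AICc, delta
#' AICc relative to the best model, Akaike weights, and the `n/K < 40`
#' small-sample flag. `K` and `n` are caller-supplied (read from the fit
#' summaries of the external ML program); they are never inferred from model
#' names.
#'
#' @param fits A data frame with columns `model`, `logL`, `K`, `n` and
#'   optionally `characters` (a data-set label carried through).
#' @return A data frame of class `"aic_comparison"` with the input columns
#'   plus `AIC`, `AICc`, `delta_AICc`, `weight`, `small_sample`, `best`;
#'   attribute `best_model` names the minimum-AICc model.
#' @export
aic_compare <- function(fits) {
  need <- c("model", "logL", "K", "n")
  miss <- setdiff(need, names(fits))
  if (length(miss)) stop("fits table lacks column(s): ",
                         paste(miss, collapse = ", "))
  out <- as.data.frame(fits)
  out$AIC <- aic(out$logL, out$K)
  out$AICc <- aicc(out$logL, out$K, out$n)
  out$delta_AICc <- out$AICc - min(out$AICc)
  out$weight <- akaike_weights(out$delta_AICc)
  out$small_sample <- small_sample_flag(out$K, out$n)
  out$best <- out$AICc == min(out$AICc)
  attr(out, "best_model") <- out$model[which.min(out$AICc)]
  class(out) <- c("aic_comparison", class(out))
  out
}

#' Read a model-fit summary table
#'
#' @param path TSV file with columns `model`, `logL`, `K`, `n` and optional
#'   `characters`.
#' @return A data frame suitable for [aic_compare()].
#' @export
read_model_fits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("model", "logL", "K", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fits file lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Write a comparison table as TSV
#'
#' Emits display columns at conventional precisions (log-likelihood and
#' criteria to 2 decimals, weights to 3) alongside full-precision values.
#'
#' @param comparison Output of [aic_compare()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aic_table <- function(comparison, path) {
  df <- as.data.frame(comparison)
  df$weight_display <- sprintf("%.3f", df$weight)
  df$delta_AICc_display <- sprintf("%.2f", df$delta_AICc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
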