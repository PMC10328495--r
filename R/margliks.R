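# Aggregation of per-run stepping-stone log marginal likelihoods, Bayes
# factors, and their interpretation on the standard evidence scale.

#' Combine per-run log marginal likelihoods
#'
#' Runs estimate the same marginal likelihood, so they are averaged on the
#' likelihood scale: the combined value is `ln((1/R) * sum(exp(v_r)))`,
#' i.e. a log-mean-exp, computed stably relative to the largest run. Note
#' this is *not* the arithmetic mean of the log values: when runs disagree
#' the largest run dominates, and the combined value always lies in
#' `[max(v) - ln(R), max(v)]`.
#'
#' @param values Numeric vector of per-run log marginal likelihoods (>= 1
#'   finite value).
#' @return Length-one numeric.
#' @examples
#' combine_log_marginals(c(-36376.42, -36352.75))  # -36353.44
#' @export
combine_log_marginals <- function(values) {
  if (!length(values)) stop("no run values supplied")
  if (any(!is.finite(values))) stop("non-finite log marginal likelihood")
  log_sum_exp(values) - log(length(values))
}

#' Interpret a log Bayes factor on the standard evidence scale
#'
#' Bands `2 ln(BF)` as: 0-2 negligible, 2-6 positive, 6-10 strong, >10 very
#' strong; mirrored for negative values as evidence *against* the first
#' model. Band edges belong to the stronger category.
#'
#' @param ln_bf Natural-log Bayes factor of model 0 versus model 1.
#' @return A character label, e.g. `"strong (against M0)"`.
#' @export
interpret_evidence <- function(ln_bf) {
  two <- 2 * abs(ln_bf)
  band <- if (two < 2) "negligible"
  else if (two < 6) "positive"
  else if (two < 10) "strong"
  else "very strong"
  if (band == "negligible") return(band)
  paste0(band, if (ln_bf < 0) " (against M0)" else " (for M0)")
}

#' Bayes factor from two log marginal likelihoods
#'
#' `BF = exp(ln P(X|M0) - ln P(X|M1))`. Because real comparisons routinely
#' produce |ln BF| far beyond the range of double-precision `exp()`, the
#' result is carried in log space and additionally reported as a base-10
#' mantissa/exponent pair, so values like 3.5e-94 survive serialisation.
#'
#' @param ln_ml_m0,ln_ml_m1 Log marginal likelihoods of the two models.
#' @return An object of class `"bayes_factor"`: list with `ln_bf`, `bf`
#'   (numeric; 0 or Inf only when truly unrepresentable), `log10_bf`,
#'   `mantissa`, `exponent` and `category`.
#' @examples
#' bayes_factor(-36353.44, -36138.25)  # BF ~ 3.5e-94
#' @export
bayes_factor <- function(ln_ml_m0, ln_ml_m1) {
  stopifnot(is.finite(ln_ml_m0), is.finite(ln_ml_m1))
  ln_bf <- ln_ml_m0 - ln_ml_m1
  me <- ln_to_mantissa_exp(ln_bf)
  structure(list(ln_bf = ln_bf,
                 bf = exp(ln_bf),
                 log10_bf = ln_bf / log(10),
                 mantissa = me$mantissa,
                 exponent = me$exponent,
                 category = interpret_evidence(ln_bf)),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("BF = %.2fe%+d (ln BF = %.2f): %s\n",
              x$mantissa, x$exponent, x$ln_bf, x$category))
  invisible(x)
}

#' Read a per-run marginal-likelihood table
#'
#' @param path TSV file with columns `model`, `run_id`, `log_marginal`.
#' @return A data frame.
#' @export
read_marginal_runs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("model", "run_id", "log_marginal"), names(df))
  if (length(miss)) stop("runs file lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Marginal-likelihood summary and Bayes factor for two models
#'
#' Combines each model's runs with [combine_log_marginals()] and computes the
#' Bayes factor of the first model (M0) over the second (M1).
#'
#' @param runs Data frame with columns `model`, `run_id`, `log_marginal`
#'   containing exactly two models.
#' @param m0 Optional name of the model to treat as M0; defaults to the first
#'   model in order of appearance.
#' @return A list with `summary` (per-model data frame: model, n_runs,
#'   combined log marginal) and `bayes_factor` (a `"bayes_factor"`).
#' @export
marginal_summary <- function(runs, m0 = NULL) {
  models <- unique(runs$model)
  if (length(models) != 2L) {
    stop("need exactly 2 models, got ", length(models))
  }
  if (is.null(m0)) m0 <- models[1]
  if (!m0 %in% models) stop("model '", m0, "' not present")
  m1 <- setdiff(models, m0)
  comb <- vapply(models, function(m) {
    combine_log_marginals(runs$log_marginal[runs$model == m])
  }, numeric(1))
  nruns <- vapply(models, function(m) sum(runs$model == m), integer(1))
  list(summary = data.frame(model = models, n_runs = nruns,
                            combined_log_marginal = comb,
                            row.names = NULL),
       bayes_factor = bayes_factor(comb[[m0]], comb[[m1]]))
}
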