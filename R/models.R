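# Amino-acid substitution models: LG exchangeabilities, stationary
# frequencies, discrete-gamma rate heterogeneity and an invariant-site
# class; rate-matrix construction and transition probabilities.

# Canonical one-letter amino-acid order (PAML convention), used everywhere.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Characters treated as missing data in alignments.
AA_MISSING <- c("-", ".", "?", "X", "B", "Z", "*", "U", "O", "J")

#' Read an exchangeability matrix in the published PAML text layout
#'
#' The layout is 19 lines holding the lower triangle of the symmetric
#' exchangeability matrix (amino acids in A R N D C Q E G H I L K M F P S T
#' W Y V order), a blank line, then the 20 stationary frequencies.
#'
#' @param path Path to the matrix file; defaults to the LG matrix bundled
#'   with the package.
#' @return A list with `rates` (symmetric 20x20, zero diagonal, dimnames set)
#'   and `freqs` (named, summing to 1).
#' @export
read_paml_matrix <- function(path = system.file("extdata", "lg.dat",
                                                package = "cladetest")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 20L) stop("matrix file too short: ", path)
  vals <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (i in 2:20) {
    row <- vals[[i - 1L]]
    if (length(row) != i - 1L) stop("bad triangle row ", i - 1L, " in ", path)
    m[i, 1:(i - 1L)] <- row
  }
  m <- m + t(m)
  freqs <- vals[[20L]]
  if (length(freqs) != 20L) stop("expected 20 frequencies in ", path)
  freqs <- freqs / sum(freqs)
  names(freqs) <- AA_ALPHABET
  list(rates = m, freqs = freqs)
}

#' Construct an amino-acid substitution model
#'
#' Bundles exchangeabilities, stationary frequencies, discrete-gamma rate
#' heterogeneity (equal-probability categories with mean category rates) and
#' an optional invariant-site class.
#'
#' @param rates Symmetric 20x20 non-negative exchangeability matrix with zero
#'   diagonal (dimnames in the canonical amino-acid order).
#' @param freqs 20 stationary frequencies summing to 1.
#' @param gamma_shape Gamma shape `alpha` (> 0) or `NULL` for rate
#'   homogeneity.
#' @param n_categories Number of discrete gamma categories (default 4).
#' @param p_invariant Proportion of invariant sites in `[0, 1)`.
#' @param plus_f Logical: were the frequencies taken from observed alignment
#'   counts (+F) rather than the published model values? Informational; used
#'   by the parameter-count accounting.
#' @param renormalize_inv Logical. When `TRUE`, variable-site rates are
#'   multiplied by `1/(1 - p_invariant)` so the expected rate over all sites
#'   stays 1 (the convention of some ML programs). The default `FALSE`
#'   leaves category rates untouched and uses mixture weights
#'   `(1 - p_inv)/n_cat` and `p_inv` directly.
#' @param name Model label.
#' @return An object of class `"subst_model"`.
#' @export
subst_model <- function(rates, freqs, gamma_shape = NULL, n_categories = 4L,
                        p_invariant = 0, plus_f = FALSE,
                        renormalize_inv = FALSE, name = "custom") {
  stopifnot(is.matrix(rates), all(dim(rates) == 20L))
  if (max(abs(rates - t(rates))) > 1e-9) stop("exchangeabilities not symmetric")
  if (any(diag(rates) != 0)) stop("exchangeability diagonal must be zero")
  if (any(rates < 0)) stop("negative exchangeability")
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  freqs <- freqs / sum(freqs)
  if (!is.null(gamma_shape) && gamma_shape <= 0) stop("gamma_shape must be > 0")
  if (p_invariant < 0 || p_invariant >= 1) stop("p_invariant must be in [0, 1)")
  structure(list(name = name, rates = rates,
                 freqs = stats::setNames(as.numeric(freqs), AA_ALPHABET),
                 gamma_shape = gamma_shape,
                 n_categories = if (is.null(gamma_shape)) 1L
                                else as.integer(n_categories),
                 p_invariant = p_invariant, plus_f = plus_f,
                 renormalize_inv = renormalize_inv),
            class = "subst_model")
}

#' The LG model, optionally with +G, +I and +F
#'
#' Convenience constructor over the bundled LG matrix. With `frequencies`
#' supplied (or computed from an alignment via [empirical_aa_freqs()]) the
#' model becomes LG+F.
#'
#' @param gamma_shape Gamma shape (default 1 gives moderate heterogeneity);
#'   `NULL` disables rate heterogeneity.
#' @param n_categories Discrete gamma categories (default 4).
#' @param p_invariant Invariant-site proportion.
#' @param frequencies Optional replacement frequencies (+F).
#' @param renormalize_inv See [subst_model()].
#' @return A `"subst_model"`.
#' @export
lg_model <- function(gamma_shape = 1, n_categories = 4L, p_invariant = 0,
                     frequencies = NULL, renormalize_inv = FALSE) {
  base <- read_paml_matrix()
  plus_f <- !is.null(frequencies)
  nm <- paste0("LG",
               if (!is.null(gamma_shape)) paste0("+G", n_categories) else "",
               if (p_invariant > 0) "+I" else "",
               if (plus_f) "+F" else "")
  subst_model(base$rates,
              if (plus_f) frequencies else base$freqs,
              gamma_shape = gamma_shape, n_categories = n_categories,
              p_invariant = p_invariant, plus_f = plus_f,
              renormalize_inv = renormalize_inv, name = nm)
}

#' Parse a model specification string
#'
#' Accepts strings such as `"LG"`, `"LG+G4"`, `"LG+G4+I"`, `"LG+G4+F"`.
#' `+F` frequencies must then be supplied from the alignment (see
#' [empirical_aa_freqs()]); here the flag only switches the frequency source.
#'
#' @param spec Model string.
#' @param gamma_shape Shape used when `+G` is present.
#' @param p_invariant Proportion used when `+I` is present.
#' @param frequencies Frequencies used when `+F` is present (required then).
#' @return A `"subst_model"`.
#' @export
parse_model_spec <- function(spec, gamma_shape = 1, p_invariant = 0.1,
                             frequencies = NULL) {
  parts <- strsplit(toupper(spec), "+", fixed = TRUE)[[1]]
  if (parts[1] != "LG") stop("only the LG family is supported, got ", parts[1])
  has_g <- grepl("^G\\d*$", parts)
  ncat <- 4L
  if (any(has_g)) {
    g <- parts[which(has_g)[1]]
    if (nchar(g) > 1) ncat <- as.integer(substring(g, 2))
  }
  has_i <- "I" %in% parts
  has_f <- "F" %in% parts
  if (has_f && is.null(frequencies)) {
    stop("+F model requires observed frequencies")
  }
  lg_model(gamma_shape = if (any(has_g)) gamma_shape else NULL,
           n_categories = ncat,
           p_invariant = if (has_i) p_invariant else 0,
           frequencies = if (has_f) frequencies else NULL)
}

#' Empirical amino-acid frequencies from an alignment (+F)
#'
#' Observed residue proportions with a pseudo-count of 1/20 added for every
#' residue absent from the alignment, so no frequency is exactly zero.
#'
#' @param aln An alignment matrix (see [aa_alignment()]).
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
empirical_aa_freqs <- function(aln) {
  chars <- toupper(as.vector(aln))
  chars <- chars[chars %in% AA_ALPHABET]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  counts <- as.numeric(counts)
  counts[counts == 0] <- 1 / 20
  stats::setNames(counts / sum(counts), AA_ALPHABET)
}

#' Build the scaled rate matrix of a substitution model
#'
#' `q_ij = s_ij * pi_j` off the diagonal; the diagonal makes rows sum to
#' zero, and the whole matrix is rescaled so the expected substitution rate
#' at stationarity, `-sum(pi_i q_ii)`, equals 1 (branch lengths are then in
#' expected substitutions per site).
#'
#' @param model A `"subst_model"`.
#' @return A 20x20 generator matrix.
#' @export
build_rate_matrix <- function(model) {
  q <- model$rates * rep(model$freqs, each = 20)
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  scale <- -sum(model$freqs * diag(q))
  q / scale
}

#' Discrete-gamma category rates
#'
#' Splits the gamma(shape, rate = shape) density (mean 1) into `n` equal
#' probability slices and uses each slice's conditional mean as its rate, so
#' the rates average exactly 1.
#'
#' @param shape Gamma shape `alpha` (> 0).
#' @param n_categories Number of categories (>= 1).
#' @return Numeric vector of `n_categories` rates with mean 1.
#' @export
discrete_gamma <- function(shape, n_categories) {
  stopifnot(shape > 0, n_categories >= 1)
  n <- as.integer(n_categories)
  if (n == 1L) return(1)
  # slice boundaries, then conditional means via the incomplete-gamma
  # identity: E[X | a < X < b] * P(a < X < b) =
  #   pgamma(b, shape+1) - pgamma(a, shape+1) for gamma(shape, rate=shape)
  bounds <- stats::qgamma(seq(0, 1, length.out = n + 1), shape, rate = shape)
  upper <- stats::pgamma(bounds[-1], shape + 1, rate = shape)
  lower <- stats::pgamma(bounds[-(n + 1)], shape + 1, rate = shape)
  rates <- n * (upper - lower)
  rates / mean(rates)
}

# Category rates of a model, honouring the invariant-renormalisation toggle.
model_category_rates <- function(model) {
  rates <- if (is.null(model$gamma_shape)) 1 else {
    discrete_gamma(model$gamma_shape, model$n_categories)
  }
  if (isTRUE(model$renormalize_inv) && model$p_invariant > 0) {
    rates <- rates / (1 - model$p_invariant)
  }
  rates
}

# Symmetrised eigendecomposition of a reversible generator, cached for
# repeated transition-probability evaluations.
#   Q = D^{-1/2} (D^{1/2} Q D^{-1/2}) D^{1/2},   D = diag(pi)
eigen_decompose_q <- function(q, freqs) {
  sq <- sqrt(freqs)
  s <- q * (sq %o% (1 / sq))
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  list(values = e$values,
       u = e$vectors / sq,          # U = D^{-1/2} V
       uinv = t(e$vectors) * rep(sq, each = 20))  # U^{-1} = V' D^{1/2}
}

# P(t) from a cached decomposition.
prob_from_eigen <- function(dec, t) {
  p <- dec$u %*% (exp(dec$values * t) * dec$uinv)
  # clamp tiny negative round-off
  p[p < 0] <- 0
  p
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` via the symmetrised eigendecomposition (similarity
#' transform by `sqrt(pi)`), valid for reversible models. `P(0)` is the
#' identity and every row sums to 1.
#'
#' @param q Generator matrix from [build_rate_matrix()].
#' @param t Branch length (>= 0), in expected substitutions per site.
#' @param freqs Stationary frequencies of the model.
#' @return A 20x20 row-stochastic matrix.
#' @export
transition_probs <- function(q, t, freqs) {
  if (t < 0) stop("branch length must be >= 0")
  p <- prob_from_eigen(eigen_decompose_q(q, freqs), t)
  dimnames(p) <- list(AA_ALPHABET, AA_ALPHABET)
  p
}
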