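# Partitioned amino-acid likelihood engine. The R layer compresses site
# patterns, builds tip partials and the rate-matrix eigendecomposition, and
# hands off to compiled pruning / branch-optimisation routines (src/).

# Precompute everything that does not depend on branch lengths, in the
# layout the compiled code consumes.
lik_prep <- function(tree, aln, model) {
  stopifnot(inherits(model, "subst_model"))
  taxa <- tree$tip.label
  miss <- setdiff(taxa, rownames(aln))
  if (length(miss)) stop("taxa missing from alignment: ",
                         paste(miss, collapse = ", "))
  sub <- aln[taxa, , drop = FALSE]

  # site-pattern compression
  keys <- apply(sub, 2, paste, collapse = "\r")
  uniq <- !duplicated(keys)
  pat <- sub[, uniq, drop = FALSE]
  wts <- as.numeric(table(keys)[keys[uniq]])
  npat <- ncol(pat)
  ntip <- length(taxa)

  # tip partials: indicator rows, all-ones for missing data
  tip_part <- vector("list", ntip)
  code <- match(toupper(pat), AA_ALPHABET)  # NA for gaps/ambiguity
  dim(code) <- dim(pat)
  for (i in seq_len(ntip)) {
    e <- matrix(0, npat, 20)
    obs <- !is.na(code[i, ])
    e[cbind(which(obs), code[i, obs])] <- 1
    e[!obs, ] <- 1
    tip_part[[i]] <- e
  }

  # invariant-class site log-likelihoods
  inv_loglik <- rep(-Inf, npat)
  for (p in seq_len(npat)) {
    res <- unique(code[, p])
    res <- res[!is.na(res)]
    if (!length(res)) inv_loglik[p] <- 0
    else if (length(res) == 1L) inv_loglik[p] <- log(model$freqs[res])
  }

  dec <- eigen_decompose_q(build_rate_matrix(model), model$freqs)
  rates <- model_category_rates(model)
  pinv <- model$p_invariant
  post <- ape::reorder.phylo(tree, "postorder")
  list(tree = post, ntip = ntip,
       edge0 = post$edge - 1L,   # 0-based for the compiled layer
       part = list(tip_part = tip_part,
                   inv_loglik = inv_loglik,
                   weights = wts,
                   eig_values = dec$values,
                   eig_u = dec$u,
                   eig_uinv = dec$uinv,
                   freqs = unname(model$freqs),
                   rates = rates,
                   log_wcat = log((1 - pinv) / length(rates)),
                   log_pinv = if (pinv > 0) log(pinv) else -Inf))
}

# Per-partition preps for one tree; all share the postorder tree of the
# first (identical topology, so identical reorder).
scheme_preps <- function(tree, aln, scheme) {
  check_scheme_covers(scheme, ncol(aln))
  lapply(seq_len(n_partitions(scheme)), function(i) {
    block <- aa_alignment(aln[, (scheme$start[i] + 1L):scheme$end[i],
                              drop = FALSE])
    lik_prep(tree, block, scheme$models[[i]])
  })
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under a reversible amino-acid model with a discrete
#' gamma + invariant-site mixture. Per-site likelihoods are
#' `(1 - p_inv)/n_cat * sum_k L_k + p_inv * pi_r [site constant]`; partials
#' are rescaled per node so deep trees do not underflow; gap and ambiguity
#' columns contribute all-ones partials. Because the model is reversible the
#' value does not depend on where the tree is rooted.
#'
#' @param tree A `"phylo"` with branch lengths, taxa a subset of the
#'   alignment's.
#' @param aln An `"aa_alignment"`.
#' @param model A `"subst_model"`.
#' @return Log-likelihood (length-one numeric).
#' @export
tree_log_likelihood <- function(tree, aln, model) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  prep <- lik_prep(tree, aln, model)
  cpp_tree_loglik(list(prep$part), prep$edge0, prep$ntip,
                  prep$tree$edge.length)
}

#' Partitioned log-likelihood
#'
#' Sum of per-partition log-likelihoods under each partition's own model,
#' with one shared topology and one shared set of branch lengths (linked
#' lengths, as for a single concatenated tree).
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param aln The concatenated `"aa_alignment"`.
#' @param scheme A `"partition_scheme"` covering the alignment.
#' @return Log-likelihood (length-one numeric).
#' @export
partitioned_log_likelihood <- function(tree, aln, scheme) {
  stopifnot(inherits(scheme, "partition_scheme"))
  preps <- scheme_preps(tree, aln, scheme)
  cpp_tree_loglik(lapply(preps, `[[`, "part"), preps[[1]]$edge0,
                  preps[[1]]$ntip, preps[[1]]$tree$edge.length)
}

#' Optimise branch lengths by round-robin univariate search
#'
#' Each sweep recomputes inside and outside partials, then optimises every
#' branch in turn by golden-section search of its likelihood profile (cheap,
#' since only that branch's transition matrix changes). Sweeps repeat until
#' the log-likelihood improves by less than `tol`. A sweep that fails to
#' improve (possible because within-sweep updates reuse partials computed at
#' the sweep start) is retried with partials refreshed before every branch,
#' which is strictly non-decreasing; the reported trajectory is therefore
#' monotone.
#'
#' @param tree A `"phylo"`; missing or non-positive lengths are reset to 0.1.
#' @param aln An `"aa_alignment"`.
#' @param scheme A `"partition_scheme"` (or a single `"subst_model"`, treated
#'   as one partition over the whole alignment).
#' @param control List overriding any of: `tol` (logL convergence, default
#'   1e-6), `max_sweeps` (20), `min_len`/`max_len` (search bracket, 1e-8 and
#'   20), `opt_tol` (branch-length resolution of the inner search, 1e-6).
#' @return A list with `tree` (re-estimated lengths, postorder), `logL`, and
#'   `trajectory` (logL after each sweep).
#' @export
optimize_branch_lengths <- function(tree, aln, scheme, control = list()) {
  ctl <- utils::modifyList(list(tol = 1e-6, max_sweeps = 20,
                                min_len = 1e-8, max_len = 20,
                                opt_tol = 1e-6), control)
  if (inherits(scheme, "subst_model")) {
    scheme <- partition_scheme("all", 0L, ncol(aln), scheme)
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  tree$edge.length[!is.finite(tree$edge.length) | tree$edge.length <= 0] <- 0.1
  preps <- scheme_preps(tree, aln, scheme)
  post <- preps[[1]]$tree
  res <- cpp_optimize_lengths(lapply(preps, `[[`, "part"),
                              preps[[1]]$edge0, preps[[1]]$ntip,
                              post$edge.length,
                              as.integer(ctl$max_sweeps), ctl$tol,
                              ctl$min_len, ctl$max_len, ctl$opt_tol)
  if (!is.finite(res$trajectory[1])) {
    stop("non-finite likelihood at the starting lengths")
  }
  post$edge.length <- as.numeric(res$lengths)
  list(tree = post, logL = res$logL, trajectory = as.numeric(res$trajectory))
}

#' Count the free parameters of a toy partitioned fit
#'
#' `K` = number of branch lengths plus, per partition, one for the gamma
#' shape when rate heterogeneity is on, one for the invariant proportion
#' when `+I`, and 19 for the frequencies when `+F`. Exchangeabilities are
#' fixed (empirical matrix) and the topology is not counted, following the
#' usual phylogenetic model-selection accounting.
#'
#' @param tree A `"phylo"`.
#' @param scheme A `"partition_scheme"` or single `"subst_model"` (counted
#'   as one partition).
#' @return Integer parameter count.
#' @export
count_free_params <- function(tree, scheme) {
  models <- if (inherits(scheme, "subst_model")) list(scheme) else scheme$models
  k <- nrow(tree$edge)
  for (m in models) {
    k <- k + (!is.null(m$gamma_shape)) + (m$p_invariant > 0) + 19 * m$plus_f
  }
  as.integer(k)
}
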