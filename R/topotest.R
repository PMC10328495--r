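# Topology hypothesis predicates, posterior model odds from MCMC tree
# samples, root-placement frequency tables, MCC tree selection and outgroup
# rooting.

#' Define a clade hypothesis
#'
#' A named topological predicate evaluated against sampled trees: monophyly
#' of one taxon set, a sister grouping of two sets, or the negation of
#' monophyly (used for "cannot be sister groups" style constraints).
#'
#' @param name Hypothesis label.
#' @param sets A named list of character vectors (taxon sets). Monophyly and
#'   negative monophyly take one set; `sister_group` takes exactly two
#'   disjoint sets.
#' @param kind One of `"monophyly"`, `"sister_group"`, `"negative_monophyly"`.
#' @param background Optional list of taxon sets assumed monophyletic by the
#'   producer of the trees (recorded for provenance; not enforced).
#' @return An object of class `"clade_hypothesis"`.
#' @examples
#' clade_hypothesis("nuclear-escape", list(adeno = c("A1", "A2"),
#'                                         ncldv = c("N1", "N2")),
#'                  kind = "sister_group")
#' @export
clade_hypothesis <- function(name, sets,
                             kind = c("monophyly", "sister_group",
                                      "negative_monophyly"),
                             background = list()) {
  kind <- match.arg(kind)
  if (!is.list(sets)) sets <- list(sets)
  if (kind == "sister_group") {
    if (length(sets) != 2L) stop("sister_group requires exactly two taxon sets")
    if (length(intersect(sets[[1]], sets[[2]]))) {
      stop("sister_group sets must be disjoint")
    }
  } else if (length(sets) != 1L) {
    stop(kind, " requires exactly one taxon set")
  }
  if (any(!vapply(sets, length, integer(1)))) stop("empty taxon set")
  structure(list(name = name, sets = sets, kind = kind,
                 background = background),
            class = "clade_hypothesis")
}

#' Test monophyly of a taxon set
#'
#' On a rooted tree, `taxa` is monophyletic iff some node's leaf set equals
#' it exactly; on an unrooted tree, iff the bipartition `taxa | complement`
#' is induced by some edge. Singleton sets and the full taxon set are always
#' monophyletic.
#'
#' @param tree A `"phylo"` object.
#' @param taxa Character vector of taxon labels (non-empty subset of the
#'   tree's taxa).
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  all_taxa <- tree$tip.label
  miss <- setdiff(taxa, all_taxa)
  if (length(miss)) {
    stop("taxa not in tree: ", paste(miss, collapse = ", "))
  }
  taxa <- unique(taxa)
  k <- length(taxa)
  n <- length(all_taxa)
  if (k == 0L) stop("empty taxon set")
  if (k == 1L || k == n) return(TRUE)
  if (ape::is.rooted(tree)) {
    target <- sort(taxa)
    for (cl in node_clades(tree)) {
      if (length(cl) == k && identical(sort(cl), target)) return(TRUE)
    }
    # the complement of the clade below one root child is also a clade
    # only when it equals the other root child's clade, already covered
    FALSE
  } else {
    if (k == n - 1L) return(TRUE)  # complement is a single leaf
    split_key(taxa, all_taxa) %in% bipartitions(tree)
  }
}

#' Test a sister grouping of two taxon sets
#'
#' True iff `set_a`, `set_b` and their union are all monophyletic, i.e. the
#' two clades are each other's closest relatives.
#'
#' @param tree A `"phylo"` object.
#' @param set_a,set_b Disjoint non-empty character vectors of taxon labels.
#' @return Logical scalar.
#' @export
is_sister_group <- function(tree, set_a, set_b) {
  if (length(intersect(set_a, set_b))) stop("sets overlap")
  is_monophyletic(tree, set_a) &&
    is_monophyletic(tree, set_b) &&
    is_monophyletic(tree, union(set_a, set_b))
}

# Evaluate a clade hypothesis on one tree.
hypothesis_holds <- function(tree, hyp) {
  stopifnot(inherits(hyp, "clade_hypothesis"))
  switch(hyp$kind,
         monophyly = is_monophyletic(tree, hyp$sets[[1]]),
         sister_group = is_sister_group(tree, hyp$sets[[1]], hyp$sets[[2]]),
         negative_monophyly = !is_monophyletic(tree, hyp$sets[[1]]))
}

#' Posterior model odds from a tree sample
#'
#' Counts the post-burn-in trees consistent and inconsistent with a
#' topological hypothesis and forms the posterior odds of the two models.
#' The headline `odds` is `n_consistent / n_inconsistent` (the ratio of the
#' posterior masses of the two models); `odds_total`
#' (`n_consistent / n_total`) is reported alongside because published tables
#' mix the two conventions.
#'
#' @param sample A `"tree_sample"`.
#' @param hyp A `"clade_hypothesis"`.
#' @param burnin Burn-in fraction applied before counting; defaults to the
#'   fraction stored on the sample.
#' @return An object of class `"posterior_odds"`: a list with
#'   `n_consistent`, `n_inconsistent`, `n_total`, `frequency` (consistent
#'   fraction), `percent`, `odds`, `odds_total` and the hypothesis name.
#'   `odds` is `Inf` when no inconsistent tree was sampled.
#' @export
posterior_model_odds <- function(sample, hyp, burnin = NULL) {
  stopifnot(inherits(sample, "tree_sample"))
  if (!is.null(burnin)) sample <- apply_burnin(sample, burnin)
  else if (sample$burnin_fraction > 0) sample <- apply_burnin(sample)
  trees <- sample$trees
  if (!length(trees)) stop("empty tree sample after burn-in")
  cons <- sum(vapply(trees, hypothesis_holds, logical(1), hyp = hyp))
  total <- length(trees)
  incons <- total - cons
  structure(list(hypothesis = hyp$name,
                 n_consistent = cons,
                 n_inconsistent = incons,
                 n_total = total,
                 frequency = cons / total,
                 percent = 100 * cons / total,
                 odds = if (incons == 0L) Inf else cons / incons,
                 odds_total = cons / total),
            class = "posterior_odds")
}

#' Posterior model odds from published tree counts
#'
#' Builds the same record as [posterior_model_odds()] directly from a
#' consistent-tree count and a total, for re-analysing published
#' filtered-count tables when the raw tree samples are unavailable.
#'
#' @param n_consistent Number of trees consistent with the hypothesis.
#' @param n_total Total number of post-burn-in trees.
#' @param hypothesis Hypothesis label.
#' @return A `"posterior_odds"` object.
#' @examples
#' posterior_odds_from_counts(15, 28001)$odds   # 5.36e-4
#' @export
posterior_odds_from_counts <- function(n_consistent, n_total,
                                       hypothesis = "M0") {
  stopifnot(n_consistent >= 0, n_total >= 1, n_consistent <= n_total)
  incons <- n_total - n_consistent
  structure(list(hypothesis = hypothesis,
                 n_consistent = n_consistent,
                 n_inconsistent = incons,
                 n_total = n_total,
                 frequency = n_consistent / n_total,
                 percent = 100 * n_consistent / n_total,
                 odds = if (incons == 0L) Inf else n_consistent / incons,
                 odds_total = n_consistent / n_total),
            class = "posterior_odds")
}

#' @export
print.posterior_odds <- function(x, ...) {
  cat(sprintf("Hypothesis '%s': %d/%d trees (%.4g%%); odds %.3g (vs rest %.3g)\n",
              x$hypothesis, x$n_consistent, x$n_total, x$percent, x$odds,
              x$odds_total))
  invisible(x)
}

#' Root bipartition of a rooted tree
#'
#' The canonical split between the two subtrees descending from the root;
#' identifies where the root lies, ignoring branch lengths.
#'
#' @param tree A rooted `"phylo"` with a binary root.
#' @return A canonical split key (see [bipartitions()]).
#' @export
root_bipartition <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  if (length(kids) != 2L) {
    stop("tree is unrooted or has a multifurcating root (",
         length(kids), " basal children)")
  }
  ntips_all <- tree$tip.label
  side <- if (kids[1] <= ntip) {
    ntips_all[kids[1]]
  } else {
    ape::extract.clade(tree, kids[1])$tip.label
  }
  split_key(side, ntips_all)
}

#' Root-placement frequency table
#'
#' Tallies the root bipartition of every tree in a rooted sample, sorted by
#' descending frequency (ties broken lexicographically by split key).
#'
#' @param sample A `"tree_sample"` of rooted trees.
#' @param burnin Optional burn-in fraction applied before tallying.
#' @return A data frame of class `"root_freq_table"` with columns `split`,
#'   `count`, `frequency`, and attribute `n_trees`.
#' @export
root_frequency_table <- function(sample, burnin = NULL) {
  stopifnot(inherits(sample, "tree_sample"))
  if (!is.null(burnin)) sample <- apply_burnin(sample, burnin)
  else if (sample$burnin_fraction > 0) sample <- apply_burnin(sample)
  keys <- vapply(sample$trees, root_bipartition, character(1))
  tab <- table(keys)
  df <- data.frame(split = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$frequency <- df$count / length(keys)
  df <- df[order(-df$count, df$split), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_trees") <- length(keys)
  class(df) <- c("root_freq_table", class(df))
  df
}

#' Maximum clade credibility (MCC) tree
#'
#' Scores every sampled tree by the sum over its non-trivial clades of the
#' log clade frequency (clade frequencies estimated from the same sample;
#' equivalently, the log product of clade credibilities) and returns the
#' best-scoring sampled tree. Ties resolve to the earliest tree in sample
#' order. Clades of size 1 and of the full taxon set are excluded.
#'
#' @param sample A `"tree_sample"` of rooted trees.
#' @param burnin Optional burn-in fraction applied first.
#' @return The winning `"phylo"` tree, with attributes `mcc_score` (log
#'   credibility) and `mcc_index` (its position in the sample).
#' @export
mcc_tree <- function(sample, burnin = NULL) {
  stopifnot(inherits(sample, "tree_sample"))
  if (!is.null(burnin)) sample <- apply_burnin(sample, burnin)
  else if (sample$burnin_fraction > 0) sample <- apply_burnin(sample)
  trees <- sample$trees
  if (!length(trees)) stop("empty tree sample")
  n <- length(trees[[1]]$tip.label)
  taxa <- trees[[1]]$tip.label
  clade_keys <- lapply(trees, function(tr) {
    cls <- node_clades(tr)
    keep <- vapply(cls, function(cl) length(cl) >= 2 && length(cl) < n,
                   logical(1))
    unique(vapply(cls[keep], function(cl) paste(sort(cl), collapse = "|"),
                  character(1)))
  })
  freq <- table(unlist(clade_keys)) / length(trees)
  scores <- vapply(clade_keys, function(k) sum(log(freq[k])), numeric(1))
  best <- which.max(scores)  # first index on ties
  out <- trees[[best]]
  attr(out, "mcc_score") <- scores[best]
  attr(out, "mcc_index") <- best
  out
}

#' Root an unrooted tree on an outgroup
#'
#' Places the root on the edge separating the outgroup from the remaining
#' taxa, splitting that edge's length evenly between the two root children.
#'
#' @param tree An unrooted `"phylo"` (a rooted input is unrooted first).
#' @param outgroup Character vector of taxon labels; must induce a
#'   bipartition of the tree (or be a single taxon).
#' @return A rooted `"phylo"` whose root bipartition is
#'   `outgroup | rest`.
#' @export
outgroup_root <- function(tree, outgroup) {
  taxa <- tree$tip.label
  miss <- setdiff(outgroup, taxa)
  if (length(miss)) stop("outgroup taxa not in tree: ",
                         paste(miss, collapse = ", "))
  if (length(outgroup) >= length(taxa)) {
    stop("outgroup must be a proper subset of the taxa")
  }
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  complement <- setdiff(taxa, outgroup)
  if (length(outgroup) > 1L && length(complement) > 1L &&
      !(split_key(outgroup, taxa) %in% bipartitions(utree))) {
    stop("outgroup {", paste(outgroup, collapse = ", "),
         "} is not a bipartition of the tree")
  }
  node <- if (length(outgroup) == 1L) {
    which(utree$tip.label == outgroup)
  } else if (length(complement) == 1L) {
    which(utree$tip.label == complement)
  } else {
    # in the unrooted (basal-trichotomy) representation the outgroup clade
    # is attached either below its MRCA or below the MRCA of the complement
    mrca <- ape::getMRCA(utree, outgroup)
    below <- if (mrca == length(utree$tip.label) + 1L) NULL else {
      ape::extract.clade(utree, mrca)$tip.label
    }
    if (!is.null(below) && setequal(below, outgroup)) mrca
    else ape::getMRCA(utree, setdiff(taxa, outgroup))
  }
  edge_row <- which(utree$edge[, 2] == node)
  if (!length(edge_row)) stop("cannot locate the outgroup attachment edge")
  len <- if (is.null(utree$edge.length)) NULL else utree$edge.length[edge_row]
  pos <- if (is.null(len)) 0 else len / 2
  rooted <- phytools::reroot(utree, node, position = pos)
  rooted
}
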