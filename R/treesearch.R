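# Exhaustive constrained maximum-likelihood topology search at toy scale:
# enumerate all unrooted binary topologies, filter by a topological
# constraint (or its negation), optimise branch lengths on each candidate,
# and keep the best. Stands in, at <= 8 taxa, for the constrained searches a
# full-scale ML program performs on real data.

# Normalise a constraint argument to a clade_hypothesis.
as_hypothesis <- function(constraint) {
  if (inherits(constraint, "clade_hypothesis")) return(constraint)
  if (is.character(constraint)) {
    return(clade_hypothesis("constraint", list(constraint), "monophyly"))
  }
  stop("constraint must be a clade_hypothesis or a character vector of taxa")
}

#' Exhaustive constrained best tree
#'
#' Enumerates every unrooted binary topology on the alignment's taxa
#' (feasible up to 8 taxa: 10,395 topologies), keeps those satisfying the
#' constraint — or violating it when `negative = TRUE`, mirroring a negative
#' topological constraint — optimises branch lengths on each, and returns
#' the maximum-likelihood topology. Enumeration order breaks exact ties
#' (first wins), so the search is deterministic.
#'
#' A two-stage schedule keeps the search affordable: every candidate is
#' scored with a coarse optimisation, then the few best candidates are
#' re-optimised to convergence.
#'
#' @param aln An `"aa_alignment"`; all rows are used as taxa.
#' @param scheme A `"partition_scheme"` or single `"subst_model"`.
#' @param constraint A `"clade_hypothesis"` or character vector of taxa
#'   (interpreted as a monophyly constraint).
#' @param negative If `TRUE`, search the topologies *violating* the
#'   constraint.
#' @param init_length Starting branch length for every edge.
#' @param coarse,fine Control lists for the screening and refinement
#'   optimisations (see [optimize_branch_lengths()]). The screening pass
#'   only has to *rank* topologies, so it is deliberately cheap; the
#'   refinement pass polishes the leaders to convergence.
#' @param refine_top How many screened candidates to re-optimise.
#' @return A list with `tree` (branch-length-optimised `"phylo"`), `logL`,
#'   `n_candidates` (topologies satisfying the filter) and `K`
#'   (free-parameter count from [count_free_params()]).
#' @export
constrained_best_tree <- function(aln, scheme, constraint, negative = FALSE,
                                  init_length = 0.1,
                                  coarse = list(max_sweeps = 2, tol = 1e-2,
                                                opt_tol = 1e-2),
                                  fine = list(max_sweeps = 10, tol = 1e-5,
                                              opt_tol = 1e-4),
                                  refine_top = 3L) {
  taxa <- rownames(aln)
  n <- length(taxa)
  if (n > 8L) stop("exhaustive search is limited to 8 taxa (got ", n, ")")
  if (n < 4L) stop("need at least 4 taxa")
  if (inherits(scheme, "subst_model")) {
    scheme <- partition_scheme("all", 0L, ncol(aln), scheme)
  }
  hyp <- as_hypothesis(constraint)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  sat <- vapply(topos, hypothesis_holds, logical(1), hyp = hyp)
  keep <- if (negative) !sat else sat
  if (!any(keep)) stop("constraint unsatisfiable: no topology passes")
  cands <- topos[keep]

  screened <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    tr <- cands[[i]]
    tr$edge.length <- rep(init_length, nrow(tr$edge))
    screened[[i]] <- optimize_branch_lengths(tr, aln, scheme, control = coarse)
  }
  lls <- vapply(screened, `[[`, numeric(1), "logL")
  ord <- order(-lls)
  top <- ord[seq_len(min(refine_top, length(ord)))]
  best <- NULL
  for (i in top) {
    ref <- optimize_branch_lengths(screened[[i]]$tree, aln, scheme,
                                   control = fine)
    if (is.null(best) || ref$logL > best$logL) best <- ref
  }
  list(tree = best$tree, logL = best$logL,
       n_candidates = length(cands),
       K = count_free_params(best$tree, scheme))
}

#' Constrained-versus-negative model fits for AIC comparison
#'
#' Runs [constrained_best_tree()] twice — once restricted to topologies
#' consistent with the hypothesis (M0) and once restricted to topologies
#' inconsistent with it (M1) — and returns a fits table ready for
#' [aic_compare()]. Both fits share `K` (same branch count and models) and
#' `n` (alignment length), so the comparison reduces to the likelihood gap,
#' exactly as when comparing constrained ML searches on real data.
#'
#' @inheritParams constrained_best_tree
#' @param labels Length-2 model names for the consistent / inconsistent fits.
#' @param characters Data-set label carried into the fits table.
#' @return A list with `fits` (data frame: model, characters, logL, K, n)
#'   and `trees` (the two optimised trees, named by model).
#' @export
ml_compare <- function(aln, scheme, constraint,
                       labels = c("constrained", "unconstrained-negative"),
                       characters = "synthetic", ...) {
  m0 <- constrained_best_tree(aln, scheme, constraint, negative = FALSE, ...)
  m1 <- constrained_best_tree(aln, scheme, constraint, negative = TRUE, ...)
  fits <- data.frame(model = labels,
                     characters = characters,
                     logL = c(m0$logL, m1$logL),
                     K = c(m0$K, m1$K),
                     n = ncol(aln),
                     stringsAsFactors = FALSE)
  list(fits = fits,
       trees = stats::setNames(list(m0$tree, m1$tree), labels))
}
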