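# Synthetic-data generators with known ground truth: pure-birth trees,
# alignments evolved along them, posterior-like tree samples with a
# controllable focal-clade frequency or root-position distribution, and
# run-level marginal-likelihood replicates. Every generator draws from its
# own seeded stream (seed + operation tag), so adding one call never shifts
# the output of another.

#' Simulate a pure-birth (Yule) tree
#'
#' Standard constant-rate pure-birth process started from two lineages,
#' stopped after the waiting time at `n` lineages, so the expected root
#' height is `sum(1/(k * birth_rate))` for `k = 2..n`. Tip labels
#' (`t1..tn`) are assigned exchangeably.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Integer seed.
#' @return A rooted binary `"phylo"` with branch lengths.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed = 1L) {
  stopifnot(n_taxa >= 2, birth_rate > 0)
  with_stream(seed, "yule", {
    n <- as.integer(n_taxa)
    # lineage records: parent, birth time, end time
    parent <- c(0L, 0L)
    birth <- c(0, 0)
    end <- c(NA_real_, NA_real_)
    active <- c(1L, 2L)
    now <- 0
    while (length(active) < n) {
      k <- length(active)
      now <- now + stats::rexp(1, k * birth_rate)
      i <- active[sample.int(k, 1L)]
      end[i] <- now
      for (rep in 1:2) {
        parent <- c(parent, i)
        birth <- c(birth, now)
        end <- c(end, NA_real_)
      }
      active <- c(setdiff(active, i), length(parent) - 1L, length(parent))
    }
    now <- now + stats::rexp(1, n * birth_rate)
    end[active] <- now

    is_tip <- is.na(vapply(seq_along(parent),
                           function(i) match(i, parent), integer(1)))
    tip_ids <- which(is_tip)
    labels <- paste0("t", seq_len(n))[sample.int(n)]
    lab_of <- stats::setNames(labels, tip_ids)
    kids <- split(seq_along(parent), parent)
    emit <- function(i) {
      len <- end[i] - birth[i]
      if (is_tip[i]) {
        paste0(lab_of[[as.character(i)]], ":", sprintf("%.12g", len))
      } else {
        paste0("(", paste(vapply(kids[[as.character(i)]], emit, character(1)),
                          collapse = ","), "):", sprintf("%.12g", len))
      }
    }
    roots <- kids[["0"]]
    nwk <- paste0("(", paste(vapply(roots, emit, character(1)),
                             collapse = ","), ");")
    parse_newick(nwk)
  })
}

#' Simulate an amino-acid alignment along a tree
#'
#' Each site is assigned to the invariant class with probability
#' `p_invariant`, otherwise to one of the equal-weight gamma categories;
#' the root residue is drawn from the stationary frequencies and evolved
#' edge by edge with the model's transition probabilities.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param model A `"subst_model"`.
#' @param length Number of sites.
#' @param seed Integer seed.
#' @return An `"aa_alignment"` on the tree's taxa.
#' @export
simulate_alignment <- function(tree, model, length, seed = 1L) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  with_stream(seed, "alignment", {
    L <- as.integer(length)
    rates <- model_category_rates(model)
    ncat <- length(rates)
    inv <- stats::runif(L) < model$p_invariant
    cat_of <- sample.int(ncat, L, replace = TRUE)
    cat_of[inv] <- 0L  # invariant class: rate zero
    dec <- eigen_decompose_q(build_rate_matrix(model), model$freqs)

    post <- ape::reorder.phylo(tree, "postorder")
    ntip <- length(post$tip.label)
    nn <- ntip + post$Nnode
    states <- matrix(NA_integer_, nn, L)
    root <- ntip + 1L
    states[root, ] <- sample.int(20, L, replace = TRUE, prob = model$freqs)
    # walk edges root-down (reverse postorder)
    for (r in rev(seq_len(nrow(post$edge)))) {
      par <- post$edge[r, 1]; chd <- post$edge[r, 2]
      t_edge <- post$edge.length[r]
      child <- states[par, ]
      for (c in seq_len(ncat)) {
        sel <- which(cat_of == c)
        if (!length(sel)) next
        P <- prob_from_eigen(dec, rates[c] * t_edge)
        for (s in 1:20) {
          idx <- sel[states[par, sel] == s]
          if (length(idx)) {
            child[idx] <- sample.int(20, length(idx), replace = TRUE,
                                     prob = P[s, ])
          }
        }
      }
      states[chd, ] <- child
    }
    m <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]],
                ntip, L, dimnames = list(post$tip.label, NULL))
    aa_alignment(m)
  })
}

# Random branch length: gamma(shape 2, mean `mean_len`) gives moderate,
# realistic protein-tree lengths that are never pathologically close to 0.
rand_len <- function(n, mean_len) {
  stats::rgamma(n, shape = 2, rate = 2 / mean_len)
}

# Recursive uniform-split topology builder over "units" (each unit is either
# a taxon label or an already-built newick subtree string). Returns a newick
# substring without a trailing branch length.
rand_topology_str <- function(units, mean_len) {
  n <- length(units)
  if (n == 1L) return(units[[1]])
  sizes <- if (n == 2L) 1L else sample.int(n - 1L, 1L)
  pick <- sample.int(n, sizes)
  left <- rand_topology_str(units[pick], mean_len)
  right <- rand_topology_str(units[-pick], mean_len)
  lens <- rand_len(2, mean_len)
  paste0("(", left, ":", lens[1], ",", right, ":", lens[2], ")")
}

# Random rooted binary tree on `taxa` with gamma branch lengths.
random_rooted_tree <- function(taxa, mean_len = 0.2) {
  units <- as.list(quote_label(taxa))
  parse_newick(paste0(rand_topology_str(units, mean_len), ";"))
}

# One rooted tree in which every focal set of `hyp` (and, for sister
# groupings, their union) is monophyletic: focal subtrees are built first
# and then treated as atomic units inside a random backbone on the rest.
constrained_tree_draw <- function(taxa, hyp, mean_len = 0.2) {
  focal <- unique(unlist(hyp$sets))
  rest <- setdiff(taxa, focal)
  if (!length(rest)) stop("clade impossible: focal set equals the taxon set")
  clade_str <- if (hyp$kind == "sister_group") {
    a <- rand_topology_str(as.list(quote_label(hyp$sets[[1]])), mean_len)
    b <- rand_topology_str(as.list(quote_label(hyp$sets[[2]])), mean_len)
    lens <- rand_len(2, mean_len)
    paste0("(", a, ":", lens[1], ",", b, ":", lens[2], ")")
  } else {
    rand_topology_str(as.list(quote_label(hyp$sets[[1]])), mean_len)
  }
  units <- c(as.list(quote_label(rest)), list(clade_str))
  parse_newick(paste0(rand_topology_str(units, mean_len), ";"))
}

#' Simulate a posterior-like tree sample with a controllable clade frequency
#'
#' Emits `n_trees` rooted trees in which the focal hypothesis holds,
#' independently per tree, with probability `p`: a "consistent" draw is
#' constructed with the focal clade(s) in place, an "inconsistent" draw is
#' rejection-sampled from unconstrained random topologies until the
#' hypothesis fails (capped at 10,000 attempts — a safety valve, since for
#' realistic taxon counts absence is overwhelmingly likely).
#'
#' @param taxa Character vector: the taxon namespace.
#' @param hypothesis A `"clade_hypothesis"` or character vector (monophyly).
#' @param p Per-tree probability that the hypothesis holds.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @param mean_branch Mean branch length of the generated trees.
#' @return A `"tree_sample"`.
#' @export
simulate_tree_sample <- function(taxa, hypothesis, p, n_trees, seed = 1L,
                                 mean_branch = 0.2) {
  stopifnot(p >= 0, p <= 1, n_trees >= 1)
  hyp <- as_hypothesis(hypothesis)
  miss <- setdiff(unlist(hyp$sets), taxa)
  if (length(miss)) stop("focal taxa outside namespace: ",
                         paste(miss, collapse = ", "))
  if (setequal(unlist(hyp$sets), taxa)) {
    stop("clade impossible: focal set equals the taxon set")
  }
  with_stream(seed, "tree_sample", {
    # a "positive" hypothesis holds on constructed trees and is rejection
    # sampled for absence; negative monophyly is the mirror image
    base_hyp <- if (hyp$kind == "negative_monophyly") {
      clade_hypothesis(hyp$name, hyp$sets, "monophyly")
    } else hyp
    draw_with_clade <- function() constrained_tree_draw(taxa, base_hyp,
                                                        mean_branch)
    draw_without_clade <- function() {
      for (try in seq_len(10000L)) {
        tr <- random_rooted_tree(taxa, mean_branch)
        if (!hypothesis_holds(tr, base_hyp)) return(tr)
      }
      stop("could not draw a clade-free tree in 10,000 attempts")
    }
    flags <- stats::runif(n_trees) < p
    trees <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      want_hold <- flags[i]
      want_clade <- if (hyp$kind == "negative_monophyly") !want_hold
                    else want_hold
      trees[[i]] <- if (want_clade) draw_with_clade() else draw_without_clade()
      stopifnot(hypothesis_holds(trees[[i]], hyp) == want_hold)
    }
    tree_sample(trees, source = sprintf("synthetic p=%g", p))
  })
}

#' Simulate a posterior-like sample of alternative root placements
#'
#' Roots a fixed unrooted tree on edges drawn from a given root-position
#' distribution, emulating the spread of root placements across an MCMC
#' sample.
#'
#' @param base_tree An unrooted `"phylo"` with branch lengths.
#' @param root_distribution Named list: `placements` is a list of taxon
#'   vectors (one side of the target edge each), `probabilities` their
#'   sampling weights (summing to 1). A plain list of taxon vectors with a
#'   `prob` attribute, or a list of `list(placement=, probability=)` pairs,
#'   is also accepted.
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return A `"tree_sample"` of rooted trees.
#' @export
simulate_root_sample <- function(base_tree, root_distribution, n_trees,
                                 seed = 1L) {
  if (ape::is.rooted(base_tree)) base_tree <- ape::unroot(base_tree)
  rd <- root_distribution
  if (!is.null(rd$placements)) {
    placements <- rd$placements
    probs <- rd$probabilities
  } else {
    placements <- lapply(rd, function(x) if (is.list(x)) x$placement else x)
    probs <- vapply(rd, function(x) if (is.list(x)) x$probability else NA_real_,
                    numeric(1))
    if (anyNA(probs)) probs <- attr(root_distribution, "prob")
  }
  if (is.null(probs) || abs(sum(probs) - 1) > 1e-8) {
    stop("root distribution probabilities must sum to 1")
  }
  taxa <- base_tree$tip.label
  splits <- bipartitions(base_tree)
  variants <- lapply(placements, function(pl) {
    trivial <- length(pl) == 1L || length(pl) == length(taxa) - 1L
    if (!trivial && !(split_key(pl, taxa) %in% splits)) {
      stop("root placement {", paste(pl, collapse = ", "),
           "} is not an edge of the base tree")
    }
    outgroup_root(base_tree, pl)
  })
  with_stream(seed, "root_sample", {
    idx <- sample.int(length(variants), n_trees, replace = TRUE, prob = probs)
    tree_sample(variants[idx], source = "synthetic root sample")
  })
}

#' Simulate run-level log marginal likelihoods
#'
#' Per-run estimates drawn as the true value plus zero-mean Gaussian noise
#' of scale `run_sd`, mirroring the run-to-run spread of stepping-stone
#' estimates.
#'
#' @param true_ln_ml True log marginal likelihood.
#' @param run_sd Between-run standard deviation (>= 0).
#' @param n_runs Number of runs.
#' @param seed Integer seed.
#' @param model Model label attached to the table.
#' @return A data frame with columns `model`, `run_id`, `log_marginal`;
#'   attribute `true_ln_ml`.
#' @export
simulate_marginal_runs <- function(true_ln_ml, run_sd, n_runs, seed = 1L,
                                   model = "M0") {
  stopifnot(run_sd >= 0, n_runs >= 1)
  with_stream(seed, "marginal_runs", {
    vals <- true_ln_ml + stats::rnorm(n_runs, 0, run_sd)
    structure(data.frame(model = model, run_id = seq_len(n_runs),
                         log_marginal = vals, stringsAsFactors = FALSE),
              true_ln_ml = true_ln_ml)
  })
}
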