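# Diversity-maximising taxon subsampling: iteratively collapse the closest
# leaf pair until the target count remains, emulating the reduction of large
# per-group protein trees to a handful of maximally diverse representatives.

#' Diversity-maximising leaf subsample of one tree
#'
#' Repeatedly finds the leaf pair with the smallest patristic distance and
#' removes one member of it until exactly `target` leaves remain. In the
#' default deterministic mode the member removed is the less peripheral one
#' (smaller total distance to all remaining leaves; ties remove the
#' lexicographically larger label), so results are reproducible without a
#' seed. `mode = "random"` instead drops a random member of the closest
#' pair, the behaviour of the classic tool, reproducible under `seed`.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param target Number of leaves to retain (>= 2).
#' @param mode `"deterministic"` (default) or `"random"`.
#' @param seed Integer seed for `mode = "random"`.
#' @return Character vector of retained taxon labels (sorted).
#' @export
diversity_subsample <- function(tree, target, mode = c("deterministic",
                                                       "random"),
                                seed = 1L) {
  mode <- match.arg(mode)
  if (target < 2) stop("target must be >= 2")
  ntip <- length(tree$tip.label)
  if (target > ntip) stop("target (", target, ") exceeds leaf count (", ntip, ")")
  if (target == ntip) return(sort(tree$tip.label))
  d <- patristic_matrix(tree)
  run <- function() {
    keep <- rownames(d)
    dd <- d
    while (length(keep) > target) {
      diag(dd) <- Inf
      idx <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      a <- keep[idx[1]]; b <- keep[idx[2]]
      diag(dd) <- 0
      drop_tx <- if (mode == "random") {
        sample(c(a, b), 1L)
      } else {
        ta <- sum(dd[a, ]); tb <- sum(dd[b, ])
        if (ta < tb) a
        else if (tb < ta) b
        else max(a, b)   # tie: remove the lexicographically larger label
      }
      keep <- setdiff(keep, drop_tx)
      dd <- dd[keep, keep, drop = FALSE]
    }
    keep
  }
  res <- if (mode == "random") with_stream(seed, "diversity_subsample", run())
         else run()
  sort(res)
}

#' Group-wise diversity subsampling
#'
#' Applies [diversity_subsample()] independently to each group's own tree
#' (matching per-group phylogenies built separately); groups at or below the
#' target size are kept whole.
#'
#' @param group_trees Named list of `"phylo"` trees, one per group.
#' @param per_group_target Representatives to retain per group.
#' @param mode,seed Passed to [diversity_subsample()].
#' @return Named list of retained taxon vectors, one per group.
#' @export
subsample_groups <- function(group_trees, per_group_target,
                             mode = c("deterministic", "random"), seed = 1L) {
  mode <- match.arg(mode)
  if (!length(group_trees)) stop("no groups supplied")
  if (is.null(names(group_trees))) stop("group trees must be named")
  out <- vector("list", length(group_trees))
  names(out) <- names(group_trees)
  for (g in names(group_trees)) {
    tr <- group_trees[[g]]
    if (is.null(tr) || !inherits(tr, "phylo") || !length(tr$tip.label)) {
      stop("empty group: ", g)
    }
    out[[g]] <- if (length(tr$tip.label) <= per_group_target) {
      sort(tr$tip.label)
    } else {
      diversity_subsample(tr, per_group_target, mode = mode,
                          seed = derive_seed(seed, g))
    }
  }
  out
}

#' Read a taxon-to-group map
#'
#' @param path Two-column TSV (taxon, group), no header required; a header
#'   line `taxon<TAB>group` is tolerated.
#' @return Named character vector mapping taxon to group.
#' @export
read_group_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("group map needs two columns (taxon, group)")
  if (identical(tolower(df[1, 1]), "taxon")) df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
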