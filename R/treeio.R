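# Reading, writing and interrogating phylogenetic trees and MCMC tree
# samples.  Trees are plain ape "phylo" objects; a tree sample is a light
# wrapper around a "multiPhylo" list that records burn-in metadata and
# enforces a single taxon namespace.

## ---- Newick / NEXUS parsing --------------------------------------------

# Remove [...] comment blocks (including BEAST/MrBayes [&...] annotations)
# outside quoted labels.  Quote-aware: brackets inside '...' are preserved.
strip_tree_comments <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, length(chars))
  in_quote <- FALSE
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == "'") in_quote <- FALSE
      next
    }
    if (depth == 0L && ch == "'") {
      in_quote <- TRUE
      next
    }
    if (ch == "[") {
      depth <- depth + 1L
      keep[i] <- FALSE
    } else if (ch == "]") {
      if (depth > 0L) {
        depth <- depth - 1L
        keep[i] <- FALSE
      }
    } else if (depth > 0L) {
      keep[i] <- FALSE
    }
  }
  paste(chars[keep], collapse = "")
}

# Validate parenthesis balance outside quotes; returns NULL if fine, else the
# 1-based character offset of the first offending character.
newick_paren_error <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == "'") in_quote <- FALSE
      next
    }
    if (ch == "'") in_quote <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(length(chars))
  NULL
}

# Strip surrounding single quotes from labels and undo '' escaping.
unquote_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Parse a Newick string into a phylogenetic tree
#'
#' Wraps [ape::read.tree()] with the conventions used throughout the package:
#' `[...]` comments (including BEAST-style `[&...]` annotations) are stripped,
#' quoted labels are unquoted (`'PLV BS_539'` becomes `PLV BS_539`), and
#' malformed parentheses are reported with their character offset.
#' Underscores are kept literal, not converted to spaces.
#'
#' @param text A single Newick string terminated by `;`.
#' @return An object of class `"phylo"`. The tree is rooted (in the
#'   [ape::is.rooted()] sense) iff its basal node is binary.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- strip_tree_comments(text)
  off <- newick_paren_error(clean)
  if (!is.null(off)) {
    stop("malformed Newick: unbalanced parenthesis at character ", off)
  }
  if (!grepl(";", clean, fixed = TRUE)) {
    stop("malformed Newick: no terminating ';' found")
  }
  phy <- tryCatch(
    ape::read.tree(text = clean),
    error = function(e) stop("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(phy)) stop("Newick parse error: ape could not read the string")
  phy$tip.label <- unquote_label(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- unquote_label(phy$node.label)
  if (any(!nzchar(phy$tip.label))) stop("empty taxon label in tree")
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate taxon labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  phy
}

# Quote a label for Newick output when it contains characters outside the
# safe set; embedded quotes are doubled.
quote_label <- function(x) {
  needs <- grepl("[][ ()':;,]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write a tree as a Newick string
#'
#' Emits labels quoted whenever they contain Newick metacharacters or spaces,
#' so that `parse_newick(write_newick(t))` round-trips topology, labels and
#' branch lengths exactly. Branch-length fields are omitted for trees that
#' carry none.
#'
#' @param tree A `"phylo"` object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  labs <- quote_label(tree$tip.label)
  emit <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- labs[node]
    } else {
      rows <- kids[[as.character(node)]]
      s <- paste0("(", paste(vapply(rows, function(r) {
        emit(tree$edge[r, 2], r)
      }, character(1)), collapse = ","), ")")
    }
    if (has_len && !is.na(edge_idx)) {
      s <- paste0(s, ":", sprintf("%.*g", digits,
                                  tree$edge.length[edge_idx]))
    }
    s
  }
  paste0(emit(root, NA_integer_), ";")
}

## ---- Tree samples -------------------------------------------------------

#' Construct a tree sample
#'
#' An ordered collection of trees from one MCMC run, on one shared taxon
#' namespace. A taxon-set mismatch between trees is an error (all downstream
#' counting assumes a single namespace).
#'
#' @param trees A `"multiPhylo"` object or list of `"phylo"` trees.
#' @param burnin_fraction Fraction of leading trees regarded as burn-in
#'   (in `[0, 1)`); informational until [apply_burnin()] is called.
#' @param source Free-text provenance tag.
#' @return An object of class `"tree_sample"` with elements `trees`,
#'   `burnin_fraction`, `source`.
#' @export
tree_sample <- function(trees, burnin_fraction = 0, source = "") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("tree_sample: empty tree list")
  if (!all(vapply(trees, inherits, logical(1), "phylo"))) {
    stop("tree_sample: all elements must be 'phylo' trees")
  }
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must be in [0, 1)")
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("tree ", i, " has a different taxon set from tree 1")
    }
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, burnin_fraction = burnin_fraction,
                 source = source),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample:", length(x$trees), "trees on",
      length(x$trees[[1]]$tip.label), "taxa;",
      "burn-in fraction", x$burnin_fraction, "\n")
  if (nzchar(x$source)) cat("source:", x$source, "\n")
  invisible(x)
}

#' Number of trees in a sample
#' @param sample A `"tree_sample"`.
#' @return Integer count.
#' @export
n_trees <- function(sample) length(sample$trees)

#' Discard burn-in trees
#'
#' Drops the first `floor(fraction * N)` trees and keeps the rest in order.
#' Counts in deposited posterior files (for example 28,001 trees from a
#' 140M-generation chain sampled every 5,000 generations with 25% relative
#' burn-in) are treated as properties of the input file; the package never
#' recomputes them from chain settings.
#'
#' @param sample A `"tree_sample"`.
#' @param fraction Burn-in fraction in `[0, 1)`; defaults to the fraction
#'   stored on the sample.
#' @return A `"tree_sample"` with `burnin_fraction = 0`.
#' @export
apply_burnin <- function(sample, fraction = sample$burnin_fraction) {
  stopifnot(inherits(sample, "tree_sample"))
  if (fraction < 0 || fraction >= 1) stop("burn-in fraction must be in [0, 1)")
  n <- length(sample$trees)
  drop <- floor(fraction * n)
  kept <- sample$trees[(drop + 1L):n]
  class(kept) <- "multiPhylo"
  structure(list(trees = kept, burnin_fraction = 0, source = sample$source),
            class = "tree_sample")
}

#' Parse a NEXUS TREES block into a tree sample
#'
#' Understands the BEAST 2 / MrBayes output dialects: an optional `Translate`
#' table mapping indices to labels, `[&...]` metadata comments (stripped), and
#' one `tree NAME = ...;` statement per tree. Tree order is preserved.
#'
#' @param text NEXUS file content as a single string or a character vector of
#'   lines.
#' @param burnin_fraction Burn-in fraction to record on the sample.
#' @param source Provenance tag; defaults to `"nexus"`.
#' @return A `"tree_sample"`.
#' @export
parse_nexus_trees <- function(text, burnin_fraction = 0, source = "nexus") {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  clean <- strip_tree_comments(text)
  m <- regexpr("(?is)begin\\s+trees\\s*;.*?\\bend\\s*;", clean, perl = TRUE)
  if (m == -1L) stop("NEXUS input has no TREES block")
  block <- regmatches(clean, m)

  translate <- NULL
  tm <- regexpr("(?is)\\btranslate\\b(.*?);", block, perl = TRUE)
  if (tm != -1L) {
    body <- sub("(?is)^\\btranslate\\b", "", regmatches(block, tm), perl = TRUE)
    body <- sub(";\\s*$", "", body)
    entries <- strsplit(body, ",")[[1]]
    entries <- trimws(entries)
    entries <- entries[nzchar(entries)]
    idx <- sub("^(\\S+)\\s+.*$", "\\1", entries)
    lab <- unquote_label(sub("^\\S+\\s+", "", entries))
    translate <- stats::setNames(lab, idx)
  }

  tree_stmts <- regmatches(
    block,
    gregexpr("(?is)\\btree\\s+[^=]+=\\s*[^;]*;", block, perl = TRUE)
  )[[1]]
  if (!length(tree_stmts)) stop("TREES block contains no tree statements")
  trees <- lapply(tree_stmts, function(s) {
    nwk <- sub("(?is)^\\s*tree\\s+[^=]+=\\s*", "", s, perl = TRUE)
    nwk <- sub("^\\s*\\&?[RU]?\\s*", "", nwk)  # leftover rooting token
    phy <- parse_newick(nwk)
    if (!is.null(translate)) {
      hit <- match(phy$tip.label, names(translate))
      if (anyNA(hit)) {
        stop("translate index undefined for tip(s): ",
             paste(phy$tip.label[is.na(hit)], collapse = ", "))
      }
      phy$tip.label <- unname(translate[hit])
    }
    phy
  })
  tree_sample(trees, burnin_fraction = burnin_fraction, source = source)
}

#' Read a tree sample from a file
#'
#' @param path Path to a NEXUS `.trees` file or a plain Newick file (one tree
#'   per line).
#' @param format `"auto"` (sniff for `#NEXUS`), `"nexus"` or `"newick"`.
#' @param burnin_fraction Burn-in fraction to record.
#' @return A `"tree_sample"`.
#' @export
read_tree_sample <- function(path, format = c("auto", "nexus", "newick"),
                             burnin_fraction = 0) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^\\s*#NEXUS", lines[seq_len(min(5, length(lines)))],
                            ignore.case = TRUE))) "nexus" else "newick"
  }
  if (format == "nexus") {
    parse_nexus_trees(lines, burnin_fraction = burnin_fraction, source = path)
  } else {
    lines <- lines[grepl(";", lines, fixed = TRUE)]
    if (!length(lines)) stop("no Newick trees found in ", path)
    tree_sample(lapply(lines, parse_newick),
                burnin_fraction = burnin_fraction, source = path)
  }
}

#' Write a tree sample as a NEXUS TREES block with a translate table
#'
#' @param sample A `"tree_sample"`.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return The NEXUS text, invisibly when written to a file.
#' @export
write_nexus_trees <- function(sample, path = NULL) {
  stopifnot(inherits(sample, "tree_sample"))
  taxa <- sort(sample$trees[[1]]$tip.label)
  idx <- stats::setNames(seq_along(taxa), taxa)
  lines <- c("#NEXUS", "begin trees;", "\ttranslate",
             paste0("\t\t", idx, " ", quote_label(taxa),
                    ifelse(seq_along(taxa) < length(taxa), ",", ";")))
  for (i in seq_along(sample$trees)) {
    tr <- sample$trees[[i]]
    tr$tip.label <- as.character(idx[tr$tip.label])
    lines <- c(lines, paste0("tree STATE_", i - 1L, " = ", write_newick(tr)))
  }
  lines <- c(lines, "end;")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

## ---- Bipartitions and distances ----------------------------------------

# Canonical key for the split separating `side` from the rest of `taxa`:
# the stored side is the one containing the lexicographically smallest taxon
# label; members are sorted and joined with "|".
split_key <- function(side, taxa) {
  side <- sort(side)
  other <- sort(setdiff(taxa, side))
  if (!length(side) || !length(other)) {
    stop("trivial split: both sides must be non-empty")
  }
  canon <- if (side[1] < other[1]) side else other
  paste(canon, collapse = "|")
}

# Leaf-label sets below each internal node (root excluded), as a list.
node_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (r in seq_len(nrow(post$edge))) {
    par <- post$edge[r, 1]; chd <- post$edge[r, 2]
    sets[[par]] <- c(sets[[par]], sets[[chd]])
  }
  internal <- (ntip + 1L):(ntip + nnode)
  internal <- internal[internal != ntip + 1L]  # drop root (full taxon set)
  lapply(internal, function(i) sets[[i]])
}

#' Non-trivial bipartitions of a tree
#'
#' Returns the set of splits induced by the internal edges, in the canonical
#' string form produced by the package (the stored side is the one holding
#' the lexicographically smallest taxon; members sorted, joined by `|`).
#' For a fully resolved unrooted tree on `n` taxa the count is `n - 3`.
#'
#' @param tree A `"phylo"` object.
#' @return A sorted character vector of canonical split keys (possibly empty).
#' @export
bipartitions <- function(tree) {
  taxa <- tree$tip.label
  n <- length(taxa)
  keys <- character(0)
  for (cl in node_clades(tree)) {
    if (length(cl) >= 2 && length(cl) <= n - 2) {
      keys <- c(keys, split_key(cl, taxa))
    }
  }
  sort(unique(keys))
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between each pair of leaves, via
#' [ape::cophenetic.phylo()].
#'
#' @param tree A `"phylo"` with a complete set of branch lengths.
#' @return A symmetric numeric matrix with zero diagonal, rows and columns
#'   named by taxon.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  bad <- which(is.na(tree$edge.length))
  if (length(bad)) {
    chd <- tree$edge[bad[1], 2]
    what <- if (chd <= length(tree$tip.label)) {
      paste0("leaf '", tree$tip.label[chd], "'")
    } else paste0("internal node ", chd)
    stop("missing branch length on the edge above ", what)
  }
  ape::cophenetic.phylo(tree)
}
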