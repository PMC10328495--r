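# Shared fixtures and independent oracles used across the test files.
# Oracles deliberately take a different computational path from the package
# (exhaustive enumeration, graph search, matrix exponentials via Matrix).

# Random binary tree with moderate branch lengths.
rand_bin_tree <- function(n, seed, rooted = TRUE, mean_len = 0.3) {
  set.seed(seed)
  tr <- ape::rtree(n)
  if (!rooted) tr <- ape::unroot(tr)
  tr$edge.length <- stats::rgamma(nrow(tr$edge), 2, 2 / mean_len)
  tr
}

# Random valid reversible amino-acid model.
rand_model <- function(seed, gamma = TRUE, pinv = 0) {
  set.seed(seed)
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- stats::runif(190, 0.05, 2)
  s <- s + t(s)
  dimnames(s) <- list(cladetest:::AA_ALPHABET, cladetest:::AA_ALPHABET)
  f <- stats::rgamma(20, 5, 1)
  f <- f / sum(f)
  subst_model(s, f,
              gamma_shape = if (gamma) stats::runif(1, 0.4, 2) else NULL,
              n_categories = 2L, p_invariant = pinv)
}

# Exhaustive ancestral-state summation: the brute-force likelihood oracle.
# Transition matrices come from Matrix::expm, independent of the package's
# eigendecomposition.
brute_force_loglik <- function(tree, aln, model) {
  post <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(post$tip.label)
  nnode <- post$Nnode
  alpha <- cladetest:::AA_ALPHABET
  code <- match(toupper(aln[post$tip.label, , drop = FALSE]), alpha)
  dim(code) <- c(ntip, ncol(aln))
  q <- build_rate_matrix(model)
  rates <- cladetest:::model_category_rates(model)
  pinv <- model$p_invariant
  grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
  total <- 0
  P_all <- lapply(seq_along(rates), function(c) {
    lapply(post$edge.length, function(t) {
      as.matrix(Matrix::expm(q * rates[c] * t))
    })
  })
  for (s in seq_len(ncol(aln))) {
    liks <- vapply(seq_along(rates), function(c) {
      pr <- model$freqs[grid[, 1]]  # root is internal node 1 (ntip + 1)
      for (e in seq_len(nrow(post$edge))) {
        par <- post$edge[e, 1]; chd <- post$edge[e, 2]
        ps <- grid[, par - ntip]
        if (chd <= ntip) {
          obs <- code[chd, s]
          if (is.na(obs)) next  # missing data: sums over child states = 1
          pr <- pr * P_all[[c]][[e]][cbind(ps, obs)]
        } else {
          pr <- pr * P_all[[c]][[e]][cbind(ps, grid[, chd - ntip])]
        }
      }
      sum(pr)
    }, numeric(1))
    res <- unique(code[, s])
    res <- res[!is.na(res)]
    invl <- if (!length(res)) 1 else if (length(res) == 1L) {
      unname(model$freqs[res])
    } else 0
    total <- total +
      log((1 - pinv) / length(rates) * sum(liks) + pinv * invl)
  }
  total
}

# Patristic distances by breadth-first search on the edge graph.
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    dist <- rep(NA_real_, nn)
    dist[i] <- 0
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + adj[[v]][k, 2]
          queue <- c(queue, u)
        }
      }
    }
    d[i, ] <- dist[seq_len(ntip)]
  }
  d
}

# Sum of pairwise patristic distances within a taxon subset.
subset_diversity <- function(dmat, taxa) {
  sum(dmat[taxa, taxa]) / 2
}

# Exhaustive best subset of given size by total pairwise distance.
exhaustive_best_subset <- function(dmat, size) {
  taxa <- rownames(dmat)
  combos <- utils::combn(taxa, size, simplify = FALSE)
  best <- -Inf
  for (cc in combos) {
    v <- subset_diversity(dmat, cc)
    if (v > best) best <- v
  }
  best
}

# Independent MCC scorer: clade frequency table via sorted label strings.
oracle_mcc_scores <- function(trees) {
  n <- length(trees[[1]]$tip.label)
  keysets <- lapply(trees, function(tr) {
    cls <- cladetest:::node_clades(tr)
    keep <- vapply(cls, function(cl) length(cl) >= 2 && length(cl) < n,
                   logical(1))
    unique(vapply(cls[keep], function(cl) paste(sort(cl), collapse = "|"),
                  character(1)))
  })
  freq <- table(unlist(keysets)) / length(trees)
  vapply(keysets, function(k) sum(log(freq[k])), numeric(1))
}

# Small helper: write a temp file of lines and return the path.
tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
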