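# Substitution models, alignments, the pruning engine, branch-length
# optimisation and the exhaustive constrained search.

test_that("the bundled LG matrix is valid and matches the reference copy", {
  lg <- read_paml_matrix()
  expect_equal(lg$rates, t(lg$rates))
  expect_true(all(diag(lg$rates) == 0))
  expect_equal(sum(lg$freqs), 1, tolerance = 1e-9)
  # independent copy shipped with phangorn
  env <- new.env()
  eval(quote(phangorn:::getModelAA("LG", bf = TRUE, Q = TRUE)), env)
  ref <- matrix(0, 20, 20)
  ref[lower.tri(ref)] <- get("Q", env)
  ref <- ref + t(ref)
  expect_equal(unname(lg$rates), ref, tolerance = 1e-5)
  expect_equal(unname(lg$freqs), unname(get("bf", env)), tolerance = 1e-5)
})

test_that("rate matrices are proper scaled reversible generators", {
  # uniform model: all off-diagonal rates equal 1/19 after scaling
  u <- matrix(1, 20, 20); diag(u) <- 0
  dimnames(u) <- list(cladetest:::AA_ALPHABET, cladetest:::AA_ALPHABET)
  um <- subst_model(u, rep(1 / 20, 20), gamma_shape = NULL)
  qu <- build_rate_matrix(um)
  expect_equal(unique(round(qu[row(qu) != col(qu)], 12)), 1 / 19)

  for (seed in 1:5) {
    m <- rand_model(seed)
    q <- build_rate_matrix(m)
    expect_equal(unname(rowSums(q)), rep(0, 20), tolerance = 1e-12)
    expect_equal(-sum(m$freqs * diag(q)), 1, tolerance = 1e-12)
    # stationarity and detailed balance
    expect_equal(as.numeric(m$freqs %*% q), rep(0, 20), tolerance = 1e-12)
    flux <- unname(m$freqs * q)
    expect_equal(flux, t(flux), tolerance = 1e-12)
  }
})

test_that("discrete gamma uses mean-rate equal-probability slices", {
  expect_equal(discrete_gamma(0.5, 1), 1)
  expect_equal(discrete_gamma(1e6, 4), rep(1, 4), tolerance = 1e-3)
  r <- discrete_gamma(0.5, 4)
  expect_equal(mean(r), 1, tolerance = 1e-12)
  expect_true(all(diff(r) > 0))
  # quadrature oracle for each slice mean
  shape <- 0.5
  bounds <- qgamma(seq(0, 1, 0.25), shape, rate = shape)
  for (k in 1:4) {
    num <- integrate(function(x) x * dgamma(x, shape, rate = shape),
                     bounds[k], bounds[k + 1], rel.tol = 1e-10)$value
    expect_equal(r[k], num * 4, tolerance = 1e-6)
  }
})

test_that("transition probabilities behave like a semigroup", {
  m <- rand_model(3)
  q <- build_rate_matrix(m)
  expect_equal(unname(transition_probs(q, 0, m$freqs)), diag(20),
               tolerance = 1e-12)
  p_inf <- transition_probs(q, 500, m$freqs)
  for (i in 1:20) expect_equal(unname(p_inf[i, ]), unname(m$freqs),
                               tolerance = 1e-9)
  p1 <- transition_probs(q, 0.3, m$freqs)
  p2 <- transition_probs(q, 0.45, m$freqs)
  expect_equal(unname(p1 %*% p2),
               unname(transition_probs(q, 0.75, m$freqs)),
               tolerance = 1e-10)
  expect_equal(unname(rowSums(p1)), rep(1, 20), tolerance = 1e-12)
  expect_error(transition_probs(q, -1, m$freqs), ">= 0")
})

test_that("alignment concatenation records partitions and fills gaps", {
  m <- lg_model(NULL)
  a1 <- aa_alignment(list(A = strrep("ACD", 10), B = strrep("ACD", 10)))
  a2 <- aa_alignment(list(A = strrep("WY", 5), C = strrep("WY", 5)))
  cc <- concatenate_alignments(list(one = a1, two = a2), m)
  expect_equal(ncol(cc$alignment), 40)
  expect_equal(cc$scheme$start, c(0L, 30L))
  expect_equal(cc$scheme$end, c(30L, 40L))
  expect_equal(unique(cc$alignment["B", 31:40]), "-")
  expect_equal(unique(cc$alignment["C", 1:30]), "-")
  expect_error(concatenate_alignments(list(), m), "no alignment")
})

test_that("partition maps convert 1-based inclusive to half-open ranges", {
  f <- tmp_lines(c("# comment", "capsid = 1-120", "protease = 121-200"))
  sch <- read_partition_map(f, lg_model(NULL))
  expect_equal(sch$start, c(0L, 120L))
  expect_equal(sch$end, c(120L, 200L))
  expect_error(read_partition_map(tmp_lines("bad line"), lg_model(NULL)),
               "unparseable")
})

test_that("two-taxon identical-residue likelihood has its closed form", {
  m <- lg_model(NULL)  # no gamma, no invariant class
  tr <- parse_newick("(A:0.2,B:0.3);")
  aln <- aa_alignment(list(A = "W", B = "W"))
  q <- build_rate_matrix(m)
  p <- transition_probs(q, 0.5, m$freqs)
  expect_equal(tree_log_likelihood(tr, aln, m),
               log(m$freqs[["W"]] * p["W", "W"]), tolerance = 1e-10)
})

test_that("pruning equals brute-force state summation on small trees", {
  for (seed in 1:8) {
    n <- sample(2:4, 1)
    tr <- rand_bin_tree(n, seed)
    m <- rand_model(seed, pinv = if (seed %% 2) 0.2 else 0)
    aln <- simulate_alignment(tr, m, 6, seed = seed)
    expect_equal(tree_log_likelihood(tr, aln, m),
                 brute_force_loglik(tr, aln, m), tolerance = 1e-8)
  }
})

test_that("gaps and ambiguity codes act as missing data", {
  m <- lg_model(NULL)
  tr <- parse_newick("((A:0.1,B:0.2):0.1,C:0.3);")
  full <- aa_alignment(list(A = "W", B = "-", C = "X"))
  only_a <- aa_alignment(list(A = "W", B = "-", C = "-"))
  # B and C unobserved: likelihood is the marginal of A's single residue
  expect_equal(tree_log_likelihood(tr, full, m), log(m$freqs[["W"]]),
               tolerance = 1e-9)
  expect_equal(tree_log_likelihood(tr, only_a, m), log(m$freqs[["W"]]),
               tolerance = 1e-9)
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  for (seed in 1:5) {
    tr <- rand_bin_tree(6, seed)
    m <- rand_model(seed + 50, pinv = 0.1)
    aln <- simulate_alignment(tr, m, 50, seed = seed)
    ll <- tree_log_likelihood(tr, aln, m)
    set.seed(seed)
    node <- sample(setdiff(2:(6 + tr$Nnode), 7), 1)  # any non-root node
    pos <- tr$edge.length[which(tr$edge[, 2] == node)] / 2
    rr <- phytools::reroot(tr, node, position = pos)
    expect_equal(tree_log_likelihood(rr, aln, m), ll, tolerance = 1e-6)
  }
})

test_that("partitioned likelihood is additive over blocks", {
  tr <- rand_bin_tree(5, 4)
  m1 <- lg_model(gamma_shape = 0.8)
  m2 <- lg_model(NULL, p_invariant = 0.3)
  aln <- simulate_alignment(tr, m1, 120, seed = 9)
  one <- partition_scheme("all", 0L, 120L, m1)
  expect_equal(partitioned_log_likelihood(tr, aln, one),
               tree_log_likelihood(tr, aln, m1), tolerance = 1e-9)

  # two identical blocks: exactly twice the single-block value
  double <- aa_alignment(cbind(unclass(aln), unclass(aln)))
  two <- partition_scheme(c("a", "b"), c(0L, 120L), c(120L, 240L), m1)
  expect_equal(partitioned_log_likelihood(tr, double, two),
               2 * tree_log_likelihood(tr, aln, m1), tolerance = 1e-9)

  # four blocks, mixed models: additivity against block-wise computation
  quad <- partition_scheme(paste0("p", 1:4), c(0L, 30L, 60L, 90L),
                           c(30L, 60L, 90L, 120L),
                           list(m1, m2, m1, m2))
  manual <- sum(vapply(1:4, function(i) {
    blk <- aa_alignment(unclass(aln)[, (quad$start[i] + 1):quad$end[i],
                                     drop = FALSE])
    tree_log_likelihood(tr, blk, quad$models[[i]])
  }, numeric(1)))
  expect_equal(partitioned_log_likelihood(tr, aln, quad), manual,
               tolerance = 1e-8)
  bad <- partition_scheme("short", 0L, 100L, m1)
  expect_error(partitioned_log_likelihood(tr, aln, bad), "cover")
})

test_that("branch-length optimisation improves monotonically and converges", {
  m <- lg_model(gamma_shape = 1)
  tr <- rand_bin_tree(5, 21, mean_len = 0.25)
  aln <- simulate_alignment(tr, m, 400, seed = 21)
  start <- tr; start$edge.length <- rep(0.3, nrow(tr$edge))
  fit <- optimize_branch_lengths(start, aln, m)
  expect_false(is.unsorted(fit$trajectory))
  expect_gte(fit$logL, fit$trajectory[1])
  # re-optimising an optimum changes nothing appreciable
  again <- optimize_branch_lengths(fit$tree, aln, m)
  expect_lt(again$logL - fit$logL, 0.01)
  # and beats the likelihood at the true lengths (ML property)
  expect_gte(fit$logL + 1e-6, tree_log_likelihood(tr, aln, m))
})

test_that("optimised lengths recover the simulation truth", {
  m <- lg_model(gamma_shape = 1)
  tr <- rand_bin_tree(6, 31, mean_len = 0.25)
  aln <- simulate_alignment(tr, m, 2000, seed = 31)
  fit <- optimize_branch_lengths(tr, aln, m)
  # compare patristic paths on the unrooted shape: root-adjacent branches
  # are only identifiable through their sum
  d_true <- patristic_matrix(ape::unroot(tr))
  d_est <- patristic_matrix(ape::unroot(fit$tree))
  rel <- abs(d_est[rownames(d_true), colnames(d_true)] - d_true) /
    pmax(d_true, 0.05)
  expect_lt(max(rel[upper.tri(rel)]), 0.15)
})

test_that("constrained search counts topologies and respects the filter", {
  m <- lg_model(NULL)
  tr <- parse_newick("((A:0.2,B:0.2):0.2,(C:0.2,D:0.2):0.2);")
  aln <- simulate_alignment(tr, m, 150, seed = 2)
  pos <- constrained_best_tree(aln, m, c("A", "B"))
  expect_equal(pos$n_candidates, 1L)  # 1 of the 3 quartet topologies
  neg <- constrained_best_tree(aln, m, c("A", "B"), negative = TRUE)
  expect_equal(neg$n_candidates, 2L)
  expect_lte(neg$logL, pos$logL + 1e-6)  # truth satisfies the constraint
  expect_true(is_monophyletic(pos$tree, c("A", "B")))
  expect_false(is_monophyletic(neg$tree, c("A", "B")))
  expect_equal(pos$K, count_free_params(pos$tree, m))
  # the full taxon set is monophyletic on every topology, so its negation
  # leaves nothing to search
  expect_error(constrained_best_tree(aln, m, c("A", "B", "C", "D"),
                                     negative = TRUE),
               "unsatisfiable")
})

test_that("free-parameter accounting follows the documented rule", {
  tr <- rand_bin_tree(6, 1)
  e <- nrow(tr$edge)
  expect_equal(count_free_params(tr, lg_model(NULL)), e)
  expect_equal(count_free_params(tr, lg_model(1)), e + 1L)
  expect_equal(count_free_params(tr, lg_model(1, p_invariant = 0.1)), e + 2L)
  f <- lg_model(1, frequencies = rep(0.05, 20))
  expect_equal(count_free_params(tr, f), e + 20L)
  sch <- partition_scheme(c("a", "b"), c(0L, 10L), c(10L, 20L),
                          list(lg_model(1), lg_model(NULL)))
  expect_equal(count_free_params(tr, sch), e + 1L)
})

test_that("model specification strings parse to the right structure", {
  m <- parse_model_spec("LG+G4+I", gamma_shape = 0.7, p_invariant = 0.15)
  expect_equal(m$n_categories, 4L)
  expect_equal(m$p_invariant, 0.15)
  expect_false(m$plus_f)
  plain <- parse_model_spec("LG")
  expect_null(plain$gamma_shape)
  expect_error(parse_model_spec("WAG+G4"), "LG family")
  expect_error(parse_model_spec("LG+G4+F"), "requires observed")
  aln <- aa_alignment(list(A = "AAAW", B = "AAWW"))
  mf <- parse_model_spec("LG+G4+F", frequencies = empirical_aa_freqs(aln))
  expect_true(mf$plus_f)
  expect_equal(sum(mf$freqs), 1, tolerance = 1e-12)
  # pseudo-counts keep absent residues non-zero
  expect_true(all(empirical_aa_freqs(aln) > 0))
})
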