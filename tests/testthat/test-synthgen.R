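# Synthetic-data generators: validity, reproducibility, and agreement with
# the analytic properties of the processes they emulate.

test_that("pure-birth trees are valid, reproducible and correctly sized", {
  cherry <- simulate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(cherry), 2L)
  expect_true(ape::is.rooted(cherry))

  tr <- simulate_yule_tree(9, seed = 3)
  expect_equal(ape::Ntip(tr), 9L)
  expect_equal(tr$Nnode, 8L)  # n - 1 internal nodes
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(write_newick(simulate_yule_tree(9, seed = 3)),
                   write_newick(tr))
  expect_false(identical(write_newick(simulate_yule_tree(9, seed = 4)),
                         write_newick(tr)))
})

test_that("mean pure-birth root height matches the analytic expectation", {
  lambda <- 2
  n <- 8
  heights <- vapply(1:600, function(s) {
    max(ape::node.depth.edgelength(simulate_yule_tree(n, lambda, seed = s)))
  }, numeric(1))
  expected <- sum(1 / (lambda * (2:n)))
  se <- stats::sd(heights) / sqrt(length(heights))
  expect_lt(abs(mean(heights) - expected), 3 * se)
})

test_that("simulated alignments honour the model's degenerate limits", {
  tr <- rand_bin_tree(5, 8)
  all_inv <- subst_model(read_paml_matrix()$rates, read_paml_matrix()$freqs,
                         gamma_shape = NULL, p_invariant = 0.999999)
  aln <- simulate_alignment(tr, all_inv, 40, seed = 1)
  expect_true(all(apply(unclass(aln), 2, function(col) length(unique(col))) == 1))

  star <- parse_newick("(A:0,B:0,C:0,D:0);")
  a0 <- simulate_alignment(star, lg_model(NULL), 30, seed = 2)
  expect_equal(unclass(a0)[1, ], unclass(a0)[3, ])

  expect_identical(simulate_alignment(tr, lg_model(1), 25, seed = 9),
                   simulate_alignment(tr, lg_model(1), 25, seed = 9))
})

test_that("long-branch simulation reaches the stationary frequencies", {
  tr <- parse_newick("(A:40,B:40);")
  m <- lg_model(NULL)
  aln <- simulate_alignment(tr, m, 4000, seed = 5)
  counts <- table(factor(unclass(aln)["B", ], levels = cladetest:::AA_ALPHABET))
  p <- stats::chisq.test(as.numeric(counts), p = m$freqs)$p.value
  expect_gt(p, 0.001)
})

test_that("tree samples hit the requested clade frequency exactly at 0 and 1", {
  taxa <- paste0("t", 1:7)
  hyp <- clade_hypothesis("s", list(c("t1", "t2"), c("t3", "t4")),
                          "sister_group")
  s1 <- simulate_tree_sample(taxa, hyp, 1, 30, seed = 1)
  expect_true(all(vapply(s1$trees, is_sister_group, logical(1),
                         set_a = c("t1", "t2"), set_b = c("t3", "t4"))))
  s0 <- simulate_tree_sample(taxa, hyp, 0, 30, seed = 2)
  expect_false(any(vapply(s0$trees, is_sister_group, logical(1),
                          set_a = c("t1", "t2"), set_b = c("t3", "t4"))))
  expect_error(simulate_tree_sample(c("a", "b"), c("a", "b"), 0.5, 5),
               "impossible")
  # reproducibility
  expect_identical(write_nexus_trees(simulate_tree_sample(taxa, hyp, 0.5, 10,
                                                          seed = 3)),
                   write_nexus_trees(simulate_tree_sample(taxa, hyp, 0.5, 10,
                                                          seed = 3)))
})

test_that("intermediate clade frequencies match the binomial expectation", {
  taxa <- paste0("t", 1:8)
  s <- simulate_tree_sample(taxa, c("t1", "t2"), 0.2, 600, seed = 11)
  o <- posterior_model_odds(s, clade_hypothesis("c", list(c("t1", "t2")),
                                                "monophyly"))
  ci <- stats::qbinom(c(0.005, 0.995), 600, 0.2)
  expect_gte(o$n_consistent, ci[1])
  expect_lte(o$n_consistent, ci[2])
})

test_that("root samples follow the requested placement distribution", {
  base <- ape::unroot(rand_bin_tree(7, 13))
  taxa <- base$tip.label
  one <- simulate_root_sample(base, list(list(placement = taxa[1],
                                              probability = 1)),
                              50, seed = 1)
  tab <- root_frequency_table(one)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$frequency, 1)
  expect_equal(sum(root_frequency_table(one)$frequency), 1)

  # {t4, t5} does not sit on one side of any edge of this tree
  expect_false(cladetest:::split_key(c("t4", "t5"), taxa) %in%
                 bipartitions(base))
  expect_error(simulate_root_sample(base,
                                    list(list(placement = c("t4", "t5"),
                                              probability = 1)), 5),
               "not an edge")
  expect_error(simulate_root_sample(base,
                                    list(list(placement = taxa[1],
                                              probability = 0.4)), 5),
               "sum to 1")
})

test_that("simulated marginal runs respect their documented structure", {
  df <- simulate_marginal_runs(-1234.5, 0, 4, seed = 2)
  expect_equal(df$log_marginal, rep(-1234.5, 4))
  expect_equal(combine_log_marginals(df$log_marginal), -1234.5)
  noisy <- simulate_marginal_runs(-1234.5, 8, 6, seed = 3)
  comb <- combine_log_marginals(noisy$log_marginal)
  expect_lte(comb, max(noisy$log_marginal))
  expect_gte(comb, max(noisy$log_marginal) - log(6))
  expect_identical(noisy, simulate_marginal_runs(-1234.5, 8, 6, seed = 3))
})

test_that("simulation recovers the generating topology as ML (round trip)", {
  m <- lg_model(gamma_shape = 1)
  hits <- 0
  for (seed in 1:2) {
    taxa <- paste0("t", 1:6)
    truth <- simulate_tree_sample(taxa, c("t1", "t2"), 1, 1, seed = seed)$trees[[1]]
    aln <- simulate_alignment(truth, m, 2000, seed = seed)
    # topology recovery needs ranking, not polished lengths: cheap controls
    best <- constrained_best_tree(aln, m, "t1",  # singleton: no restriction
                                  fine = list(max_sweeps = 2, tol = 1e-2,
                                              opt_tol = 1e-2),
                                  refine_top = 1L)
    if (setequal(bipartitions(ape::unroot(truth)), bipartitions(best$tree))) {
      hits <- hits + 1
    }
  }
  expect_equal(hits, 2)
})
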