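# Topology predicates, posterior model odds, root-placement tables, MCC
# selection and outgroup rooting.

test_that("monophyly works on rooted and unrooted trees", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, "A"))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "not in tree")

  un <- parse_newick("((A,B),(C,D),E);")
  expect_true(is_monophyletic(un, c("C", "D")))
  expect_false(is_monophyletic(un, c("B", "C")))
})

test_that("monophyly agrees with split membership on random trees", {
  for (seed in 1:10) {
    tr <- rand_bin_tree(12, seed, rooted = FALSE)
    splits <- bipartitions(tr)
    taxa <- tr$tip.label
    set.seed(seed + 100)
    for (k in c(2, 3, 5)) {
      sub <- sample(taxa, k)
      expect_identical(is_monophyletic(tr, sub),
                       cladetest:::split_key(sub, taxa) %in% splits)
    }
    # every actual split must test monophyletic (take first side of key)
    sub <- strsplit(splits[1], "|", fixed = TRUE)[[1]]
    expect_true(is_monophyletic(tr, sub))
  }
})

test_that("sister grouping requires both clades and their union", {
  yes <- parse_newick("(((A1,A2),(N1,N2)),(V1,V2));")
  no <- parse_newick("(((A1,N1),(A2,N2)),(V1,V2));")
  expect_true(is_sister_group(yes, c("A1", "A2"), c("N1", "N2")))
  expect_false(is_sister_group(no, c("A1", "A2"), c("N1", "N2")))
  expect_error(is_sister_group(yes, c("A1", "A2"), c("A2", "N1")), "overlap")

  # implication: sister(a, b) => monophyletic(a u b), on random trees
  for (seed in 1:20) {
    tr <- rand_bin_tree(8, seed)
    taxa <- tr$tip.label
    set.seed(seed)
    a <- sample(taxa, 2)
    b <- sample(setdiff(taxa, a), 2)
    if (is_sister_group(tr, a, b)) {
      expect_true(is_monophyletic(tr, c(a, b)))
    }
  }
})

test_that("posterior model odds counts and both denominators are correct", {
  cons <- parse_newick("(((A1,A2),(N1,N2)),(V1,V2));")
  incons <- parse_newick("(((A1,N1),(A2,N2)),(V1,V2));")
  hyp <- clade_hypothesis("sister", list(c("A1", "A2"), c("N1", "N2")),
                          "sister_group")
  s <- tree_sample(c(rep(list(cons), 3), rep(list(incons), 2)))
  o <- posterior_model_odds(s, hyp)
  expect_equal(o$n_consistent, 3L)
  expect_equal(o$n_inconsistent, 2L)
  expect_equal(o$odds, 1.5)
  expect_equal(o$odds_total, 0.6)
  expect_equal(o$percent, 60)

  even <- posterior_model_odds(tree_sample(list(cons, incons)), hyp)
  expect_equal(even$odds, 1)

  all_cons <- posterior_model_odds(tree_sample(list(cons)), hyp)
  expect_identical(all_cons$odds, Inf)
})

test_that("odds from published counts reproduce the record structure", {
  o <- posterior_odds_from_counts(15, 28001)
  expect_equal(o$n_inconsistent, 27986)
  expect_equal(o$odds, 15 / 27986)
  expect_equal(o$odds_total, 15 / 28001)
})

test_that("root bipartition identifies the root split", {
  tr <- parse_newick("((V1,V2),((M1,M2),(N1,N2)));")
  expect_equal(root_bipartition(tr),
               cladetest:::split_key(c("V1", "V2"), tr$tip.label))
  rerooted <- outgroup_root(ape::unroot(
    parse_newick("((V1:1,V2:1):1,((M1:1,M2:1):1,(N1:1,N2:1):1):1);")),
    c("N1", "N2"))
  expect_equal(root_bipartition(rerooted),
               cladetest:::split_key(c("N1", "N2"), rerooted$tip.label))
  expect_error(root_bipartition(parse_newick("(A,B,C);")), "multifurcating")
})

test_that("root placement agrees with edge enumeration on random trees", {
  for (seed in 1:5) {
    tr <- rand_bin_tree(7, seed, rooted = TRUE)
    rb <- root_bipartition(tr)
    # oracle: the root split must be among the clades hanging off the root
    ntip <- length(tr$tip.label)
    kids <- tr$edge[tr$edge[, 1] == ntip + 1L, 2]
    sides <- lapply(kids, function(k) {
      if (k <= ntip) tr$tip.label[k] else ape::extract.clade(tr, k)$tip.label
    })
    keys <- vapply(sides, cladetest:::split_key, character(1),
                   taxa = tr$tip.label)
    expect_true(rb %in% keys)
    expect_equal(length(unique(keys)), 1L)  # the two sides are one split
  }
})

test_that("root frequency tables tally and sort correctly", {
  tr <- parse_newick("((A:1,B:1):1,((C:1,D:1):1,E:1):1);")
  s <- tree_sample(rep(list(tr), 10))
  tab <- root_frequency_table(s)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$frequency, 1)

  other <- outgroup_root(ape::unroot(tr), c("C", "D"))
  s2 <- tree_sample(c(rep(list(tr), 6), rep(list(other), 4)))
  tab2 <- root_frequency_table(s2)
  expect_equal(tab2$frequency, c(0.6, 0.4))
  expect_equal(sum(tab2$count), 10L)
  expect_equal(sum(tab2$frequency), 1)
})

test_that("the MCC tree maximises summed log clade frequencies", {
  t1 <- parse_newick("((A,B),((C,D),E));")
  t2 <- parse_newick("((A,C),((B,D),E));")
  s <- tree_sample(c(rep(list(t1), 9), list(t2)))
  best <- mcc_tree(s)
  expect_equal(bipartitions(best), bipartitions(t1))
  expect_equal(attr(best, "mcc_index"), 1L)

  # all identical: that tree, index 1
  same <- mcc_tree(tree_sample(rep(list(t2), 5)))
  expect_equal(attr(same, "mcc_index"), 1L)

  # 50-tree synthetic sample: argmax matches exhaustive scoring oracle
  trees <- lapply(1:50, function(i) rand_bin_tree(6, i %% 7 + 1))
  s3 <- tree_sample(trees)
  best3 <- mcc_tree(s3)
  scores <- oracle_mcc_scores(trees)
  expect_equal(attr(best3, "mcc_index"), which.max(scores))
  expect_equal(attr(best3, "mcc_score"), max(scores), tolerance = 1e-12)
})

test_that("outgroup rooting splits the attachment edge evenly", {
  un <- parse_newick("(A:1,B:2,(C:1,D:1):4);")
  r1 <- outgroup_root(un, "A")
  expect_equal(root_bipartition(r1),
               cladetest:::split_key("A", un$tip.label))
  # the two root-child branches each get half the original edge (1/2)
  kids <- r1$edge[r1$edge[, 1] == length(r1$tip.label) + 1L, ]
  lens <- r1$edge.length[r1$edge[, 1] == length(r1$tip.label) + 1L]
  expect_equal(sort(lens)[1], 0.5, tolerance = 1e-9)

  r2 <- outgroup_root(un, c("C", "D"))
  expect_equal(root_bipartition(r2),
               cladetest:::split_key(c("C", "D"), un$tip.label))
  lens2 <- r2$edge.length[r2$edge[, 1] == length(r2$tip.label) + 1L]
  expect_equal(lens2, c(2, 2), tolerance = 1e-9)

  expect_error(outgroup_root(un, c("A", "C")), "not a bipartition")
})
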