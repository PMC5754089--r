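test_that("Nexus files in the MrBayes dialect are read with translate applied", {
  path <- system.file("extdata", "example_mrbayes.t", package = "ksclock")
  ens <- read_tree_ensemble(path)
  expect_length(ens, 3L)
  expect_identical(ens$taxa, c("A", "B", "C", "D"))
  # metacomments stripped, branch lengths parsed
  expect_equal(sort(ens$trees[[1]]$edge.length),
               sort(c(0.010, 0.020, 0.005, 0.030, 0.040)))
})

test_that("plain Newick parses into trees with the stated edge lengths", {
  path <- system.file("extdata", "example.nwk", package = "ksclock")
  ens <- read_tree_ensemble(path)
  expect_length(ens, 2L)
  expect_setequal(ens$trees[[1]]$edge.length, c(1.0, 1.0, 0.5, 1.5))

  f <- tempfile(fileext = ".nwk")
  writeLines("((A:1.0,B:1.0):0.5,C:1.5);", f)
  one <- read_tree_ensemble(f)
  expect_length(one$trees[[1]]$edge.length, 4L)
})

test_that("inconsistent taxon sets and malformed Newick are rejected", {
  f <- tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):0.5,C:1.5);", "((A:1,B:1):0.5,D:1.5);"), f)
  expect_error(read_tree_ensemble(f), "taxon set")

  g <- tempfile(fileext = ".nwk")
  writeLines(c("((A:1,B:1):0.5,C:1.5);", "((A:1,B:1:0.5,C((;"), g)
  expect_error(read_tree_ensemble(g), "tree 2")
})

test_that("burn-in removes ceiling(fraction * T) leading trees in order", {
  nwk <- sprintf("((A:%d,B:1):0.5,C:1.5);", 1:40)
  ens <- toy_ensemble(nwk)
  kept <- apply_burnin(ens, 0.5)
  expect_length(kept, 20L)
  # order preserved: first kept tree is tree 21
  expect_equal(kept$trees[[1]]$edge.length,
               ens$trees[[21]]$edge.length)
  expect_length(apply_burnin(ens, 0.25), 30L)
  expect_equal(apply_burnin(ens, 0), ens)
  expect_error(apply_burnin(toy_ensemble(nwk[1]), 0.5), "every tree")
  expect_error(apply_burnin(ens, 1), "fraction")
})

test_that("outgroup pruning drops exactly the outgroup terminal edge", {
  ens <- toy_ensemble(rep(nine_taxon_newick(), 3))
  expect_length(ens$trees[[1]]$edge.length, 15L)
  pruned <- prune_outgroup(ens, "O")
  expect_length(pruned$trees[[1]]$edge.length, 14L)
  expect_false("O" %in% pruned$taxa)
  # the outgroup edge length is discarded, nothing merged
  expect_equal(sum(pruned$trees[[1]]$edge.length),
               sum(ens$trees[[1]]$edge.length) - 0.025)
  # smallest case: 3-leaf unrooted tree keeps the two ingroup edges
  small <- toy_ensemble("(A:1,B:2,O:9);")
  ps <- prune_outgroup(small, "O")
  expect_setequal(ps$trees[[1]]$edge.length, c(1, 2))
  expect_error(prune_outgroup(ens, "Z"), "not in the taxon set")
})

test_that("pruning then pooling yields tau * (B - 1) values", {
  ens <- toy_ensemble(rep(nine_taxon_newick(), 5))
  n_before <- pooled_branch_lengths(ens, 5)$n
  n_after <- pooled_branch_lengths(prune_outgroup(ens, "O"), 5)$n
  expect_equal(n_before, 5 * 15)
  expect_equal(n_after, 5 * 14)
})

test_that("pooling concatenates the first tau trees and sets N = tau * B", {
  nwk <- c("((A:1,B:2):3,C:4);", "((A:5,B:6):7,C:8);", "((A:9,B:10):11,C:12);")
  ens <- toy_ensemble(nwk)
  s <- pooled_branch_lengths(ens, 2)
  expect_equal(s$n, 8L)
  expect_equal(s$branches_per_tree, 4L)
  expect_setequal(s$values, 1:8)
  s1 <- pooled_branch_lengths(ens, 1)
  expect_setequal(s1$values, c(1, 2, 3, 4))
  expect_error(pooled_branch_lengths(ens, 0), "positive")
  expect_error(pooled_branch_lengths(ens, 4), "exceeds")
})

test_that("unequal edge counts across trees are reported with tree indices", {
  ens <- toy_ensemble(c("((A:1,B:2):3,C:4);", "(A:1,B:2,C:4);"))
  expect_error(pooled_branch_lengths(ens, 2), "2")
})

test_that("tree-length trace sums branch lengths per tree", {
  ens <- toy_ensemble(c("((A:1,B:1):0.5,C:1.5);", "((A:2,B:1):0.5,C:1.5);"))
  expect_equal(tree_length_trace(ens), c(4.0, 5.0))
  # invariant under leaf-label permutation
  perm <- toy_ensemble(c("((B:1,A:1):0.5,C:1.5);", "((C:1.5,B:1):0.5,A:2);"))
  expect_equal(sort(tree_length_trace(perm)), sort(tree_length_trace(ens)))
  # constant ensembles give constant traces of ensemble length
  same <- toy_ensemble(rep("((A:1,B:1):0.5,C:1.5);", 4))
  expect_equal(tree_length_trace(same), rep(4, 4))
})

test_that("write/read round trip preserves topology and branch lengths", {
  cfg <- synth_config(n_taxa = 6, n_trees = 8, seed = 31,
                      branch_model = list(kind = "poisson", lambda = 7))
  ens <- simulate_clock_ensemble(cfg)
  for (fmt in c("newick", "nexus")) {
    f <- tempfile(fileext = if (fmt == "newick") ".nwk" else ".nex")
    write_ensemble(ens, f, fmt)
    back <- read_tree_ensemble(f)
    expect_length(back, length(ens))
    expect_identical(back$taxa, ens$taxa)
    for (i in seq_len(length(ens)))
      expect_equal(sort(back$trees[[i]]$edge.length),
                   sort(ens$trees[[i]]$edge.length), tolerance = 1e-9)
  }
  # Nexus output carries a translate block naming every taxon
  f <- tempfile(fileext = ".nex")
  write_ensemble(ens, f, "nexus")
  txt <- tolower(paste(readLines(f), collapse = "\n"))
  expect_match(txt, "translate")
  for (taxon in ens$taxa) expect_match(txt, tolower(taxon))
})

test_that("ensemble validation rejects negative lengths and bad generations", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  bad <- tr
  bad$edge.length[1] <- -0.1
  expect_error(tree_ensemble(list(bad)), "negative")
  expect_error(tree_ensemble(list(tr, tr), generations = c(2, 1)),
               "increasing")
  expect_silent(tree_ensemble(list(tr, tr), generations = c(100, 200)))
})
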