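test_that("wagner_build is deterministic and correct in forced cases", {
  m3 <- encode_matrix(random_seq_set(3, 10, seed = 1))
  w3 <- wagner_build(m3, seed = 5)
  expect_identical(sort(w3$tip.label), c("t1", "t2", "t3"))

  # identical sequences: any build has length 0
  ident <- seq_set(stats::setNames(rep("ACGTACGT", 5), paste0("t", 1:5)),
                   "nucleotide")
  mi <- encode_matrix(ident)
  expect_identical(fitch_length(wagner_build(mi, seed = 2), mi), 0L)

  m <- encode_matrix(random_seq_set(6, 30, seed = 3))
  expect_identical(splits_key(wagner_build(m, seed = 9)),
                   splits_key(wagner_build(m, seed = 9)))
  expect_error(wagner_build(encode_matrix(random_seq_set(2, 5, seed = 1))),
               "3 taxa")
})

test_that("SPR and TBR neighborhoods contain valid distinct topologies", {
  tr <- random_topology(6, seed = 4)
  for (fn in list(phylomask:::spr_neighbors, phylomask:::tbr_neighbors)) {
    nb <- fn(tr)
    expect_gt(length(nb), 5)
    keys <- character(0)
    for (s in nb) {
      t2 <- ape::read.tree(text = s)
      expect_identical(sort(t2$tip.label), sort(tr$tip.label))
      expect_true(ape::is.binary(t2))
      keys <- c(keys, splits_key(t2))
    }
    # neighborhoods reach beyond the original topology
    expect_gt(length(unique(keys)), 3)
  }
  # TBR includes all SPR rearrangements reachable from this tree
  spr_keys <- sapply(phylomask:::spr_neighbors(tr),
                     function(s) splits_key(ape::read.tree(text = s)))
  tbr_keys <- sapply(phylomask:::tbr_neighbors(tr),
                     function(s) splits_key(ape::read.tree(text = s)))
  expect_true(all(spr_keys %in% tbr_keys))
})

test_that("heuristic search finds the exhaustive optimum on random matrices", {
  for (seed in 1:12) {
    m <- encode_matrix(random_seq_set(6, 25, seed = seed + 1300),
                       gap_mode = if (seed %% 2) "fifth_state" else "missing")
    ex <- exhaustive_search(m)
    he <- heuristic_search(m, builds = 3, swap = "TBR", seed = seed)
    expect_identical(he$best_length, ex$best_length)
  }
})

test_that("search results are deterministic and collapse trivial structure", {
  m <- encode_matrix(random_seq_set(6, 25, seed = 77))
  a <- heuristic_search(m, builds = 3, seed = 11)
  b <- heuristic_search(m, builds = 3, seed = 11)
  expect_identical(a$best_length, b$best_length)
  expect_identical(sapply(a$best_trees, splits_key),
                   sapply(b$best_trees, splits_key))

  ident <- encode_matrix(seq_set(
    stats::setNames(rep("ACGTACGT", 5), paste0("t", 1:5)), "nucleotide"))
  hs <- heuristic_search(ident, builds = 2, seed = 1)
  expect_identical(hs$best_length, 0L)
  expect_identical(length(hs$best_trees), 1L)   # all collapse to one star
  expect_identical(length(tree_splits(hs$best_trees[[1]])), 0L)
})

test_that("exhaustive_search enumerates and refuses large problems", {
  # 5 identical taxa: all 15 topologies optimal at 0, one collapsed star
  ident <- encode_matrix(seq_set(
    stats::setNames(rep("AAAA", 5), paste0("t", 1:5)), "nucleotide"))
  ex <- exhaustive_search(ident)
  expect_identical(ex$replicates_run, 15L)
  expect_identical(ex$best_length, 0L)
  expect_identical(length(ex$best_trees), 1L)

  s <- seq_set(c(a = "AAA", b = "AAT", c = "CCA", d = "CCT"), "nucleotide")
  # sites 1-2 cost 1 on ab|cd; site 3 (A,T,A,T) costs 2 on it: total 4,
  # which beats 2+2+2 and 2+2+1 on the two alternative quartets
  ex2 <- exhaustive_search(encode_matrix(s))
  expect_identical(ex2$best_length, 4L)
  big <- encode_matrix(random_seq_set(10, 5, seed = 1))
  expect_error(exhaustive_search(big), "9 taxa")
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- read_newick("((a,b),(c,d));")
  t2 <- read_newick("((a,c),(b,d));")
  star <- strict_consensus(list(t1, t2))
  expect_identical(length(tree_splits(star)), 0L)

  expect_identical(splits_key(strict_consensus(list(t1, t1))), splits_key(t1))

  # a split present in every input is retained
  trees <- lapply(1:6, function(i) {
    withr::with_seed(i, {
      rest <- sample(c("c", "d", "e", "f"))
      read_newick(sprintf("((x,y),((%s,%s),(%s,%s)));",
                          rest[1], rest[2], rest[3], rest[4]))
    })
  })
  cons <- strict_consensus(trees)
  expect_true("x|y" %in% tree_splits(cons))

  expect_error(strict_consensus(list(t1, read_newick("((a,b),(c,e));"))),
               "identical leaf set")
})

test_that("bootstrap support is deterministic, bounded, and finds clean clades", {
  # two clades with many unique shared states: support 100 for the split
  left <- strrep("A", 20)
  right <- strrep("T", 20)
  s <- seq_set(c(a = left, b = left, c = right, d = right), "nucleotide")
  m <- encode_matrix(s)
  bs <- bootstrap_support(m, replicates = 20, builds_per_rep = 1, seed = 3)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  expect_equal(bs$support[bs$split == "c|d"], 100)

  m2 <- encode_matrix(random_seq_set(5, 30, seed = 21))
  b1 <- bootstrap_support(m2, replicates = 10, builds_per_rep = 1, seed = 9)
  b2 <- bootstrap_support(m2, replicates = 10, builds_per_rep = 1, seed = 9)
  expect_identical(b1, b2)
})

test_that("collapse_zero_branches removes only unsupported edges", {
  # t5 identical to t4: the edge resolving them has zero length
  s <- seq_set(c(t1 = "AAAA", t2 = "AATT", t3 = "TTAA", t4 = "TTTT",
                 t5 = "TTTT"), "nucleotide")
  m <- encode_matrix(s)
  tr <- read_newick("((t1,t2),(t3,(t4,t5)));")
  col <- collapse_zero_branches(tr, m)
  expect_identical(sankoff_length(col, m), fitch_length(tr, m))
  expect_lt(length(tree_splits(col)), length(tree_splits(tr)))
})
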