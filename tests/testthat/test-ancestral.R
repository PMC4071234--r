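test_that("morph_character construction and table reading", {
  ch <- morph_character(c(AtPIN1 = 1, AtPIN5 = 2))
  expect_identical(ch$states$AtPIN1, 1L)
  expect_identical(ch$states$AtPIN5, 2L)

  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("terminal\tscore", "AtPIN1\t1", "AtPIN5\t2"), p)
  ch2 <- character_from_table(p, all_taxa = c("AtPIN1", "AtPIN5", "PpPIN1A"))
  expect_identical(ch2$states$AtPIN1, 1L)
  expect_identical(ch2$states$PpPIN1A, 1:5)  # unlisted: full ambiguity

  writeLines(c("terminal\tscore", "x\t7"), p)
  expect_error(character_from_table(p), "1..5")
  expect_error(morph_character(c(a = 0)), "non-empty subset")
})

test_that("quartet reconstructions match hand enumeration", {
  q <- read_newick("((a,b),(c,d));")

  rs <- mpr_reconstruct(q, morph_character(c(a = 1, b = 1, c = 2, d = 2)))
  expect_identical(rs$min_cost, 1L)
  expect_identical(rs$n_reconstructions, 1)
  expect_identical(unname(rs$mpr[[1]]), 1L)   # node above (a,b)
  expect_identical(unname(rs$mpr[[2]]), 2L)   # node above (c,d)

  rs2 <- mpr_reconstruct(q, morph_character(c(a = 1, b = 2, c = 1, d = 2)))
  expect_identical(rs2$min_cost, 2L)
  expect_identical(rs2$n_reconstructions, 2)
  expect_identical(unname(rs2$mpr[[1]]), 1:2)
  expect_identical(unname(rs2$mpr[[2]]), 1:2)
  recs <- enumerate_reconstructions(rs2)
  states <- sort(sapply(recs, function(r) paste(r, collapse = "")))
  expect_identical(states, c("11", "22"))  # (1,1) and (2,2) only
  expect_error(enumerate_reconstructions(rs2, cap = 1), "2")

  rs3 <- mpr_reconstruct(q, morph_character(c(a = 1, b = 1, c = 1, d = 1)))
  expect_identical(rs3$min_cost, 0L)
  expect_identical(rs3$n_reconstructions, 1)
  expect_identical(length(enumerate_reconstructions(rs3)), 1L)
})

test_that("DP agrees with exhaustive enumeration over internal assignments", {
  for (seed in 1:40) {
    n <- sample(4:7, 1)
    tr <- random_topology(n, seed = seed)
    st <- withr::with_seed(seed + 50, {
      stats::setNames(sample(1:5, n, replace = TRUE), tr$tip.label)
    })
    # sprinkle missing data
    if (seed %% 3 == 0) {
      st <- as.list(st)
      st[[1]] <- 1:5
    }
    ch <- morph_character(st)
    rs <- mpr_reconstruct(tr, ch, root_taxa = tr$tip.label[1])
    tree <- rs$tree
    nt <- length(tree$tip.label)
    nn <- tree$Nnode
    grid <- as.matrix(expand.grid(rep(list(1:5), nn)))
    costs <- apply(grid, 1, function(g) {
      asn <- as.list(g)
      names(asn) <- as.character((nt + 1):(nt + nn))
      phylomask:::reconstruction_cost(rs, asn)
    })
    mc <- min(costs)
    expect_identical(rs$min_cost, as.integer(mc))
    expect_equal(rs$n_reconstructions, sum(costs == mc))
    opt <- grid[costs == mc, , drop = FALSE]
    for (j in seq_len(nn)) {
      expect_identical(rs$mpr[[as.character(nt + j)]],
                       sort(unique(opt[, j])))
    }
  }
})

test_that("min_cost agrees with fitch_length on the 5-state encoding", {
  state_chars <- c("A", "C", "G", "T", "-")  # 5-state proxy alphabet
  for (seed in 1:15) {
    n <- 6
    tr <- random_topology(n, seed = seed)
    st <- withr::with_seed(seed, {
      stats::setNames(sample(1:5, n, replace = TRUE), tr$tip.label)
    })
    ch <- morph_character(st)
    s <- seq_set(stats::setNames(state_chars[st], names(st)), "nucleotide")
    m <- encode_matrix(s, gap_mode = "fifth_state")
    rs <- mpr_reconstruct(tr, ch, root_taxa = tr$tip.label[1])
    expect_identical(rs$min_cost, fitch_length(tr, m))
  }
})

test_that("missing data never increases cost; cost is root-invariant", {
  for (seed in 1:10) {
    n <- 6
    tr <- random_topology(n, seed = seed)
    st <- withr::with_seed(seed + 10, {
      stats::setNames(sample(1:5, n, replace = TRUE), tr$tip.label)
    })
    ch <- morph_character(st)
    base <- mpr_reconstruct(tr, ch, root_taxa = tr$tip.label[1])
    relaxed <- as.list(st)
    relaxed[[3]] <- 1:5
    rs2 <- mpr_reconstruct(tr, morph_character(relaxed),
                           root_taxa = tr$tip.label[1])
    expect_lte(rs2$min_cost, base$min_cost)
    for (root in c("t2", "t4")) {
      expect_identical(
        mpr_reconstruct(tr, ch, root_taxa = root)$min_cost, base$min_cost)
    }
  }
})

test_that("reconstruction works on multifurcating (consensus) trees", {
  poly <- read_newick("((a,b,c),(d,e));")
  ch <- morph_character(c(a = 1, b = 1, c = 2, d = 2, e = 2))
  rs <- mpr_reconstruct(poly, ch)
  # c sits inside the (a,b,c) polytomy, so its state-2 match with (d,e)
  # cannot be explained by one change: cost 2
  expect_identical(rs$min_cost, 2L)
  # brute force over the 2 internal nodes
  costs <- sapply(1:5, function(s1) sapply(1:5, function(s2) {
    asn <- list(`6` = s1, `7` = s2)
    phylomask:::reconstruction_cost(rs, asn)
  }))
  expect_identical(min(costs), rs$min_cost)
})

test_that("paint_tree annotates MPR sets and flags ambiguity", {
  q <- read_newick("((a,b),(c,d));")
  rs <- mpr_reconstruct(q, morph_character(c(a = 1, b = 2, c = 1, d = 2)))
  painted <- paint_tree(rs)
  expect_true(all(painted$table$ambiguous))
  expect_identical(painted$table$states, rep("1|2", 2))
  expect_true(all(nzchar(painted$tree$node.label)))
  # annotation table survives a TSV round trip
  p <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(painted$table, p, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  back <- utils::read.delim(p, colClasses = c("integer", "character",
                                              "character", "logical"))
  expect_equal(tibble::as_tibble(back), painted$table)
})

test_that("unrooted trees without an outgroup are refused", {
  tr <- random_topology(5, seed = 2)
  ch <- morph_character(stats::setNames(rep(1, 5), tr$tip.label))
  expect_error(mpr_reconstruct(tr, ch), "root")
})
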