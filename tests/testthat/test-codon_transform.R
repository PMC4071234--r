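test_that("back_translate maps residues to their codons and gaps to ---", {
  aa <- seq_set(c(t1 = "M-K", t2 = "MSK"), "amino_acid")
  cds <- seq_set(c(t1 = "ATGAAA", t2 = "ATGTCAAAG"), "nucleotide",
                 aligned = FALSE)
  ca <- back_translate(aa, cds)
  expect_s3_class(ca, "codon_alignment")
  expect_identical(unname(chr(ca)), c("ATG---AAA", "ATGTCAAAG"))

  # length mismatch names the taxon
  bad <- seq_set(c(t1 = "ATGAAAG", t2 = "ATGTCAAAG"), "nucleotide",
                 aligned = FALSE)
  expect_error(back_translate(aa, bad), "t1")

  # codon/residue disagreement names the position
  aa2 <- seq_set(c(t1 = "MK"), "amino_acid")
  cds2 <- seq_set(c(t1 = "ATGCCC"), "nucleotide", aligned = FALSE)
  expect_error(back_translate(aa2, cds2), "position 2")

  # terminal stop trimmed with warning; internal stop is an error
  cds3 <- seq_set(c(t1 = "ATGAAATAA", t2 = "ATGTCAAAG"), "nucleotide",
                  aligned = FALSE)
  expect_warning(back_translate(aa, cds3), "stop")
  aa4 <- seq_set(c(t1 = "M?K"), "amino_acid")
  cds4 <- seq_set(c(t1 = "ATGTAAAAA"), "nucleotide", aligned = FALSE)
  expect_error(back_translate(aa4, cds4), "stop")
})

test_that("back_translate round trips with translation", {
  # translating the back-translated alignment (gaps removed) recovers the
  # input amino acids under the standard code
  code <- Biostrings::GENETIC_CODE
  withr::with_seed(42, {
    codons <- names(code)[code != "*"]
    cds_str <- paste0(sample(codons, 30, replace = TRUE), collapse = "")
  })
  aa_str <- paste0(code[substring(cds_str, seq(1, 88, 3), seq(3, 90, 3))],
                   collapse = "")
  aa <- seq_set(stats::setNames(c(aa_str, aa_str), c("x", "y")), "amino_acid")
  cds <- seq_set(c(x = cds_str, y = cds_str), "nucleotide", aligned = FALSE)
  ca <- back_translate(aa, cds)
  expect_identical(unname(chr(ca))[1], cds_str)
})

test_that("strip_third_positions keeps positions 1,2 of every codon", {
  ca <- as_codon_alignment(c(a = "ATGTCA", b = "------"))
  out <- strip_third_positions(ca)
  expect_identical(unname(chr(out)), c("ATTC", "----"))
  expect_equal(nchar(out[[1]]), 2 / 3 * nchar(ca[[1]]))
})

test_that("mask_gc_to_n leaves no G or C and touches nothing else", {
  expect_identical(
    unname(chr(mask_gc_to_n(seq_set(c(a = "GATTACA"), "nucleotide")))),
    "NATTANA")
  expect_identical(
    unname(chr(mask_gc_to_n(seq_set(c(a = "AT-N?"), "nucleotide")))),
    "AT-N?")
  for (seed in 1:20) {
    s <- random_seq_set(4, 40, seed)
    out <- mask_gc_to_n(s)
    expect_false(any(grepl("[GC]", unclass(out))))
    expect_equal(nchar(out[[1]]), nchar(s[[1]]))
  }
})

test_that("serine_mask keeps serine positions 1-2 only, forced by the code", {
  expect_identical(
    unname(chr(serine_mask(as_codon_alignment(c(t = "TCAGGTAGC"))))),
    "TCNNAG")
  expect_identical(
    unname(chr(serine_mask(as_codon_alignment(c(t = "AGT"))))), "AG")
  expect_identical(
    unname(chr(serine_mask(as_codon_alignment(c(t = "NNN---"))))), "NN--")

  # invariant: retained 1st positions in {T,A,N,-}, 2nd in {C,G,N,-}
  for (seed in 1:20) {
    ca <- random_codon_alignment(4, 30, seed)
    out <- serine_mask(ca)
    m <- do.call(rbind, strsplit(unclass(out), ""))
    odd <- m[, seq(1, ncol(m), 2)]
    even <- m[, seq(2, ncol(m), 2)]
    expect_true(all(odd %in% c("T", "A", "N", "?", "-")))
    expect_true(all(even %in% c("C", "G", "N", "?", "-")))
    expect_equal(nchar(out[[1]]), 2 * n_codons(ca))
  }
})

test_that("to_question_marks widens N and gaps to ? and is idempotent", {
  s <- seq_set(c(a = "AN-T", b = "????"), "nucleotide")
  out <- to_question_marks(s)
  expect_identical(unname(chr(out)), c("A??T", "????"))
  expect_identical(unclass(to_question_marks(out)), unclass(out))
  expect_identical(
    unname(chr(to_question_marks(seq_set(c(a = "ACGT"), "nucleotide")))),
    "ACGT")
})

test_that("trim_gappy_blocks drops gappy columns and short blocks", {
  s <- seq_set(c(a = "A-A", b = "A-A", c = "AAA", d = "A-A"), "nucleotide")
  out <- trim_gappy_blocks(s, min_block = 1)
  expect_identical(unname(chr(out)), rep("AA", 4))
  expect_identical(trim_report(out)$kept_column, c(1L, 3L))

  # gapless alignment is untouched
  g <- random_seq_set(4, 30, seed = 3, chars = c("A", "C", "G", "T"),
                      prob = rep(0.25, 4))
  expect_identical(unclass(trim_gappy_blocks(g)[]), unclass(g[]))

  # a column at exactly the threshold is allowed ("gaps in half the rows")
  s2 <- seq_set(c(a = "A-", b = "A-", c = "AA", d = "AA"), "nucleotide")
  expect_identical(unname(chr(trim_gappy_blocks(s2, min_block = 1))),
                   c("AN", "AN", "AA", "AA"))

  # kept columns never exceeded the gap threshold; residual gaps replaced
  for (seed in 1:10) {
    s3 <- random_seq_set(6, 60, seed)
    out3 <- trim_gappy_blocks(s3, max_gap_fraction = 0.5, min_block = 3)
    m <- do.call(rbind, strsplit(unclass(s3), ""))
    frac <- colMeans(m == "-")
    expect_true(all(frac[trim_report(out3)$kept_column] <= 0.5))
    expect_false(any(grepl("-", unclass(out3), fixed = TRUE)))
  }

  all_gap <- seq_set(c(a = "--", b = "--"), "nucleotide")
  expect_warning(trim_gappy_blocks(all_gap), "all columns")
})

test_that("flag_suspect_sequences catches short copies and long branches", {
  lens <- c(a = 900, b = 880, c = 920, d = 450)
  s <- seq_set(stats::setNames(strrep("A", lens), names(lens)), "nucleotide",
               aligned = FALSE)
  fl <- flag_suspect_sequences(s)
  expect_identical(fl$identifier, "d")

  eq <- seq_set(stats::setNames(strrep("A", rep(300, 4)), letters[1:4]),
                "nucleotide", aligned = FALSE)
  expect_identical(nrow(flag_suspect_sequences(eq)), 0L)

  tr <- read_newick("((a:0.1,b:0.04):0.02,(c:0.05,d:0.05):0.02);")
  fl2 <- flag_suspect_sequences(eq, tree = tr)
  expect_identical(fl2$identifier, "a")  # 0.1 >= 2 x 0.04

  nolen <- read_newick("((a,b),(c,d));")
  expect_warning(flag_suspect_sequences(eq, tree = nolen), "branch lengths")
})
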