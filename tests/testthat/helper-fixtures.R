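# Shared generators for randomized tests. All draws are made under explicit
# seeds via withr::with_seed so test order never matters.

random_seq_set <- function(n_taxa, n_sites, seed,
                           chars = c("A", "C", "G", "T", "N", "?", "-"),
                           prob = c(.2, .2, .2, .2, .07, .07, .06)) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n_taxa), function(i) {
      paste0(sample(chars, n_sites, replace = TRUE, prob = prob),
             collapse = "")
    }, character(1))
    seq_set(stats::setNames(seqs, paste0("t", seq_len(n_taxa))),
            "nucleotide", aligned = TRUE)
  })
}

random_codon_alignment <- function(n_taxa, n_codons, seed) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n_taxa), function(i) {
      paste0(sample(bases, 3 * n_codons, replace = TRUE), collapse = "")
    }, character(1))
    as_codon_alignment(stats::setNames(seqs, paste0("t", seq_len(n_taxa))))
  })
}

random_topology <- function(n_taxa, seed, rooted = FALSE) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = TRUE, br = NULL)
    tr$tip.label <- paste0("t", seq_len(n_taxa))
    if (!rooted) tr <- ape::unroot(tr)
    tr
  })
}

# independent brute-force parsimony: minimize over all full internal-node
# state assignments (states as bitmask singletons over alphabet size k)
brute_force_length <- function(tree, matrix) {
  k <- length(attr(matrix, "alphabet"))
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  bits <- unclass(matrix)[match(tree$tip.label, rownames(matrix)), ,
                          drop = FALSE]
  w <- attr(matrix, "weights")
  total <- 0
  for (site in seq_len(ncol(bits))) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      asn <- grid[g, ]
      cost <- 0
      for (e in seq_len(nrow(tree$edge))) {
        p <- asn[tree$edge[e, 1] - nt]
        ch <- tree$edge[e, 2]
        if (ch <= nt) {
          ok <- bitwAnd(bits[ch, site], bitwShiftL(1L, p - 1L)) != 0L
          cost <- cost + as.integer(!ok)
        } else {
          cost <- cost + as.integer(asn[ch - nt] != p)
        }
      }
      best <- min(best, cost)
    }
    total <- total + w[site] * best
  }
  total
}

# plain named character view of a seq_set (drops class and attributes)
chr <- function(x) stats::setNames(as.character(x), names(x))
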