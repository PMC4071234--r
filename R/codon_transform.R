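#' Back-translate an aligned protein onto its coding sequences
#'
#' Replaces each aligned amino-acid residue by the codon it came from, and
#' each alignment gap by `---`, so the nucleotide alignment inherits the
#' protein alignment's gap structure whole-codon-wise. Every codon is checked
#' against the aligned residue under the standard genetic code; a mismatch
#' signals a frame shift or a wrong CDS and is an error naming the taxon and
#' alignment position. A terminal stop codon on the CDS is trimmed with a
#' warning; an internal stop is an error.
#'
#' @param aa_alignment Aligned amino-acid [seq_set].
#' @param cds Unaligned nucleotide [seq_set] with the same taxon set.
#' @return A [codon_alignment][as_codon_alignment].
#' @examples
#' aa <- seq_set(c(t1 = "M-K", t2 = "MSK"), "amino_acid")
#' cds <- seq_set(c(t1 = "ATGAAA", t2 = "ATGTCAAAG"), "nucleotide",
#'                aligned = FALSE)
#' back_translate(aa, cds)
#' @export
back_translate <- function(aa_alignment, cds) {
  stopifnot(inherits(aa_alignment, "seq_set"), inherits(cds, "seq_set"))
  if (seq_alphabet(aa_alignment) != "amino_acid") {
    stop("aa_alignment must be amino-acid", call. = FALSE)
  }
  if (seq_alphabet(cds) != "nucleotide") {
    stop("cds must be nucleotide", call. = FALSE)
  }
  if (!is_aligned(aa_alignment)) stop("aa_alignment must be aligned", call. = FALSE)
  if (!setequal(names(aa_alignment), names(cds))) {
    stop("taxon sets of alignment and CDS differ", call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  out <- character(length(aa_alignment))
  for (i in seq_along(aa_alignment)) {
    tax <- names(aa_alignment)[i]
    aa <- strsplit(aa_alignment[[i]], "")[[1]]
    nt <- cds[[tax]]
    n_res <- sum(aa != "-")
    if (nchar(nt) == 3L * (n_res + 1L)) {
      last <- substr(nt, nchar(nt) - 2L, nchar(nt))
      if (!is.na(code[last]) && code[last] == "*") {
        warning("trimming terminal stop codon from CDS of '", tax, "'",
                call. = FALSE)
        nt <- substr(nt, 1L, nchar(nt) - 3L)
      }
    }
    if (nchar(nt) != 3L * n_res) {
      stop(sprintf("CDS length mismatch for '%s': %d nt for %d residues",
                   tax, nchar(nt), n_res), call. = FALSE)
    }
    codons <- substring(nt, seq(1L, nchar(nt), by = 3L),
                        seq(3L, nchar(nt), by = 3L))
    if (n_res == 0L) codons <- character(0)
    res <- character(length(aa))
    k <- 0L
    for (j in seq_along(aa)) {
      if (aa[j] == "-") {
        res[j] <- "---"
      } else {
        k <- k + 1L
        cod <- codons[k]
        tr <- if (grepl("[^ACGT]", cod)) NA_character_ else unname(code[cod])
        if (!is.na(tr) && tr == "*") {
          stop(sprintf("internal stop codon %s in '%s' at alignment position %d",
                       cod, tax, j), call. = FALSE)
        }
        if (!is.na(tr) && !aa[j] %in% c("X", "?") && tr != aa[j]) {
          stop(sprintf(
            "codon %s of '%s' translates to %s but alignment has %s at position %d",
            cod, tax, tr, aa[j], j), call. = FALSE)
        }
        res[j] <- cod
      }
    }
    out[i] <- paste0(res, collapse = "")
  }
  as_codon_alignment(stats::setNames(out, names(aa_alignment)))
}

#' Remove third codon positions
#'
#' Keeps positions 1 and 2 of every codon, in order; the output has exactly
#' two thirds the aligned length of the input.
#'
#' @param aln A [codon_alignment][as_codon_alignment].
#' @return An aligned nucleotide [seq_set] (no longer frame-valid).
#' @export
strip_third_positions <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln) == 0 || nchar(aln[[1]]) == 0) {
    return(seq_set(stats::setNames(character(length(aln)), names(aln)),
                   "nucleotide", aligned = TRUE))
  }
  len <- nchar(aln[[1]])
  keep <- setdiff(seq_len(len), seq(3L, len, by = 3L))
  m <- seq_char_matrix(aln)[, keep, drop = FALSE]
  chars_to_seq_set(m, "nucleotide")
}

#' Mask G and C as N
#'
#' Replaces every G and C with N, leaving A, T, N, ?, gap and IUPAC codes
#' untouched. After this transform only A/T states (and missing data) remain,
#' which removes the signal a lineage-specific GC substitution bias can
#' generate; shared A/T states still inform the tree.
#'
#' @param seqs A nucleotide [seq_set] (class is preserved).
#' @return The masked set, same class and dimensions.
#' @export
mask_gc_to_n <- function(seqs) {
  stopifnot(inherits(seqs, "seq_set"))
  if (seq_alphabet(seqs) != "nucleotide") {
    stop("mask_gc_to_n applies to nucleotide sequences", call. = FALSE)
  }
  out <- chartr("GC", "NN", unclass(seqs))
  attributes(out) <- attributes(seqs)
  out
}

#' Serine first/second position extraction
#'
#' Serine is the only amino acid whose codons (TCT, TCC, TCA, TCG, AGT, AGC)
#' constrain position 1 to \{T,A\} and position 2 to \{C,G\}: a T/A contrast at
#' position 1 and a C/G contrast at position 2 are therefore immune to a
#' genome-wide GC bias. This transform keeps positions 1-2 of serine codons,
#' masks positions 1-2 of every other codon to `NN`, renders gap codons as
#' `--`, and drops all third positions. Codons containing N or ? cannot be
#' confirmed as serine and are masked (counted in the `masked_ambiguous`
#' attribute, not an error).
#'
#' @param aln A [codon_alignment][as_codon_alignment].
#' @return An aligned nucleotide [seq_set] of 2/3 the input length.
#' @examples
#' serine_mask(as_codon_alignment(c(t1 = "TCAGGTAGC")))  # "TCNNAG"
#' @export
serine_mask <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  ser <- c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC")
  n_amb <- 0L
  out <- vapply(unclass(aln), function(s) {
    if (nchar(s) == 0) return("")
    codons <- substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
    pieces <- vapply(codons, function(cod) {
      if (cod == "---") return("--")
      if (cod %in% ser) return(substr(cod, 1L, 2L))
      if (grepl("[N?]", cod)) n_amb <<- n_amb + 1L
      "NN"
    }, character(1))
    paste0(pieces, collapse = "")
  }, character(1))
  res <- seq_set(stats::setNames(out, names(aln)), "nucleotide", aligned = TRUE)
  attr(res, "masked_ambiguous") <- n_amb
  res
}

#' Recode missing data and gaps as ?
#'
#' Replaces every `N` and every gap `-` with `?`. Under the fifth-state gap
#' convention this deliberately widens N ("any nucleotide") to ? ("any
#' nucleotide or gap"), mimicking programs that treat gaps as missing data.
#'
#' @param seqs A nucleotide [seq_set] (class preserved).
#' @return The recoded set.
#' @export
to_question_marks <- function(seqs) {
  stopifnot(inherits(seqs, "seq_set"))
  if (seq_alphabet(seqs) != "nucleotide") {
    stop("to_question_marks applies to nucleotide sequences", call. = FALSE)
  }
  out <- chartr("N-", "??", unclass(seqs))
  attributes(out) <- attributes(seqs)
  out
}

#' Trim gappy alignment blocks
#'
#' A light-weight block trimmer in the spirit of alignment cleaners: a column
#' is dropped when its gap fraction exceeds `max_gap_fraction` (the default
#' allows gaps in up to half of the rows), then runs of surviving columns that
#' are shorter than `min_block` contiguous original columns are dropped too.
#' Gaps remaining in the kept columns are replaced by
#' `replace_remaining_gaps_with` (default `N`, i.e. any nucleotide).
#'
#' @param seqs An aligned [seq_set].
#' @param max_gap_fraction Columns with a strictly greater gap fraction are
#'   removed.
#' @param min_block Minimum length of a kept run of contiguous columns.
#' @param replace_remaining_gaps_with Single character substituted for
#'   residual gaps; use `"-"` to keep them.
#' @return The trimmed [seq_set] with attribute `kept_columns` (1-based
#'   indices into the original alignment); see [trim_report()].
#' @export
trim_gappy_blocks <- function(seqs, max_gap_fraction = 0.5, min_block = 5L,
                              replace_remaining_gaps_with = "N") {
  stopifnot(inherits(seqs, "seq_set"))
  if (!is_aligned(seqs)) stop("input must be aligned", call. = FALSE)
  m <- seq_char_matrix(seqs)
  if (ncol(m) == 0) return(seqs)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  # drop kept runs shorter than min_block (contiguity in original coordinates)
  r <- rle(keep)
  r$values[r$values & r$lengths < min_block] <- FALSE
  keep <- inverse.rle(r)
  if (!any(keep)) {
    warning("all columns removed by trimming", call. = FALSE)
  }
  m2 <- m[, keep, drop = FALSE]
  if (!identical(replace_remaining_gaps_with, "-")) {
    m2[m2 == "-"] <- replace_remaining_gaps_with
  }
  out <- chars_to_seq_set(m2, seq_alphabet(seqs))
  attr(out, "kept_columns") <- which(keep)
  out
}

#' Kept-column report of a trimmed alignment
#'
#' @param trimmed Output of [trim_gappy_blocks()].
#' @return A tibble with column `kept_column` (1-based original coordinates).
#' @export
trim_report <- function(trimmed) {
  kc <- attr(trimmed, "kept_columns")
  if (is.null(kc)) stop("no trimming report attached", call. = FALSE)
  tibble::tibble(kept_column = as.integer(kc))
}

#' Flag suspect (pseudogene-like) sequences
#'
#' Screens a gene set for members that should be excluded before tree search,
#' by the two symptoms of a decayed or truncated copy: (i) an ungapped length
#' at most `length_ratio` times the median ungapped length of the set, and
#' (ii) when a tree with branch lengths is supplied, a terminal branch at
#' least `branch_ratio` times as long as the branch to its sister group.
#'
#' @param seqs A [seq_set] (aligned or not) of at least two sequences.
#' @param tree Optional [ape::phylo] whose leaves are a subset of the
#'   identifiers; without branch lengths only the length criterion runs (with
#'   a warning).
#' @param length_ratio,branch_ratio Flagging thresholds.
#' @return A tibble with columns `identifier`, `reason` (one row per reason).
#' @export
flag_suspect_sequences <- function(seqs, tree = NULL, length_ratio = 0.5,
                                   branch_ratio = 2.0) {
  stopifnot(inherits(seqs, "seq_set"), length(seqs) >= 2)
  ung <- nchar(gsub("[-?]", "", unclass(seqs)))
  # leave-one-out median, so one truncated copy cannot shield itself
  med <- vapply(seq_along(ung), function(i) stats::median(ung[-i]), numeric(1))
  out <- tibble::tibble(identifier = character(0), reason = character(0))
  short <- which(ung <= length_ratio * med)
  if (length(short)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      identifier = names(seqs)[short],
      reason = sprintf("ungapped length %d <= %.2g x median of others (%g)",
                       ung[short], length_ratio, med[short])))
  }
  if (!is.null(tree)) {
    stopifnot(inherits(tree, "phylo"))
    if (!all(tree$tip.label %in% names(seqs))) {
      stop("tree has leaves not present among the sequences", call. = FALSE)
    }
    if (is.null(tree$edge.length)) {
      warning("tree has no branch lengths; length criterion only",
              call. = FALSE)
    } else {
      for (i in seq_along(tree$tip.label)) {
        e <- which(tree$edge[, 2] == i)
        parent <- tree$edge[e, 1]
        sib_e <- which(tree$edge[, 1] == parent & tree$edge[, 2] != i)
        if (!length(sib_e)) next
        sib_len <- max(tree$edge.length[sib_e])
        if (sib_len > 0 && tree$edge.length[e] >= branch_ratio * sib_len) {
          out <- dplyr::bind_rows(out, tibble::tibble(
            identifier = tree$tip.label[i],
            reason = sprintf("terminal branch %.4g >= %.2g x sister branch %.4g",
                             tree$edge.length[e], branch_ratio, sib_len)))
        }
      }
    }
  }
  out
}
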