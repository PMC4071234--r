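#' Sequence sets
#'
#' A `seq_set` is the package's basic container for a collection of named
#' sequences: a named character vector with a declared alphabet
#' (`"nucleotide"` or `"amino_acid"`) and an alignment flag. Aligned sets have
#' equal-length members. Residues are stored uppercase; for nucleotides, `U`
#' is normalized to `T` on construction.
#'
#' Allowed characters are the declared alphabet plus the missing-data and gap
#' symbols `-`, `N`, `?`, `X`. Nucleotide sets additionally admit the IUPAC
#' ambiguity codes (R, Y, S, W, K, M, B, D, H, V), which downstream encoding
#' maps to their standard state subsets.
#'
#' @param x Named character vector of sequences (names are identifiers).
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param aligned Logical; if `NULL`, inferred (`TRUE` when all sequences have
#'   equal length).
#' @return An object of class `seq_set`.
#' @examples
#' seq_set(c(a = "ATG", b = "AT-"), "nucleotide")
#' @export
seq_set <- function(x, alphabet = c("nucleotide", "amino_acid"), aligned = NULL) {
  alphabet <- match.arg(alphabet)
  if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop("all sequences must be named with non-empty identifiers", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    dup <- names(x)[duplicated(names(x))][1]
    stop("duplicate sequence identifier: '", dup, "'", call. = FALSE)
  }
  x <- stats::setNames(toupper(as.character(x)), names(x))
  if (alphabet == "nucleotide") x <- gsub("U", "T", x, fixed = TRUE)
  if (is.null(aligned)) {
    aligned <- length(x) > 0 && length(unique(nchar(x))) == 1L
  }
  if (aligned && length(x) > 0 && length(unique(nchar(x))) != 1L) {
    stop("aligned seq_set requires equal-length sequences", call. = FALSE)
  }
  .check_alphabet(x, alphabet)
  structure(x, alphabet = alphabet, aligned = aligned, class = "seq_set")
}

.alphabet_chars <- function(alphabet) {
  if (alphabet == "nucleotide") {
    c("A", "C", "G", "T",
      "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
      "-", "N", "?", "X")
  } else {
    c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*", "-", "?", "X")
  }
}

.check_alphabet <- function(x, alphabet) {
  ok <- .alphabet_chars(alphabet)
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad)) {
      stop(sprintf("invalid %s character '%s' in record '%s' at position %d",
                   alphabet, chars[bad[1]], names(x)[i], bad[1]), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("<seq_set> %d %s sequence(s)%s\n", length(x),
              attr(x, "alphabet"),
              if (isTRUE(attr(x, "aligned")))
                sprintf(", aligned (%d columns)",
                        if (length(x)) nchar(x[[1]]) else 0L)
              else ""))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- x[[i]]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %-20s %s\n", names(x)[i], s))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i, ...) {
  seq_set(unclass(x)[i], alphabet = attr(x, "alphabet"),
          aligned = attr(x, "aligned"))
}

is_aligned <- function(x) isTRUE(attr(x, "aligned"))

seq_alphabet <- function(x) attr(x, "alphabet")

#' Codon alignments
#'
#' A `codon_alignment` is an aligned nucleotide [seq_set] whose length is a
#' multiple of three and whose reading frame starts at column 1, so that
#' columns 1,2,3 are codon positions 1,2,3 of the first codon, and so on.
#' Back-translated alignments ([back_translate()]) always satisfy this;
#' pre-aligned coding-sequence alignments can be cast with this constructor.
#'
#' @param x An aligned nucleotide `seq_set` (or named character vector).
#' @param provenance Optional free-text metadata (e.g. the aligner and its
#'   settings) carried along unmodified.
#' @return An object of class `c("codon_alignment", "seq_set")`.
#' @examples
#' as_codon_alignment(seq_set(c(a = "ATGAAA", b = "ATG---"), "nucleotide"))
#' @export
as_codon_alignment <- function(x, provenance = NULL) {
  if (!inherits(x, "seq_set")) x <- seq_set(x, "nucleotide")
  if (seq_alphabet(x) != "nucleotide") {
    stop("codon alignments are nucleotide alignments", call. = FALSE)
  }
  if (!is_aligned(x)) stop("codon alignments must be aligned", call. = FALSE)
  if (length(x) && nchar(x[[1]]) %% 3L != 0L) {
    stop("aligned length ", nchar(x[[1]]), " is not a multiple of 3",
         call. = FALSE)
  }
  structure(unclass(x), alphabet = "nucleotide", aligned = TRUE,
            provenance = provenance,
            class = c("codon_alignment", "seq_set"))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d codons\n", length(x),
              if (length(x)) nchar(x[[1]]) %/% 3L else 0L))
  NextMethod()
}

n_codons <- function(x) {
  stopifnot(inherits(x, "codon_alignment"))
  if (length(x) == 0) 0L else nchar(x[[1]]) %/% 3L
}

# split each sequence into a character matrix (rows = taxa, cols = columns)
seq_char_matrix <- function(x) {
  if (length(x) == 0) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  m <- do.call(rbind, strsplit(unclass(x), ""))
  rownames(m) <- names(x)
  m
}

# inverse of seq_char_matrix
chars_to_seq_set <- function(m, alphabet, codon = FALSE) {
  seqs <- apply(m, 1L, paste0, collapse = "")
  if (nrow(m) == 0) seqs <- stats::setNames(character(0), character(0))
  out <- seq_set(stats::setNames(as.character(seqs), rownames(m)),
                 alphabet = alphabet, aligned = TRUE)
  if (codon) out <- as_codon_alignment(out)
  out
}
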