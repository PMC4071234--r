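#' Read a FASTA file
#'
#' Parses FASTA into a [seq_set], preserving record order, uppercasing
#' residues and (for nucleotide data) normalizing U to T. Duplicate
#' identifiers and characters outside the declared alphabet are errors that
#' name the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param aligned Logical or `NULL` (auto-detect from equal lengths).
#' @return A [seq_set].
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino_acid"),
                       aligned = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  bs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(bs))  # FASTA description dropped after first ws
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier in ", path, ": '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  seq_set(stats::setNames(as.character(bs), ids), alphabet = alphabet,
          aligned = aligned)
}

#' Write a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, p), ...)` recovers
#' `x` exactly (sequences are already case/U-normalized in a `seq_set`).
#'
#' @param seqs A [seq_set].
#' @param path Output path.
#' @param wrap Positive line width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 60L) {
  stopifnot(inherits(seqs, "seq_set"), wrap >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = wrap)
    if (nchar(s) > 0) {
      writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Accepts a file path or a literal Newick string. Leaf labels must be unique;
#' branch lengths are kept when present. An unrooted tree is recognized by its
#' basal trifurcation (the usual Newick convention).
#'
#' @param x Path to a Newick file, or a string containing `(`.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  tr <- if (grepl("(", x[1], fixed = TRUE)) {
    tryCatch(ape::read.tree(text = x), error = function(e) NULL,
             warning = function(w) NULL)
  } else {
    if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
    tryCatch(ape::read.tree(x), error = function(e) NULL,
             warning = function(w) NULL)
  }
  if (is.null(tr)) stop("not valid Newick: ", x, call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label: '",
         tr$tip.label[duplicated(tr$tip.label)][1], "'", call. = FALSE)
  }
  if (any(!nzchar(tr$tip.label))) stop("empty leaf label", call. = FALSE)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length", call. = FALSE)
  }
  tr
}

#' Write a Newick string
#'
#' @param tree An [ape::phylo] tree.
#' @param path Optional file path; when given, the string is also written there.
#' @param digits Precision for branch lengths.
#' @return The Newick string.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(path)) writeLines(s, path)
  s
}

#' Write a TNT/Hennig86 xread matrix
#'
#' Emits a character matrix as an `xread` block for parsimony programs in the
#' TNT dialect. The ambiguity conventions of the package are preserved
#' verbatim: a cell meaning "any nucleotide" is written `N`, never silently
#' promoted to `?` (which additionally admits the gap); gaps are written `-`.
#' Taxon names are whitespace-sanitized deterministically (runs of whitespace
#' become `_`); a collision after sanitization is an error.
#'
#' @param matrix A [char_matrix] or an aligned [seq_set].
#' @param path Output path.
#' @param title Comment string placed in the xread header.
#' @return `path`, invisibly.
#' @export
write_tnt_matrix <- function(matrix, path, title = "phylomask export") {
  if (inherits(matrix, "seq_set")) {
    if (!is_aligned(matrix)) stop("matrix must be aligned", call. = FALSE)
    seqs <- unclass(matrix)
  } else if (inherits(matrix, "char_matrix")) {
    seqs <- decode_matrix(matrix)
  } else {
    stop("matrix must be a seq_set or char_matrix", call. = FALSE)
  }
  if (length(seqs) == 0 || nchar(seqs[[1]]) == 0) {
    stop("refusing to write an empty matrix", call. = FALSE)
  }
  nm <- gsub("\\s+", "_", names(seqs))
  if (anyDuplicated(nm)) {
    stop("taxon name collision after sanitization: '",
         nm[duplicated(nm)][1], "'", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("xread", con)
  writeLines(paste0("'", title, "'"), con)
  writeLines(paste(nchar(seqs[[1]]), length(seqs)), con)
  writeLines(paste(nm, seqs), con)
  writeLines(";", con)
  invisible(path)
}
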