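# Bitmask encoding of state sets over the ordered alphabet A,C,G,T[,gap]:
# A=1, C=2, G=4, T=8, gap=16. N = {A,C,G,T} = 15. Under the fifth-state gap
# convention ? = 31 and - = 16; when gaps are missing data both ? and - (and
# N) collapse to 15.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 1L + 4L, Y = 2L + 8L, S = 2L + 4L, W = 1L + 8L,
  K = 4L + 8L, M = 1L + 2L,
  B = 2L + 4L + 8L, D = 1L + 4L + 8L, H = 1L + 2L + 8L, V = 1L + 2L + 4L,
  N = 15L, X = 15L)

#' Encode an aligned sequence set as a state-set character matrix
#'
#' Maps each residue to its set of admissible states over the ordered
#' alphabet A, C, G, T and (under `gap_mode = "fifth_state"`) the gap. The
#' two missing-data symbols are deliberately distinct: `N` always means "any
#' nucleotide" (the gap is excluded, so gap information is preserved), while
#' `?` means "any nucleotide or gap". With `gap_mode = "missing"`, gap, N and
#' ? all collapse to "any nucleotide", mimicking programs that cannot score
#' gaps as states. IUPAC ambiguity codes map to their standard subsets.
#'
#' @param seqs An aligned nucleotide [seq_set].
#' @param gap_mode `"fifth_state"` (gap is a scorable state) or `"missing"`.
#' @param site_weights Optional non-negative integer weights per site
#'   (default all 1).
#' @return A `char_matrix`: integer bitmask matrix (taxa x sites) with
#'   attributes `alphabet`, `gap_mode`, `weights`.
#' @export
encode_matrix <- function(seqs, gap_mode = c("fifth_state", "missing"),
                          site_weights = NULL) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(seqs, "seq_set"))
  if (seq_alphabet(seqs) != "nucleotide") {
    stop("encode_matrix expects nucleotide sequences", call. = FALSE)
  }
  if (!is_aligned(seqs)) stop("input must be aligned", call. = FALSE)
  lut <- .IUPAC_BITS
  if (gap_mode == "fifth_state") {
    lut <- c(lut, "-" = 16L, "?" = 31L)
  } else {
    lut <- c(lut, "-" = 15L, "?" = 15L)
  }
  m <- seq_char_matrix(seqs)
  bits <- matrix(lut[m], nrow = nrow(m), dimnames = list(rownames(m), NULL))
  if (anyNA(bits)) {
    bad <- which(is.na(bits), arr.ind = TRUE)[1, ]
    stop(sprintf("unknown character '%s' in '%s' at column %d",
                 m[bad[1], bad[2]], rownames(m)[bad[1]], bad[2]),
         call. = FALSE)
  }
  if (is.null(site_weights)) site_weights <- rep(1L, ncol(bits))
  stopifnot(length(site_weights) == ncol(bits), all(site_weights >= 0))
  structure(bits,
            alphabet = if (gap_mode == "fifth_state")
              c("A", "C", "G", "T", "-") else c("A", "C", "G", "T"),
            gap_mode = gap_mode,
            weights = as.integer(site_weights),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix> %d taxa x %d sites, gap_mode=%s\n",
              nrow(x), ncol(x), attr(x, "gap_mode")))
  invisible(x)
}

n_states <- function(matrix) length(attr(matrix, "alphabet"))

# Render bitmasks back to characters (for TNT export and debugging).
decode_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "char_matrix"))
  rev_lut <- character(32)
  for (ch in names(.IUPAC_BITS)) rev_lut[.IUPAC_BITS[[ch]] + 1L] <- ch
  rev_lut[15L + 1L] <- "N"  # prefer N over X for the full nucleotide set
  rev_lut[16L + 1L] <- "-"
  rev_lut[31L + 1L] <- "?"
  # remaining gap-containing sets have no single-character code; widen to ?
  for (b in 17:30) if (rev_lut[b + 1L] == "") rev_lut[b + 1L] <- "?"
  ch <- matrix(rev_lut[unclass(matrix) + 1L], nrow = nrow(matrix),
               dimnames = dimnames(matrix))
  stats::setNames(apply(ch, 1L, paste0, collapse = ""), rownames(matrix))
}

# Subset sites (used by the bootstrap); keeps attributes coherent.
subset_sites <- function(matrix, idx) {
  structure(unclass(matrix)[, idx, drop = FALSE],
            alphabet = attr(matrix, "alphabet"),
            gap_mode = attr(matrix, "gap_mode"),
            weights = attr(matrix, "weights")[idx],
            class = "char_matrix")
}
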