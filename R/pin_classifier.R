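#' Classifier configuration for PIN morphology types
#'
#' The five PIN morphologies are defined by the arrangement of transmembrane
#' domains (TMDs) and the length of the central hydrophilic loop between the
#' N- and C-terminal TMD blocks: 1 = two TMD blocks with a long loop, 2 =
#' two blocks with a short loop, 3 = two blocks with a reduced
#' (intermediate) loop, 4 = TMDs at the C-terminal end only, 5 = TMDs at the
#' N-terminal end only. The literature gives these criteria qualitatively;
#' the numeric cutoffs here are package decisions, exposed so they can be
#' changed.
#'
#' @param long_loop_min Minimum central-loop length (aa) for type 1.
#' @param reduced_loop_min Minimum loop length (aa) for type 3 (below it,
#'   type 2).
#' @param terminal_fraction Fraction of the protein length defining the
#'   terminal halves used for types 4 and 5.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(long_loop_min = 200, reduced_loop_min = 100,
                              terminal_fraction = 0.5) {
  stopifnot(reduced_loop_min > 0, long_loop_min > reduced_loop_min,
            terminal_fraction > 0, terminal_fraction < 1)
  structure(list(long_loop_min = long_loop_min,
                 reduced_loop_min = reduced_loop_min,
                 terminal_fraction = terminal_fraction),
            class = "classifier_config")
}

validate_tmds <- function(tmds, protein_length) {
  if (is.null(tmds) || nrow(tmds) == 0) return(invisible(NULL))
  stopifnot(all(c("start", "end") %in% colnames(tmds)))
  if (any(tmds$start > tmds$end) || any(tmds$start < 1) ||
      any(tmds$end > protein_length)) {
    stop("TMD intervals must be within [1, protein_length] with start <= end",
         call. = FALSE)
  }
  o <- order(tmds$start)
  tmds <- tmds[o, , drop = FALSE]
  if (nrow(tmds) > 1 &&
      any(tmds$start[-1] <= tmds$end[-nrow(tmds)])) {
    stop("TMD intervals must not overlap", call. = FALSE)
  }
  tmds
}

#' Classify a PIN protein into morphology types 1-5
#'
#' From the protein length and its TMD intervals (1-based inclusive, as
#' reported by TMD predictors): the central hydrophilic loop is the largest
#' gap between consecutive TMDs, splitting the TMDs into an N-terminal and a
#' C-terminal block. Proteins whose TMDs all lie in the N-terminal fraction
#' of the chain are type 5, those with TMDs only in the C-terminal fraction
#' are type 4; otherwise the loop length decides between long (1), reduced
#' (3) and short (2). Documented per-gene overrides (e.g. genes known to be
#' ordinary long forms despite a partial TMD prediction) are applied last
#' and recorded in the output. TMD predictions are hypotheses pending
#' structural confirmation; treat the assigned types accordingly.
#'
#' @param protein_length Protein length in amino acids.
#' @param tmds Data frame with columns `start`, `end` (1-based inclusive),
#'   one row per TMD; intervals must be disjoint and within the protein.
#' @param id Optional identifier (used for override lookup and output).
#' @param cfg A [classifier_config()].
#' @param overrides Named integer vector id -> forced type.
#' @return A one-row tibble: `id`, `type`, `loop_length`, `n_tmd_nblock`,
#'   `n_tmd_cblock`, `overridden`.
#' @examples
#' classify_pin(620, data.frame(start = c(10, 40, 70, 100, 130,
#'                                        470, 500, 530, 560, 590),
#'                              end   = c(30, 60, 90, 120, 150,
#'                                        490, 520, 550, 580, 610)))
#' @export
classify_pin <- function(protein_length, tmds, id = NA_character_,
                         cfg = classifier_config(), overrides = NULL) {
  stopifnot(protein_length >= 1)
  tmds <- validate_tmds(tmds, protein_length)
  if (is.null(tmds) || nrow(tmds) == 0) {
    warning("no TMDs: type unassigned", call. = FALSE)
    return(tibble::tibble(id = id, type = NA_integer_,
                          loop_length = NA_real_, n_tmd_nblock = 0L,
                          n_tmd_cblock = 0L, overridden = FALSE))
  }
  n <- nrow(tmds)
  if (n == 1L) {
    loop <- 0
    n_block <- if (tmds$end[1] <= cfg$terminal_fraction * protein_length)
      c(1L, 0L) else c(0L, 1L)
  } else {
    gaps <- tmds$start[-1] - tmds$end[-n] - 1
    g <- which.max(gaps)
    loop <- gaps[g]
    n_block <- c(g, n - g)
  }
  all_in_nterm <- max(tmds$end) <= cfg$terminal_fraction * protein_length
  all_in_cterm <- min(tmds$start) > (1 - cfg$terminal_fraction) * protein_length
  type <- if (n_block[2] == 0L || all_in_nterm) {
    5L
  } else if (n_block[1] == 0L || all_in_cterm) {
    4L
  } else if (loop >= cfg$long_loop_min) {
    1L
  } else if (loop >= cfg$reduced_loop_min) {
    3L
  } else {
    2L
  }
  overridden <- FALSE
  if (!is.null(overrides) && !is.na(id) && id %in% names(overrides)) {
    type <- as.integer(overrides[[id]])
    overridden <- TRUE
  }
  tibble::tibble(id = id, type = type, loop_length = as.numeric(loop),
                 n_tmd_nblock = n_block[1], n_tmd_cblock = n_block[2],
                 overridden = overridden)
}

#' Classify a table of TMD layouts
#'
#' @param layouts Data frame/tibble with columns `id`, `protein_length`,
#'   `tmd_intervals` (semicolon-separated `start-end` pairs, e.g.
#'   `"12-34;56-78"`).
#' @param cfg A [classifier_config()].
#' @param overrides Named integer vector id -> forced type.
#' @return A tibble, one row per input, as [classify_pin()].
#' @export
classify_pin_table <- function(layouts, cfg = classifier_config(),
                               overrides = NULL) {
  stopifnot(all(c("id", "protein_length", "tmd_intervals") %in%
                  names(layouts)))
  rows <- lapply(seq_len(nrow(layouts)), function(i) {
    classify_pin(layouts$protein_length[i],
                 parse_tmd_intervals(layouts$tmd_intervals[i]),
                 id = layouts$id[i], cfg = cfg, overrides = overrides)
  })
  dplyr::bind_rows(rows)
}

parse_tmd_intervals <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  data.frame(start = as.integer(vapply(parts, `[`, character(1), 1)),
             end = as.integer(vapply(parts, `[`, character(1), 2)))
}

format_tmd_intervals <- function(tmds) {
  paste(sprintf("%d-%d", tmds$start, tmds$end), collapse = ";")
}

#' The documented morphology-type overrides
#'
#' Two genes in the packaged PIN morphology survey show no notable sequence
#' difference from long forms but were predicted with only an N-terminal TMD
#' block; they are coded as long (type 1) by override.
#'
#' @return Named integer vector suitable for `overrides =` arguments.
#' @export
pin_default_overrides <- function() {
  c(OsPIN3a = 1L, Aco018694 = 1L)
}
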