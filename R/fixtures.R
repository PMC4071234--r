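#' Packaged PIN morphology survey
#'
#' The published survey of 151 PIN proteins shipped with the package:
#' terminal name, protein length (aa), number of predicted TMDs, morphology
#' type label and numeric score (1-5), and whether the score was assigned by
#' the documented override rather than the TMD layout (two genes predicted
#' with an N-terminal TMD block only but otherwise indistinguishable from
#' long forms).
#'
#' @return A tibble with columns `terminal`, `protein_length`, `n_tmd`,
#'   `type_label`, `score`, `override`.
#' @export
pin_morphology_survey <- function() {
  path <- system.file("extdata", "pin_morphology.tsv", package = "phylomask")
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Synthetic TMD layouts for the packaged survey
#'
#' The survey prints protein lengths and TMD counts but not the TMD
#' interval coordinates, so layouts are reconstructed here: for each row a
#' deterministic [simulate_tmd_protein()] draw with the printed length and
#' TMD count, generated under the geometry of the printed type (override
#' rows are generated as N-terminal-only layouts, their pre-override
#' morphology). These layouts are synthetic stand-ins consistent with the
#' printed columns, not the original TMD predictions.
#'
#' @param survey Output of [pin_morphology_survey()] (or a subset).
#' @return A tibble with columns `id`, `protein_length`, `tmd_intervals`,
#'   `true_type`, `expected_score`, suitable for [classify_pin_table()].
#' @export
pin_survey_layouts <- function(survey = pin_morphology_survey()) {
  rows <- lapply(seq_len(nrow(survey)), function(i) {
    geom_type <- if (survey$override[i]) 5L else survey$score[i]
    rec <- simulate_tmd_protein(geom_type, survey$protein_length[i],
                                n_tmd = survey$n_tmd[i], seed = 1000L + i)
    rec$id <- survey$terminal[i]
    rec$expected_score <- survey$score[i]
    rec
  })
  dplyr::bind_rows(rows)
}

#' Morphology character of the packaged survey
#'
#' @param survey Output of [pin_morphology_survey()] (or a subset).
#' @return A [morph_character()] with one singleton state per terminal.
#' @export
pin_survey_character <- function(survey = pin_morphology_survey()) {
  morph_character(stats::setNames(as.list(survey$score), survey$terminal))
}
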