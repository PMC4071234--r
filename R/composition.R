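#' Per-codon-position nucleotide composition
#'
#' Computes, for every gene (taxon) in a codon alignment, the frequency of
#' each base T, C, A, G at each codon position 1-3. Gaps, N, ? and IUPAC
#' ambiguity codes are excluded from the denominator; a gene x position cell
#' with zero counted bases yields `NA` frequencies and is excluded from
#' downstream summaries.
#'
#' @param aln A [codon_alignment][as_codon_alignment].
#' @param groups Optional named character vector mapping taxon to a group
#'   label (e.g. monocot/dicot); unnamed genes get group `NA`.
#' @return A tibble with columns `gene`, `group`, `position`, `base`, `freq`,
#'   `n_counted`; class `composition_profile`.
#' @export
position_composition <- function(aln, groups = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  bases <- c("T", "C", "A", "G")
  rows <- list()
  for (i in seq_along(aln)) {
    chars <- strsplit(aln[[i]], "")[[1]]
    pos <- rep_len(1:3, length(chars))
    for (p in 1:3) {
      cc <- chars[pos == p]
      cc <- cc[cc %in% bases]
      n <- length(cc)
      freq <- if (n == 0) rep(NA_real_, 4) else
        as.numeric(table(factor(cc, levels = bases))) / n
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = names(aln)[i], position = p, base = bases,
        freq = freq, n_counted = n)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$group <- if (is.null(groups)) NA_character_ else
    unname(groups[out$gene])
  out <- out[, c("gene", "group", "position", "base", "freq", "n_counted")]
  class(out) <- c("composition_profile", class(out))
  out
}

#' Summarize composition across genes
#'
#' Means of the per-gene frequencies with normal-approximation 95% confidence
#' intervals (mean +/- 1.96 sd/sqrt(n)), treating genes as the sampling
#' units. Groups with a single gene report the mean with `NA` interval
#' bounds; gene x position cells with no counted bases are dropped first.
#'
#' @param profile Output of [position_composition()].
#' @return A tibble with columns `group`, `position`, `base`, `mean`,
#'   `sd`, `n`, `ci_lo`, `ci_hi`.
#' @export
composition_summary <- function(profile) {
  stopifnot(inherits(profile, "composition_profile"))
  df <- dplyr::filter(profile, !is.na(.data$freq))
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$position, .data$base),
    mean = mean(.data$freq), sd = stats::sd(.data$freq),
    n = dplyr::n(), .groups = "drop")
  hw <- 1.96 * out$sd / sqrt(out$n)
  out$ci_lo <- ifelse(out$n >= 2, out$mean - hw, NA_real_)
  out$ci_hi <- ifelse(out$n >= 2, out$mean + hw, NA_real_)
  out
}

#' Per-gene GC fraction at chosen codon positions
#'
#' @param x A [codon_alignment][as_codon_alignment], or a
#'   `composition_profile` from [position_composition()].
#' @param positions Subset of `1:3`; which codon positions to pool.
#' @return A tibble with columns `gene`, `gc` (fraction of counted bases that
#'   are G or C at the requested positions; `NA` if none counted).
#' @export
gc_percent <- function(x, positions = 3L) {
  stopifnot(all(positions %in% 1:3))
  if (inherits(x, "codon_alignment")) x <- position_composition(x)
  stopifnot(inherits(x, "composition_profile"))
  df <- dplyr::filter(x, .data$position %in% positions, !is.na(.data$freq))
  df$count <- df$freq * df$n_counted
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$gene),
    gc = sum(.data$count[.data$base %in% c("G", "C")]) / sum(.data$count),
    .groups = "drop")
  # preserve input gene order, and genes with nothing counted as NA
  genes <- unique(x$gene)
  out <- out[match(genes, out$gene), ]
  out$gene <- genes
  tibble::as_tibble(out)
}

#' Welch t-test of GC percentages between two groups
#'
#' Two-sided unequal-variance (Welch) two-sample t-test, the conservative
#' default when no variance assumption is justified. Degenerate input where
#' both groups are constant and equal returns `t = 0, p = 1`.
#'
#' @param group_a,group_b Numeric vectors of per-gene GC percentages, each of
#'   length at least 2.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `method`.
#' @export
gc_ttest <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1,
                            mean_a = mean(group_a), mean_b = mean(group_b),
                            method = "Welch two-sample t-test"))
    }
    stop("both groups constant with different means: t undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 method = "Welch two-sample t-test")
}

#' Plot a composition summary
#'
#' Bar chart of mean base frequencies per codon position with 95% CI error
#' bars, faceted by group, mirroring the usual presentation of codon-position
#' composition scans.
#'
#' @param summary Output of [composition_summary()].
#' @return A ggplot object.
#' @export
plot_composition <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$position), y = .data$mean,
                               fill = .data$base)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "codon position", y = "mean frequency", fill = "base") +
    ggplot2::theme_minimal()
}
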