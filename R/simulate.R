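#' Simulation configuration for GC3-biased codon alignments
#'
#' Describes site-independent nucleotide evolution of codons down a known
#' tree under an F81-type model (each position drawn toward a stationary
#' base composition at a rate proportional to the branch length in expected
#' substitutions per site). First and second codon positions evolve toward a
#' uniform composition on every branch; third positions evolve toward a
#' composition with GC content `gc3_default`, except on branches all of
#' whose descendant leaves are in `biased_taxa`, where the third-position
#' equilibrium GC is `gc3_biased`. This is the minimal mechanism producing
#' the phylogenetic artifact of interest: unrelated GC-shifted lineages
#' acquire convergent third-position states.
#'
#' @param tree A rooted or unrooted [ape::phylo] with branch lengths
#'   (expected substitutions per site at relative rate 1).
#' @param n_codons Number of codons to simulate.
#' @param gc3_default Equilibrium GC at third positions on unbiased branches.
#' @param gc3_biased Equilibrium GC at third positions on biased branches.
#' @param biased_taxa Leaves whose terminal lineages are GC3-biased.
#' @param rates Relative substitution rates of codon positions 1, 2, 3.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tree, n_codons = 300L, gc3_default = 0.5,
                       gc3_biased = 0.8, biased_taxa = character(0),
                       rates = c(0.3, 0.2, 1.0)) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0), n_codons >= 1,
            gc3_default > 0, gc3_default < 1,
            gc3_biased > 0, gc3_biased < 1,
            length(rates) == 3, all(rates > 0),
            all(biased_taxa %in% tree$tip.label))
  structure(list(tree = tree, n_codons = as.integer(n_codons),
                 gc3_default = gc3_default, gc3_biased = gc3_biased,
                 biased_taxa = biased_taxa, rates = rates),
            class = "sim_config")
}

.gc_pi <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                         T = (1 - gc) / 2)

# F81 transition: with prob 1-exp(-beta*t) redraw from pi, else keep
.f81_evolve <- function(states, t, pi) {
  beta <- 1 / (1 - sum(pi^2))
  p_change <- 1 - exp(-beta * t)
  redraw <- stats::runif(length(states)) < p_change
  states[redraw] <- sample.int(4L, sum(redraw), replace = TRUE, prob = pi)
  states
}

#' Simulate a codon alignment with lineage-specific GC3 bias
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; same seed, identical output.
#' @return A list with `alignment` (a
#'   [codon_alignment][as_codon_alignment]) and `true_tree` (the input
#'   topology).
#' @export
simulate_alignment <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- ape::reorder.phylo(cfg$tree, "cladewise")  # root-to-tip edge order
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  L1 <- cfg$n_codons
  esets <- edge_tipsets(tree)
  edge_biased <- vapply(esets, function(s)
    length(cfg$biased_taxa) > 0 && all(s %in% cfg$biased_taxa), logical(1))
  pi_unif <- rep(0.25, 4)
  pi_def <- .gc_pi(cfg$gc3_default)
  pi_bias <- .gc_pi(cfg$gc3_biased)
  withr::with_seed(seed, {
    # rows: nodes; per position class a state matrix (node x n_codons)
    pos_states <- lapply(1:3, function(p) {
      m <- matrix(0L, nrow = nt + nn, ncol = L1)
      pi_root <- if (p == 3L) pi_def else pi_unif
      m[nt + 1L, ] <- sample.int(4L, L1, replace = TRUE, prob = pi_root)
      m
    })
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      bl <- tree$edge.length[e]
      for (pos in 1:3) {
        pi <- if (pos == 3L) {
          if (edge_biased[e]) pi_bias else pi_def
        } else pi_unif
        pos_states[[pos]][ch, ] <-
          .f81_evolve(pos_states[[pos]][p, ], bl * cfg$rates[pos], pi)
      }
    }
  })
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(nt), function(i) {
    m <- rbind(pos_states[[1]][i, ], pos_states[[2]][i, ],
               pos_states[[3]][i, ])
    paste0(bases[as.vector(m)], collapse = "")
  }, character(1))
  aln <- as_codon_alignment(stats::setNames(seqs, tree$tip.label),
                            provenance = "simulated (F81, lineage GC3 bias)")
  list(alignment = aln, true_tree = cfg$tree)
}

#' Default configuration of the convergence experiment
#'
#' An eight-leaf balanced tree emulating a deep, rapid gene-family
#' radiation: very short internal branches (0.04 expected
#' substitutions/site at relative rate 1) under long terminals (1.0), 2000
#' codons, position rates 0.3/0.2/3.0 (third positions fast and effectively
#' saturated on terminal branches, as third positions are in deep plant
#' gene phylogenies), and two non-sister leaves (`t3`, `t6`) whose terminal
#' branches evolve third positions toward GC 0.8 while all other branches
#' use 0.5. In this regime the shared composition of the two biased
#' lineages outweighs the short true internal edges, so an unmasked
#' parsimony analysis is drawn toward grouping them.
#'
#' @return A [sim_config()] plus attribute `biased_pair`.
#' @export
convergence_default_config <- function() {
  tr <- read_newick(paste0(
    "(((t1:1,t2:1):0.04,(t3:1,t4:1):0.04):0.04,",
    "((t5:1,t6:1):0.04,(t7:1,t8:1):0.04):0.04);"))
  cfg <- sim_config(tr, n_codons = 2000L, gc3_default = 0.5, gc3_biased = 0.8,
                    biased_taxa = c("t3", "t6"), rates = c(0.3, 0.2, 3.0))
  attr(cfg, "biased_pair") <- c("t3", "t6")
  cfg
}

#' Does a tree's strict consensus group a pair of leaves as a cherry?
#'
#' @noRd
groups_pair <- function(tree, pair) {
  keys <- c(paste(sort(pair), collapse = "|"),
            paste(sort(setdiff(tree$tip.label, pair)), collapse = "|"))
  any(tree_splits(tree) %in% keys)
}

#' Convergence experiment: does GC masking remove the artifactual grouping?
#'
#' For each replicate, simulates an alignment under `cfg`, then runs the
#' same heuristic parsimony search on (i) the raw three-position alignment
#' and (ii) the masked alignment (third positions stripped, then G/C
#' replaced by N), and records whether the strict consensus groups the
#' GC-biased pair and the Robinson-Foulds distance of the consensus to the
#' true tree. Under a real bias the unmasked analysis is expected to group
#' the biased pair more often and sit farther from the truth.
#'
#' @param cfg A [sim_config()]; defaults to [convergence_default_config()].
#' @param biased_pair Two non-sister leaf labels (defaults to the config's
#'   `biased_pair` attribute).
#' @param replicates Number of simulation replicates.
#' @param seed Integer seed.
#' @param builds,swap Search effort per replicate (passed to
#'   [heuristic_search()]).
#' @return A tibble with one row per replicate: `replicate`,
#'   `unmasked_groups_pair`, `masked_groups_pair`, `rf_unmasked`,
#'   `rf_masked`.
#' @export
convergence_experiment <- function(cfg = convergence_default_config(),
                                   biased_pair = attr(cfg, "biased_pair"),
                                   replicates = 20L, seed = 1L,
                                   builds = 2L, swap = "SPR") {
  stopifnot(inherits(cfg, "sim_config"), length(biased_pair) == 2)
  true_unrooted <- ape::unroot(cfg$tree)
  if (groups_pair(true_unrooted, biased_pair)) {
    stop("biased_pair must be non-sister in the true tree", call. = FALSE)
  }
  rep_seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max %/% 2L, replicates)
  })
  one_treatment <- function(seqs, s) {
    m <- encode_matrix(seqs, gap_mode = "fifth_state")
    res <- heuristic_search(m, builds = builds, swap = swap,
                            keep_all_shortest = FALSE, seed = s)
    cons <- strict_consensus(res$best_trees)
    list(groups = groups_pair(cons, biased_pair),
         rf = as.numeric(suppressMessages(
           phangorn::RF.dist(ape::unroot(cons), true_unrooted))))
  }
  rows <- lapply(seq_len(replicates), function(r) {
    sim <- simulate_alignment(cfg, seed = rep_seeds[r])
    raw <- one_treatment(sim$alignment, rep_seeds[r])
    masked <- one_treatment(mask_gc_to_n(strip_third_positions(sim$alignment)),
                            rep_seeds[r])
    tibble::tibble(replicate = r,
                   unmasked_groups_pair = raw$groups,
                   masked_groups_pair = masked$groups,
                   rf_unmasked = raw$rf, rf_masked = masked$rf)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a TMD layout of a given PIN morphology type
#'
#' Draws a transmembrane-domain layout whose geometry realizes the requested
#' morphology type, so that [classify_pin()] with default configuration
#' recovers the generating type by construction: types 1-3 place an
#' N-terminal and a C-terminal TMD block around a central loop of the
#' type's length class; types 4 and 5 confine all TMDs to the C- or
#' N-terminal half. Residual slack is distributed to the termini by a
#' seeded draw.
#'
#' @param type Morphology type 1-5.
#' @param length Protein length (aa).
#' @param n_tmd Number of TMDs (default: 9 for types 1-3, 4 for types 4-5).
#' @param seed Integer seed.
#' @return A one-row tibble: `id`, `protein_length`, `tmd_intervals`,
#'   `true_type`.
#' @export
simulate_tmd_protein <- function(type, length, n_tmd = NULL, seed = 1L) {
  stopifnot(type %in% 1:5, length >= 30)
  if (is.null(n_tmd)) n_tmd <- if (type %in% 1:3) 9L else 4L
  stopifnot(n_tmd >= 1)
  gap_in <- 4L
  block_width <- function(m, w) if (m == 0L) 0L else m * w + (m - 1L) * gap_in
  make_block <- function(start, m, w) {
    s <- start + (0:(m - 1L)) * (w + gap_in)
    data.frame(start = s, end = s + w - 1L)
  }
  withr::with_seed(seed, {
    for (w in seq(18L, 12L, by = -2L)) {
      if (type %in% 4:5) {
        wd <- block_width(n_tmd, w)
        half <- floor(length / 2)
        if (wd > half - 2L) next
        f <- sample.int(half - wd - 1L, 1L)
        tmds <- if (type == 5L) make_block(f + 1L, n_tmd, w) else
          make_block(length - f - wd + 1L, n_tmd, w)
        if (type == 4L && min(tmds$start) <= length / 2) next
        if (type == 5L && max(tmds$end) > length / 2) next
      } else {
        if (n_tmd < 2L) stop("types 1-3 need at least 2 TMDs", call. = FALSE)
        a <- ceiling(n_tmd / 2)
        b <- n_tmd - a
        wa <- block_width(a, w)
        wb <- block_width(b, w)
        loop_rng <- switch(as.character(type),
                           "1" = c(200L, .Machine$integer.max),
                           "2" = c(gap_in + 2L, 99L),
                           "3" = c(100L, 199L))
        loop_max_avail <- length - wa - wb - 4L  # >= 2 aa at each terminus
        if (loop_max_avail < loop_rng[1]) next
        loop_choices <- seq(loop_rng[1], min(loop_rng[2], loop_max_avail))
        loop <- if (length(loop_choices) == 1L) loop_choices else
          sample(loop_choices, 1L)
        slack <- length - wa - wb - loop
        cap <- floor(length / 2) - 2L
        f <- sample.int(min(slack - 2L, cap), 1L)
        bk <- slack - f
        if (bk > cap || bk < 1L) next
        tmds <- rbind(make_block(f + 1L, a, w),
                      make_block(f + wa + loop + 1L, b, w))
      }
      rec <- tibble::tibble(
        id = sprintf("sim_type%d_len%d_seed%d", type, length, seed),
        protein_length = as.integer(length),
        tmd_intervals = format_tmd_intervals(tmds),
        true_type = as.integer(type))
      return(rec)
    }
    stop(sprintf("no feasible type-%d layout for length %d with %d TMDs",
                 type, length, n_tmd), call. = FALSE)
  })
}
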