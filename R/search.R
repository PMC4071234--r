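# Tree surgery works over Newick strings: a piece of a bisected tree is
# re-rooted along one of its edges with ape::root, rendered as "(X,Y);", and
# joined to the other piece by string assembly before re-parsing. All ops are
# on cladograms (no branch lengths).

# tip labels below each edge (child side), in phy$edge row order
edge_tipsets <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  nt <- length(phy$tip.label)
  sets <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    sets[[p]] <- c(sets[[p]], sets[[po$edge[k, 2]]])
  }
  lapply(seq_len(nrow(phy$edge)), function(i) sets[[phy$edge[i, 2]]])
}

# "X,Y" inner string of phy re-rooted on the edge above `tips_below`
root_inner <- function(phy, tips_below) {
  if (length(phy$tip.label) == 2L) {
    return(paste(sort(phy$tip.label), collapse = ","))
  }
  r <- ape::root(phy, outgroup = tips_below, resolve.root = TRUE)
  s <- ape::write.tree(r)
  sub("\\);$", "", sub("^\\(", "", s))
}

# distinct attachment points of a piece: list of inner "X,Y" strings, or the
# bare label for a single-leaf piece (kind tells the join how to use them)
piece_attach_points <- function(piece) {
  if (is.character(piece)) {
    return(list(kind = "leaf", label = piece))
  }
  nt <- length(piece$tip.label)
  if (nt == 2L) {
    return(list(kind = "tree",
                inner = paste(sort(piece$tip.label), collapse = ",")))
  }
  esets <- edge_tipsets(piece)
  # one attachment point per edge; complementary tipsets describe the same
  # edge only for the two root-adjacent edges of a rooted shape, which an
  # unrooted piece does not have
  inner <- vapply(esets, function(s) root_inner(piece, s), character(1))
  list(kind = "tree", inner = unique(inner))
}

keep_piece <- function(phy, tips) {
  if (length(tips) == 1L) return(tips)
  p <- ape::keep.tip(phy, tips)
  if (length(tips) > 2L) p <- ape::unroot(p)
  p
}

join_pieces <- function(ap1, ap2) {
  # all reconnections of two pieces given their attachment points
  out <- character(0)
  if (ap1$kind == "leaf" && ap2$kind == "leaf") return(out)
  if (ap1$kind == "leaf") return(join_pieces(ap2, ap1))
  plugs <- if (ap2$kind == "leaf") ap2$label else paste0("(", ap2$inner, ")")
  for (inner in ap1$inner) {
    out <- c(out, paste0("(", inner, ",", plugs, ");"))
  }
  out
}

# TBR: bisect every edge, re-root both pieces on each of their edges, rejoin
tbr_neighbors <- function(phy) {
  tips_all <- phy$tip.label
  esets <- edge_tipsets(phy)
  out <- character(0)
  done <- character(0)
  for (i in seq_along(esets)) {
    A <- sort(esets[[i]])
    B <- sort(setdiff(tips_all, A))
    key <- paste(A, collapse = ";")
    if (paste(B, collapse = ";") %in% done) next
    done <- c(done, key)
    ap1 <- piece_attach_points(keep_piece(phy, A))
    ap2 <- piece_attach_points(keep_piece(phy, B))
    out <- c(out, join_pieces(ap1, ap2))
  }
  unique(out)
}

# SPR: prune each clade (w.r.t. rooting at the first leaf, which fixes each
# pruned subtree's own attachment orientation) and regraft on every edge of
# the remainder
spr_neighbors <- function(phy) {
  tips_all <- phy$tip.label
  nt <- length(tips_all)
  R0 <- ape::root(ape::unroot(phy), outgroup = tips_all[1],
                  resolve.root = TRUE)
  esets <- edge_tipsets(R0)
  out <- character(0)
  for (i in seq_along(esets)) {
    C <- esets[[i]]
    if (tips_all[1] %in% C || length(C) > nt - 2L) next
    plug <- if (length(C) == 1L) C else
      sub(";$", "", ape::write.tree(ape::extract.clade(R0, R0$edge[i, 2])))
    rem <- keep_piece(phy, setdiff(tips_all, C))
    ap <- piece_attach_points(rem)
    if (ap$kind == "leaf") next
    out <- c(out, paste0("(", ap$inner, ",", plug, ");"))
  }
  unique(out)
}

# ---- canonical splits -------------------------------------------------------

# nontrivial bipartitions as canonical keys: the side not containing the
# lexicographically smallest leaf, sorted and pipe-joined
tree_splits <- function(phy) {
  nt <- length(phy$tip.label)
  if (nt < 4L) return(character(0))
  minlab <- sort(phy$tip.label)[1]
  esets <- edge_tipsets(phy)
  keys <- vapply(esets, function(s) {
    if (length(s) < 2L || length(s) > nt - 2L) return(NA_character_)
    side <- if (minlab %in% s) setdiff(phy$tip.label, s) else s
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

# topology fingerprint: identical iff same unrooted (multifurcating) topology
splits_key <- function(phy) {
  paste(paste(sort(phy$tip.label), collapse = "|"),
        paste(sort(tree_splits(phy)), collapse = " & "), sep = " :: ")
}

dedup_trees <- function(trees) {
  keys <- vapply(trees, splits_key, character(1))
  trees[!duplicated(keys)]
}

# ---- zero-length branch collapsing -----------------------------------------

contract_edge <- function(phy, e) {
  phy$edge.length <- rep(1, nrow(phy$edge))
  phy$edge.length[e] <- 0
  out <- ape::di2multi(phy, tol = 0.5)
  out$edge.length <- NULL
  out
}

#' Collapse zero-length branches of a most-parsimonious tree
#'
#' Contracts every internal branch whose minimum number of changes is zero,
#' i.e. whose removal (creating a polytomy) leaves the parsimony length
#' unchanged; contraction is repeated until no such branch remains. This is
#' the usual "collapse zero-length branches" post-processing of parsimony
#' searches, so that unsupported resolutions do not inflate the tree count.
#'
#' @param tree An [ape::phylo] (binary or already partly collapsed).
#' @param matrix The [char_matrix][encode_matrix] the tree was scored on.
#' @return A possibly multifurcating [ape::phylo].
#' @export
collapse_zero_branches <- function(tree, matrix) {
  len <- sankoff_length(tree, matrix)
  repeat {
    nt <- length(tree$tip.label)
    internal <- which(tree$edge[, 2] > nt)
    hit <- FALSE
    for (e in internal) {
      cand <- contract_edge(tree, e)
      if (sankoff_length(cand, matrix) == len) {
        tree <- cand
        hit <- TRUE
        break
      }
    }
    if (!hit) return(tree)
  }
}

# ---- searches ---------------------------------------------------------------

new_search_result <- function(best_length, best_trees, replicates_run, seed) {
  structure(list(best_length = best_length,
                 best_trees = structure(best_trees, class = "multiPhylo"),
                 replicates_run = replicates_run, seed = seed),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> best length %d, %d tree(s), %d replicate(s)%s\n",
              x$best_length, length(x$best_trees), x$replicates_run,
              if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  invisible(x)
}

#' Wagner (random stepwise-addition) starting tree
#'
#' Builds a starting tree by inserting taxa in seeded random order, each on
#' the edge that minimizes the incremental parsimony length; ties are broken
#' by a seeded uniform draw. The classical starting point for heuristic
#' parsimony searches.
#'
#' @param matrix A [char_matrix][encode_matrix] with at least 3 taxa.
#' @param seed Integer seed; same seed, same tree.
#' @return An unrooted binary [ape::phylo].
#' @export
wagner_build <- function(matrix, seed = 1L) {
  taxa <- rownames(matrix)
  if (length(taxa) < 3L) stop("need at least 3 taxa", call. = FALSE)
  withr::with_seed(seed, {
    ord <- sample(taxa)
    cur <- read_newick(paste0("(", ord[1], ",", ord[2], ",", ord[3], ");"))
    for (x in ord[-(1:3)]) {
      esets <- edge_tipsets(cur)
      cands <- vapply(esets, function(s) {
        paste0("(", root_inner(cur, s), ",", x, ");")
      }, character(1))
      sub <- encode_submatrix(matrix, c(cur$tip.label, x))
      scores <- vapply(cands, function(nwk) {
        fitch_length(ape::read.tree(text = nwk), sub)
      }, numeric(1))
      best <- which(scores == min(scores))
      pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
      cur <- ape::read.tree(text = cands[pick])
    }
    cur
  })
}

encode_submatrix <- function(matrix, taxa) {
  structure(unclass(matrix)[taxa, , drop = FALSE],
            alphabet = attr(matrix, "alphabet"),
            gap_mode = attr(matrix, "gap_mode"),
            weights = attr(matrix, "weights"),
            class = "char_matrix")
}

hill_climb <- function(tree, matrix, swap) {
  neigh_fun <- if (swap == "TBR") tbr_neighbors else spr_neighbors
  len <- fitch_length(tree, matrix)
  repeat {
    nwk <- neigh_fun(tree)
    improved <- FALSE
    for (s in nwk) {
      cand <- ape::read.tree(text = s)
      l <- fitch_length(cand, matrix)
      if (l < len) {
        tree <- cand
        len <- l
        improved <- TRUE
        break
      }
    }
    if (!improved) return(list(tree = tree, length = len))
  }
}

#' Heuristic maximum-parsimony search
#'
#' Multiple seeded random-addition Wagner builds, each followed by
#' branch-swapping (TBR by default, SPR optionally) to a local optimum; all
#' trees attaining the best length found are pooled, optionally extended by
#' their equal-length swap neighbors, zero-length branches are collapsed, and
#' duplicate topologies removed. Same seed, same result.
#'
#' @param matrix A [char_matrix][encode_matrix] with at least 4 taxa.
#' @param builds Number of random-addition replicates.
#' @param swap `"TBR"` or `"SPR"`.
#' @param keep_all_shortest Also harvest equal-length neighbors of each
#'   optimum (capped at `max_trees`).
#' @param seed Integer seed.
#' @param max_trees Cap on the number of shortest trees retained.
#' @return A `search_result`: `best_length`, `best_trees` (multiPhylo,
#'   zero-length branches collapsed, deduplicated), `replicates_run`, `seed`.
#' @export
heuristic_search <- function(matrix, builds = 100L, swap = c("TBR", "SPR"),
                             keep_all_shortest = TRUE, seed = 1L,
                             max_trees = 100L) {
  swap <- match.arg(swap)
  stopifnot(inherits(matrix, "char_matrix"))
  if (nrow(matrix) < 4L) stop("need at least 4 taxa", call. = FALSE)
  optima <- list()
  lens <- integer(0)
  for (b in seq_len(builds)) {
    start <- wagner_build(matrix, seed = seed + 7919L * b)
    res <- hill_climb(start, matrix, swap)
    optima[[b]] <- res$tree
    lens[b] <- res$length
  }
  best <- min(lens)
  pool <- optima[lens == best]
  if (keep_all_shortest) {
    neigh_fun <- if (swap == "TBR") tbr_neighbors else spr_neighbors
    extra <- list()
    for (t in pool) {
      if (length(pool) + length(extra) >= max_trees) break
      for (s in neigh_fun(t)) {
        cand <- ape::read.tree(text = s)
        if (fitch_length(cand, matrix) == best) {
          extra[[length(extra) + 1L]] <- cand
          if (length(pool) + length(extra) >= max_trees) break
        }
      }
    }
    pool <- c(pool, extra)
  }
  pool <- lapply(pool, collapse_zero_branches, matrix = matrix)
  pool <- dedup_trees(pool)
  if (length(pool) > max_trees) pool <- pool[seq_len(max_trees)]
  new_search_result(best, pool, builds, seed)
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology ((2n-5)!! of them) and scores
#' each; the exact global optimum, used as the oracle for the heuristic.
#' Refuses more than 9 taxa.
#'
#' @param matrix A [char_matrix][encode_matrix] with 4 to 9 taxa.
#' @return A `search_result` containing all optimal topologies
#'   (zero-length branches collapsed, deduplicated).
#' @export
exhaustive_search <- function(matrix) {
  stopifnot(inherits(matrix, "char_matrix"))
  n <- nrow(matrix)
  if (n < 4L) stop("need at least 4 taxa", call. = FALSE)
  if (n > 9L) stop("exhaustive enumeration refused for more than 9 taxa",
                   call. = FALSE)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(matrix))
  lens <- vapply(trees, fitch_length, numeric(1), matrix = matrix)
  best <- min(lens)
  pool <- trees[lens == best]
  pool <- lapply(pool, collapse_zero_branches, matrix = matrix)
  pool <- dedup_trees(pool)
  new_search_result(as.integer(best), pool, length(trees), NA_integer_)
}

#' Strict consensus of trees
#'
#' The tree whose internal edges are exactly the bipartitions present in
#' every input tree; all other edges are collapsed into polytomies.
#'
#' @param trees A list or multiPhylo of trees on the identical leaf set.
#' @return An unrooted (possibly multifurcating) [ape::phylo].
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1)
  tips <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), tips)) {
      stop("trees must share an identical leaf set", call. = FALSE)
    }
  }
  if (length(trees) == 1L) return(trees[[1]])
  ref <- tips[1]
  norm <- lapply(trees, function(t) {
    t$edge.length <- NULL
    ape::root(ape::unroot(t), outgroup = ref, resolve.root = TRUE)
  })
  class(norm) <- "multiPhylo"
  cons <- ape::consensus(norm, p = 1, check.labels = TRUE)
  ape::unroot(cons)
}

#' Parsimony bootstrap support
#'
#' Resamples alignment sites with replacement (same site count), runs a
#' reduced-effort heuristic search per pseudoreplicate, takes the strict
#' consensus of its shortest trees, and reports for each bipartition the
#' percentage of pseudoreplicate consensuses containing it. Deterministic
#' under `seed`.
#'
#' @param matrix A [char_matrix][encode_matrix] with at least 4 taxa.
#' @param replicates Number of pseudoreplicates.
#' @param builds_per_rep Wagner builds per pseudoreplicate.
#' @param swap Branch-swapping move for the per-replicate searches.
#' @param seed Integer seed.
#' @return A tibble with columns `split` (canonical pipe-joined leaf set of
#'   the side not containing the first leaf) and `support` (percent).
#' @export
bootstrap_support <- function(matrix, replicates = 1000L, builds_per_rep = 2L,
                              swap = "SPR", seed = 1L) {
  stopifnot(inherits(matrix, "char_matrix"), nrow(matrix) >= 4L)
  counts <- new.env(parent = emptyenv())
  withr::with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max %/% 2L, replicates)
  })
  for (r in seq_len(replicates)) {
    idx <- withr::with_seed(rep_seeds[r],
                            sample.int(ncol(matrix), replace = TRUE))
    boot <- subset_sites(matrix, idx)
    res <- heuristic_search(boot, builds = builds_per_rep, swap = swap,
                            keep_all_shortest = FALSE, seed = rep_seeds[r])
    cons <- strict_consensus(res$best_trees)
    for (sp in tree_splits(cons)) {
      counts[[sp]] <- (if (is.null(counts[[sp]])) 0L else counts[[sp]]) + 1L
    }
  }
  sp <- ls(counts)
  out <- tibble::tibble(
    split = sp,
    support = unname(vapply(sp, function(s) 100 * counts[[s]] / replicates,
                            numeric(1))))
  dplyr::arrange(out, dplyr::desc(.data$support), .data$split)
}
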