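#' Morphology characters
#'
#' An unordered multi-state character over states 1..5 for a set of taxa:
#' each taxon carries a non-empty subset of states (a singleton when scored,
#' the full set when missing). The default state labels are the five PIN
#' protein morphologies: 1 long, 2 short, 3 reduced central loop, 4
#' C-terminal TMD block only, 5 N-terminal TMD block only.
#'
#' @param states Named list mapping taxon to an integer vector of states
#'   (subset of 1..5), or a named integer vector of singletons.
#' @param labels Character vector naming the states.
#' @return An object of class `morph_character`.
#' @export
morph_character <- function(states,
                            labels = c("long", "short", "reduced",
                                       "C-terminal TMD only",
                                       "N-terminal TMD only")) {
  if (!is.list(states)) states <- lapply(states, identity)
  states <- lapply(states, function(s) sort(unique(as.integer(s))))
  if (is.null(names(states)) || any(!nzchar(names(states)))) {
    stop("all taxa must be named", call. = FALSE)
  }
  k <- length(labels)
  for (nm in names(states)) {
    s <- states[[nm]]
    if (length(s) == 0 || any(s < 1L | s > k)) {
      stop("state set for '", nm, "' must be a non-empty subset of 1..", k,
           call. = FALSE)
    }
  }
  structure(list(states = states, labels = labels),
            class = "morph_character")
}

#' @export
print.morph_character <- function(x, ...) {
  cat(sprintf("<morph_character> %d taxa, %d states (%s)\n",
              length(x$states), length(x$labels),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Read a morphology character from a two-column table
#'
#' @param tsv Path to a TSV with columns `terminal` and `score` (1-5).
#' @param all_taxa Optional character vector of all taxa that will appear on
#'   the tree; taxa absent from the table are set to full ambiguity (1..5).
#' @return A [morph_character()].
#' @export
character_from_table <- function(tsv, all_taxa = NULL) {
  df <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  if (!all(c("terminal", "score") %in% names(df))) {
    stop("table needs columns 'terminal' and 'score'", call. = FALSE)
  }
  if (any(df$score < 1 | df$score > 5 | df$score != as.integer(df$score))) {
    stop("scores must be integers in 1..5", call. = FALSE)
  }
  states <- stats::setNames(lapply(df$score, identity), df$terminal)
  if (!is.null(all_taxa)) {
    for (t in setdiff(all_taxa, df$terminal)) states[[t]] <- 1:5
  }
  morph_character(states)
}

# leaf-state incidence matrix: taxa x k logical
.char_allowed <- function(char, taxa) {
  k <- length(char$labels)
  m <- matrix(FALSE, nrow = length(taxa), ncol = k,
              dimnames = list(taxa, NULL))
  for (i in seq_along(taxa)) {
    s <- char$states[[taxa[i]]]
    if (is.null(s)) s <- seq_len(k)  # unlisted terminal: full ambiguity
    m[i, s] <- TRUE
  }
  m
}

#' Parsimony ancestral reconstruction (full MPR set)
#'
#' Unordered (unit-cost) Sankoff dynamic programming over a rooted tree,
#' polytomies allowed (a node's cost is summed over all its children, so the
#' method also applies to strict-consensus trees). Reports, for every
#' internal node, the set of states appearing in at least one
#' most-parsimonious reconstruction (the MPR set, by a re-rooting "up" pass),
#' the minimum cost, and the exact number of equally parsimonious
#' reconstructions (counted by product-sum DP over internal-node assignments;
#' ambiguous leaves contribute their cheapest resolution but are not
#' themselves enumerated).
#'
#' @param tree An [ape::phylo]. Reconstruction is over the internal nodes of
#'   the unrooted topology (a degree-2 root is collapsed first); an unrooted
#'   tree must come with `root_taxa` (e.g. the bryophyte copies) naming the
#'   outgroup at which the traversal is anchored.
#' @param char A [morph_character()] covering at least the tree's leaves.
#' @param root_taxa Optional character vector of outgroup leaves.
#' @return A `reconstruction_set`: list with `tree` (the rooted tree used),
#'   `min_cost`, `n_reconstructions`, `mpr` (list per internal node, named by
#'   ape node number, of MPR state vectors), `labels`.
#' @export
mpr_reconstruct <- function(tree, char, root_taxa = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(char, "morph_character"))
  if (!all(tree$tip.label %in% names(char$states))) {
    miss <- setdiff(tree$tip.label, names(char$states))
    stop("no character state for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # Reconstruction is over the internal nodes of the unrooted topology: a
  # degree-2 root is collapsed (for an unordered unit-cost character the
  # minimum cost, MPR sets and reconstruction count are then independent of
  # root placement, which only orients the traversal).
  if (!is.null(root_taxa)) {
    tree <- ape::root(ape::unroot(tree), outgroup = root_taxa,
                      resolve.root = FALSE)
  } else if (!ape::is.rooted(tree)) {
    if (length(tree$tip.label) > 3L) {
      stop("tree is unrooted; supply root_taxa to place the root",
           call. = FALSE)
    }
  } else {
    nt_ <- length(tree$tip.label)
    if (sum(tree$edge[, 1] == nt_ + 1L) == 2L && nt_ > 2L) {
      tree <- ape::unroot(tree)
    }
  }
  tree$edge.length <- NULL
  k <- length(char$labels)
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  BIG <- 1e9
  allowed <- .char_allowed(char, tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  children <- split(po$edge[, 2], po$edge[, 1])

  down <- matrix(0, nrow = nt + nn, ncol = k)       # min subtree cost | state
  cnt <- matrix(1, nrow = nt + nn, ncol = k)        # reconstructions | state
  down[seq_len(nt), ][!allowed] <- BIG
  node_order <- unique(po$edge[, 1])                # postorder parents
  contrib <- function(child, s) {
    # child's contribution to a parent fixed at state s
    if (child <= nt) {
      return(list(cost = if (allowed[child, s]) 0 else 1, count = 1))
    }
    cand <- down[child, ] + (seq_len(k) != s)
    m <- min(cand)
    list(cost = m, count = sum(cnt[child, cand == m]))
  }
  for (p in node_order) {
    for (s in seq_len(k)) {
      tot <- 0
      nrec <- 1
      for (ch in children[[as.character(p)]]) {
        cc <- contrib(ch, s)
        tot <- tot + cc$cost
        nrec <- nrec * cc$count
      }
      down[p, s] <- min(tot, BIG)
      cnt[p, s] <- nrec
    }
  }
  root <- nt + 1L
  min_cost <- min(down[root, ])
  opt_root <- down[root, ] == min_cost
  n_rec <- sum(cnt[root, opt_root])

  # up pass: cost of the rest of the tree when a node is fixed at each state
  up <- matrix(0, nrow = nt + nn, ncol = k)
  for (p in rev(node_order)) {
    for (ch in children[[as.character(p)]]) {
      if (ch <= nt) next
      others <- 0
      for (sib in setdiff(children[[as.character(p)]], ch)) {
        # per parent-state vector of sibling contributions
        others <- others + vapply(seq_len(k), function(s)
          contrib(sib, s)$cost, numeric(1))
      }
      base <- up[p, ] + others   # cost outside ch, given parent state
      up[ch, ] <- vapply(seq_len(k), function(s) {
        min(base + (seq_len(k) != s))
      }, numeric(1))
    }
  }
  internal <- (nt + 1L):(nt + nn)
  mpr <- lapply(internal, function(v) {
    tot <- down[v, ] + up[v, ]
    which(tot == min_cost)
  })
  names(mpr) <- as.character(internal)
  structure(list(tree = tree, min_cost = as.integer(min_cost),
                 n_reconstructions = n_rec, mpr = mpr,
                 labels = char$labels,
                 down = down, cnt = cnt, allowed = allowed,
                 children = children),
            class = "reconstruction_set")
}

#' @export
print.reconstruction_set <- function(x, ...) {
  amb <- sum(vapply(x$mpr, length, integer(1)) > 1L)
  cat(sprintf(
    "<reconstruction_set> cost %d, %s reconstruction(s), %d/%d node(s) ambiguous\n",
    x$min_cost, format(x$n_reconstructions, big.mark = ","), amb,
    length(x$mpr)))
  invisible(x)
}

#' Enumerate all most-parsimonious reconstructions
#'
#' Explicit list of internal-node state assignments achieving the minimum
#' cost, by backtracking over the optimal DP choices; refuses (naming the
#' count) when there are more than `cap`.
#'
#' @param rs A `reconstruction_set` from [mpr_reconstruct()].
#' @param cap Maximum number of reconstructions to enumerate.
#' @return A list of named integer vectors (internal node -> state), each
#'   verified to cost exactly `rs$min_cost`.
#' @export
enumerate_reconstructions <- function(rs, cap = 1000L) {
  stopifnot(inherits(rs, "reconstruction_set"))
  if (rs$n_reconstructions > cap) {
    stop("refusing to enumerate ", rs$n_reconstructions,
         " reconstructions (cap ", cap, ")", call. = FALSE)
  }
  tree <- rs$tree
  nt <- length(tree$tip.label)
  root <- nt + 1L
  k <- length(rs$labels)
  out <- list()
  assign_node <- function(node, state, acc) {
    acc[[as.character(node)]] <- state
    kids <- rs$children[[as.character(node)]]
    branches <- list(acc)
    for (ch in kids) {
      if (ch <= nt) next
      cand <- rs$down[ch, ] + (seq_len(k) != state)
      opts <- which(cand == min(cand))
      new_branches <- list()
      for (b in branches) {
        for (s in opts) {
          new_branches <- c(new_branches, assign_node(ch, s, b))
        }
      }
      branches <- new_branches
    }
    branches
  }
  for (s in which(rs$down[root, ] == min(rs$down[root, ]))) {
    out <- c(out, assign_node(root, s, list()))
  }
  out <- lapply(out, function(a) {
    v <- unlist(a)
    stats::setNames(as.integer(v), names(a))
  })
  # verify each enumerated assignment
  for (a in out) {
    if (reconstruction_cost(rs, a) != rs$min_cost) {
      stop("internal error: enumerated reconstruction is not optimal")
    }
  }
  out
}

# direct cost of a full internal assignment (leaves take their cheapest state)
reconstruction_cost <- function(rs, assignment) {
  tree <- rs$tree
  nt <- length(tree$tip.label)
  cost <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    sp <- assignment[[as.character(p)]]
    if (ch <= nt) {
      cost <- cost + as.integer(!rs$allowed[ch, sp])
    } else {
      cost <- cost + as.integer(assignment[[as.character(ch)]] != sp)
    }
  }
  cost
}

#' Annotate a tree with its MPR state sets
#'
#' Attaches each internal node's MPR state set as a node label (states
#' joined by `|`, e.g. `"1|2"` for an ambiguous node) and returns both the
#' annotated tree and a tidy per-node table.
#'
#' @param rs A `reconstruction_set` from [mpr_reconstruct()].
#' @return A list with `tree` (node-labelled [ape::phylo], serializable with
#'   [write_newick()]) and `table` (tibble: `node`, `states`, `state_labels`,
#'   `ambiguous`).
#' @export
paint_tree <- function(rs) {
  stopifnot(inherits(rs, "reconstruction_set"))
  tree <- rs$tree
  nt <- length(tree$tip.label)
  states_chr <- vapply(rs$mpr, paste, character(1), collapse = "|")
  tree$node.label <- unname(states_chr[as.character((nt + 1L):(nt + tree$Nnode))])
  tab <- tibble::tibble(
    node = as.integer(names(rs$mpr)),
    states = unname(states_chr),
    state_labels = unname(vapply(rs$mpr, function(s)
      paste(rs$labels[s], collapse = "|"), character(1))),
    ambiguous = unname(vapply(rs$mpr, length, integer(1)) > 1L))
  list(tree = tree, table = tab)
}
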