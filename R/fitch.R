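#' Fitch parsimony length of a binary tree
#'
#' Unordered, unit-cost parsimony score by the set-based Fitch pass:
#' a post-order sweep where a node's state set is the intersection of its
#' children's sets when non-empty (no change) and their union otherwise (one
#' change). Leaf ambiguity (N, ?, IUPAC codes, fifth-state gaps) enters as a
#' genuine state set, which keeps the score exact for polymorphic cells under
#' unit cost. The score is independent of rooting; polytomies are refused
#' (resolve them, or score with the Sankoff generalization used by
#' [mpr_reconstruct()]).
#'
#' @param tree An [ape::phylo], binary (its root may be the basal
#'   trifurcation of an unrooted tree).
#' @param matrix A [char_matrix][encode_matrix] whose taxa match the leaves.
#' @return Non-negative integer: weighted sum over sites of minimum changes.
#' @export
fitch_length <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "char_matrix"))
  if (!setequal(tree$tip.label, rownames(matrix))) {
    stop("tree leaves and matrix taxa differ", call. = FALSE)
  }
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  # binary check: unrooted basal trifurcation allowed (handled by sequential
  # combination, equivalent to rooting on the third child's edge)
  tab <- tabulate(tree$edge[, 1], nbins = nt + nn)
  kids <- tab[(nt + 1):(nt + nn)]
  root <- nt + 1L
  if (any(kids > 3L) || any(kids[-1L] > 2L)) {
    stop("fitch_length requires a binary tree (polytomy found)", call. = FALSE)
  }
  if (kids[1L] > 2L && ape::is.rooted(tree)) {
    stop("fitch_length requires a binary tree (polytomy found)", call. = FALSE)
  }
  w <- attr(matrix, "weights")
  S <- ncol(matrix)
  if (S == 0L) return(0L)
  po <- ape::reorder.phylo(tree, "postorder")
  states <- matrix(0L, nrow = nt + nn, ncol = S)
  states[seq_len(nt), ] <- unclass(matrix)[match(tree$tip.label,
                                                 rownames(matrix)), ,
                                           drop = FALSE]
  seen <- logical(nt + nn)
  seen[seq_len(nt)] <- TRUE
  cost <- 0
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    if (!seen[p]) {
      states[p, ] <- states[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(states[p, ], states[ch, ])
      empty <- inter == 0L
      if (any(empty)) {
        cost <- cost + sum(w[empty])
        inter[empty] <- bitwOr(states[p, empty], states[ch, empty])
      }
      states[p, ] <- inter
    }
  }
  as.integer(cost)
}

#' Sankoff parsimony length (unit costs, polytomies allowed)
#'
#' Dynamic-programming parsimony score with unit substitution cost between
#' distinct states, generalized to multifurcating nodes (each node's cost
#' vector is the sum over children of `min(child_cost_s, min(child_cost) + 1)`).
#' On binary trees this equals [fitch_length()] and serves as its independent
#' cross-check; it is also the scorer used on consensus trees with polytomies.
#'
#' @inheritParams fitch_length
#' @param tree An [ape::phylo], rooted or unrooted, polytomies allowed.
#' @return Non-negative integer parsimony length.
#' @export
sankoff_length <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "char_matrix"))
  if (!setequal(tree$tip.label, rownames(matrix))) {
    stop("tree leaves and matrix taxa differ", call. = FALSE)
  }
  k <- n_states(matrix)
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  S <- ncol(matrix)
  if (S == 0L) return(0L)
  w <- attr(matrix, "weights")
  BIG <- 1e9
  po <- ape::reorder.phylo(tree, "postorder")
  bits <- unclass(matrix)[match(tree$tip.label, rownames(matrix)), ,
                          drop = FALSE]
  # cost[[s]]: (nt+nn) x S matrix of minimal subtree cost given state s
  cost <- lapply(seq_len(k), function(s) {
    m <- matrix(0, nrow = nt + nn, ncol = S)
    allowed <- bitwAnd(bits, bitwShiftL(1L, s - 1L)) != 0L
    m[seq_len(nt), ][!allowed] <- BIG
    m
  })
  seen <- logical(nt + nn)
  seen[seq_len(nt)] <- TRUE
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    chmin <- cost[[1]][ch, ]
    for (s in 2:k) chmin <- pmin(chmin, cost[[s]][ch, ])
    for (s in seq_len(k)) {
      contrib <- pmin(cost[[s]][ch, ], chmin + 1)
      if (!seen[p]) cost[[s]][p, ] <- contrib
      else cost[[s]][p, ] <- cost[[s]][p, ] + contrib
    }
    seen[p] <- TRUE
  }
  root <- nt + 1L
  best <- cost[[1]][root, ]
  for (s in 2:k) best <- pmin(best, cost[[s]][root, ])
  as.integer(sum(w * best))
}
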