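#' Unrooted binary phylogenetic trees
#'
#' An `unrooted_phylo` is a binary unrooted tree: every node has degree 1
#' (leaf) or 3 (internal), with at least 3 uniquely labeled leaves. It is
#' stored as an undirected edge list over integer node ids.
#'
#' @param edge integer matrix E x 2 of undirected edges.
#' @param label character vector over nodes; `NA` for internal nodes.
#' @param validate check invariants.
#' @return An object of class `unrooted_phylo`.
#' @export
unrooted_phylo <- function(edge, label, validate = TRUE) {
  tree <- structure(
    list(edge = matrix(as.integer(edge), ncol = 2L),
         label = as.character(label)),
    class = "unrooted_phylo")
  if (validate) validate_unrooted_phylo(tree)
  tree
}

#' @rdname unrooted_phylo
#' @param tree an `unrooted_phylo`.
#' @export
validate_unrooted_phylo <- function(tree) {
  stopifnot(inherits(tree, "unrooted_phylo"))
  n <- length(tree$label)
  deg <- tabulate(tree$edge, nbins = n)
  if (!all(deg %in% c(1L, 3L)))
    stop("unrooted binary tree must have node degrees 1 or 3")
  leaf <- deg == 1L
  if (sum(leaf) < 3L) stop("unrooted tree must have at least 3 leaves")
  if (any(is.na(tree$label[leaf])) || anyDuplicated(tree$label[leaf]))
    stop("every leaf must carry a unique label")
  if (!all(is.na(tree$label[!leaf])))
    stop("internal nodes must be unlabeled")
  if (nrow(tree$edge) != n - 1L) stop("tree must be acyclic and connected")
  # connectivity via one traversal
  adj <- adjacency_list(tree)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  if (!all(seen)) stop("tree is not connected")
  invisible(tree)
}

adjacency_list <- function(tree) {
  n <- length(tree$label)
  both <- c(tree$edge[, 1L], tree$edge[, 2L])
  other <- c(tree$edge[, 2L], tree$edge[, 1L])
  split(other, factor(both, levels = seq_len(n)))
}

unrooted_degrees <- function(tree)
  tabulate(tree$edge, nbins = length(tree$label))

#' @export
n_leaves.unrooted_phylo <- function(tree) sum(unrooted_degrees(tree) == 1L)

#' @export
leaf_labels.unrooted_phylo <- function(tree)
  sort(tree$label[unrooted_degrees(tree) == 1L])

#' @export
print.unrooted_phylo <- function(x, ...) {
  cat("Unrooted binary tree:", n_leaves(x), "leaves\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

#' Root an unrooted tree on a leaf edge
#'
#' Subdivides the edge incident to leaf `l` with a new root node, whose two
#' children are `l` and the rest of the tree. This is the standard reduction
#' used to transfer unrooted split problems to rooted clade problems: the
#' splits of the unrooted tree correspond to the clades of the rooted one.
#'
#' @param tree an `unrooted_phylo`.
#' @param l a leaf label of `tree`.
#' @return A `rooted_phylo` on the same leaf set.
#' @export
root_at_leaf <- function(tree, l) {
  stopifnot(inherits(tree, "unrooted_phylo"))
  lv <- which(!is.na(tree$label) & tree$label == l)
  if (length(lv) != 1L) stop("'", l, "' is not a leaf of the tree")
  n <- length(tree$label)
  adj <- adjacency_list(tree)
  root <- n + 1L
  parent <- integer(n + 1L)
  children <- matrix(0L, n + 1L, 2L)
  parent[lv] <- root
  start <- adj[[lv]][1L]
  parent[start] <- root
  children[root, ] <- c(lv, start)
  # orient away from the root with an explicit stack; `came` tracks the
  # unrooted-side predecessor (for `start` that is the rooting leaf itself)
  came <- integer(n)
  came[start] <- lv
  stack <- start
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    nb <- adj[[v]]
    kids <- nb[nb != came[v]]
    if (length(kids)) {
      children[v, ] <- kids
      parent[kids] <- v
      came[kids] <- v
      stack <- c(stack, kids)
    }
  }
  rooted_phylo(parent, children, c(tree$label, NA_character_), root,
               validate = FALSE)
}

#' Unroot a rooted tree by suppressing its root
#'
#' The two children of the root are joined by an edge; the result is a
#' binary unrooted tree (all degrees 1 or 3). Requires at least 3 leaves.
#'
#' @param tree a `rooted_phylo` with >= 3 leaves.
#' @return An `unrooted_phylo` on the same leaf set.
#' @export
unroot <- function(tree) {
  stopifnot(inherits(tree, "rooted_phylo"))
  if (n_leaves(tree) < 3L) stop("cannot unroot a tree with fewer than 3 leaves")
  n <- length(tree$parent)
  keep <- seq_len(n)[-tree$root]
  newid <- integer(n)
  newid[keep] <- seq_along(keep)
  nonroot <- keep[tree$parent[keep] != tree$root]
  edge <- cbind(newid[tree$parent[nonroot]], newid[nonroot])
  rc <- tree$children[tree$root, ]
  edge <- rbind(edge, newid[rc])
  unrooted_phylo(edge, tree$label[keep], validate = FALSE)
}

#' Splits (bipartitions) of an unrooted tree
#'
#' One bipartition of the leaf-label set per edge, including the trivial
#' splits. Each split is canonicalized by storing the side that does not
#' contain the lexicographically smallest leaf label. A binary unrooted tree
#' on n leaves has exactly `2n - 3` splits.
#'
#' @param tree an `unrooted_phylo`.
#' @return An object of class `split_set`: a list with `elements` (a list of
#'   canonical sides, sorted label vectors), `keys`, and `all_labels`.
#' @export
split_set <- function(tree) {
  stopifnot(inherits(tree, "unrooted_phylo"))
  labs <- leaf_labels(tree)
  rt <- root_at_leaf(tree, labs[1L])
  cs <- clade_set(rt)
  # splits = clades of all nodes except the root and the rooting leaf;
  # none of those clades contains the smallest label, so they are canonical
  drop <- c(rt$root, which(!is.na(rt$label) & rt$label == labs[1L]))
  keep <- setdiff(seq_along(cs$elements), drop)
  structure(list(elements = cs$elements[keep],
                 keys = cs$keys[keep],
                 all_labels = labs),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat("Split set with", length(x$elements), "splits\n")
  for (e in x$elements[order(x$keys)]) {
    cat(" ", paste(setdiff(x$all_labels, e), collapse = ","), "|",
        paste(e, collapse = ","), "\n")
  }
  invisible(x)
}

#' @export
restrict.unrooted_phylo <- function(tree, L) {
  L <- unique(as.character(L))
  if (length(L) < 3L)
    stop("unrooted restriction needs at least 3 labels")
  if (!all(L %in% leaf_labels(tree)))
    stop("L must be a subset of the tree's leaf labels")
  l <- sort(L)[1L]
  unroot(restrict(root_at_leaf(tree, l), L))
}
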