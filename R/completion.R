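#' Color the nodes of a guide tree by leaf presence
#'
#' In the completion algorithms, the nodes of the guide tree S are colored
#' in one post-order pass against a reference leaf set: a leaf is green if
#' its label belongs to the reference set, red otherwise; an internal node
#' is red if both children are red, green if both are green, and blue
#' (mixed) otherwise. A blue node with exactly one red child is "marked":
#' the subtree under that red child is a maximal red subtree, the unit that
#' gets grafted into the other tree. A blue node can never have two red
#' children (both red children would force the parent red).
#'
#' @param S a `rooted_phylo`, the guide tree.
#' @param t_leaves non-empty character vector of leaf labels, a subset of
#'   `leaf_labels(S)`: the leaves of S that the other tree also has.
#' @return An object of class `node_coloring`: list with `color` (character
#'   vector over nodes of S: "green", "red" or "blue"), `marked` (integer
#'   ids of marked nodes) and `t_leaves`.
#' @export
color_and_mark <- function(S, t_leaves) {
  stopifnot(inherits(S, "rooted_phylo"))
  t_leaves <- unique(as.character(t_leaves))
  if (length(t_leaves) == 0L) stop("t_leaves must be non-empty")
  if (!all(t_leaves %in% S$label[is_leaf(S)]))
    stop("t_leaves must be a subset of the leaf labels of S")
  n <- length(S$parent)
  # 1 = green, 2 = red, 3 = blue
  col <- integer(n)
  ord <- postorder_nodes(S)
  ch <- S$children
  leaf_green <- !is.na(S$label) & S$label %in% t_leaves  # hashed, O(n)
  for (v in ord) {
    if (ch[v, 1L] == 0L) {
      col[v] <- if (leaf_green[v]) 1L else 2L
    } else {
      a <- col[ch[v, 1L]]; b <- col[ch[v, 2L]]
      col[v] <- if (a == 1L && b == 1L) 1L
        else if (a == 2L && b == 2L) 2L
        else 3L
    }
  }
  blue <- which(col == 3L)
  nred <- (col[ch[blue, 1L]] == 2L) + (col[ch[blue, 2L]] == 2L)
  structure(list(color = c("green", "red", "blue")[col],
                 marked = blue[nred == 1L],
                 t_leaves = t_leaves),
            class = "node_coloring")
}

#' LCA mapping of a colored guide tree into a target tree
#'
#' For every green or blue node v of S, `M(v)` is the least common ancestor
#' in T of the T-present (green) leaves below v. It is computed bottom-up:
#' a green leaf maps to the T-leaf with the same label, and an internal node
#' maps to the LCA in T of the mappings of its non-red children, one O(1)
#' LCA query per node.
#'
#' @param S a `rooted_phylo`, the guide tree.
#' @param coloring a [color_and_mark] result induced on S by `leaf_labels(T)`.
#' @param T_tree a `rooted_phylo`, the target tree.
#' @param idx an [lca_build] index on `T_tree`.
#' @return Integer vector over nodes of S with node ids of `T_tree`
#'   (`NA` for red nodes).
#' @export
lca_mapping <- function(S, coloring, T_tree, idx) {
  stopifnot(inherits(S, "rooted_phylo"), inherits(T_tree, "rooted_phylo"),
            inherits(coloring, "node_coloring"), inherits(idx, "lca_index"))
  n <- length(S$parent)
  col <- coloring$color
  M <- rep(NA_integer_, n)
  tleaf <- which(is_leaf(T_tree))
  # vectorized label -> T-node lookup (per-element name lookup is O(n))
  mleaf <- tleaf[match(S$label, T_tree$label[tleaf])]
  ord <- postorder_nodes(S)
  ch <- S$children
  for (v in ord) {
    if (col[v] == "red") next
    if (ch[v, 1L] == 0L) {
      M[v] <- mleaf[v]
    } else {
      a <- ch[v, 1L]; b <- ch[v, 2L]
      ma <- M[a]; mb <- M[b]
      M[v] <- if (is.na(ma)) mb
        else if (is.na(mb)) ma
        else lca_query(idx, ma, mb)
    }
  }
  M
}

#' Graft a subtree onto the parent edge of a node
#'
#' `tree_add(T, v, X)` attaches tree X (leaf-disjoint from T) to T: if v is
#' not the root, the edge (parent(v), v) is subdivided and the root of X
#' becomes v's sibling; if v is the root, a new root is created with
#' children v and the root of X. The result is a binary tree on the union
#' leaf set whose restriction to the leaves of T is T itself.
#'
#' @param T_tree a `rooted_phylo`.
#' @param v a node id of `T_tree` (attachment point).
#' @param X a `rooted_phylo` with `leaf_labels(X)` disjoint from
#'   `leaf_labels(T_tree)`.
#' @return A `rooted_phylo` on the combined leaf set.
#' @export
tree_add <- function(T_tree, v, X) {
  stopifnot(inherits(T_tree, "rooted_phylo"), inherits(X, "rooted_phylo"))
  v <- as.integer(v)
  if (v < 1L || v > length(T_tree$parent)) stop("v is not a node of T")
  if (length(intersect(leaf_labels(T_tree), leaf_labels(X))))
    stop("leaf sets of T and X must be disjoint")
  nT <- length(T_tree$parent)
  nX <- length(X$parent)
  n <- nT + nX + 1L
  parent <- c(T_tree$parent, X$parent + nT, 0L)
  xch <- X$children
  xch[xch != 0L] <- xch[xch != 0L] + nT
  children <- rbind(T_tree$children, xch, c(0L, 0L))
  label <- c(T_tree$label, X$label, NA_character_)
  w <- n
  xr <- X$root + nT
  if (v == T_tree$root) {
    children[w, ] <- c(v, xr)
    parent[v] <- w
    parent[xr] <- w
    root <- w
  } else {
    p <- parent[v]
    children[p, children[p, ] == v] <- w
    parent[w] <- p
    children[w, ] <- c(v, xr)
    parent[v] <- w
    parent[xr] <- w
    root <- T_tree$root
  }
  rooted_phylo(parent, children, label, root, validate = FALSE)
}

# Core grafting engine shared by the one-tree and two-tree solvers.
#
# Colors the guide tree S by the leaves it shares with the target T, maps
# green/blue nodes of S into T by LCAs, then walks S in pre-order and, at
# every marked node v, grafts a copy of the maximal red subtree under v's
# red child onto the current parent edge of M(v) in the evolving tree
# (immediately above M(v); grafts for S-ancestors therefore end up farther
# from M(v) than grafts for S-descendants). Returns the completion of T on
# Le(T) u Le(S) together with provenance.
graft_completion <- function(S, T_tree) {
  common <- intersect(leaf_labels(S), leaf_labels(T_tree))
  if (length(common) == 0L)
    stop("S and T must share at least one leaf")
  coloring <- color_and_mark(S, common)
  marked <- coloring$marked
  nT <- length(T_tree$parent)
  if (length(marked) == 0L) {
    return(list(completed = T_tree,
                provenance = rep("original", nT),
                grafts = list(), n_grafts = 0L))
  }
  idx <- lca_build(T_tree)
  M <- lca_mapping(S, coloring, T_tree, idx)
  col <- coloring$color
  chS <- S$children
  # red child and size of each maximal red subtree
  red_child <- integer(length(marked))
  subtree_nodes <- vector("list", length(marked))
  sz <- subtree_sizes(S)
  total_red <- 0L
  for (i in seq_along(marked)) {
    v <- marked[i]
    r <- if (col[chS[v, 1L]] == "red") chS[v, 1L] else chS[v, 2L]
    red_child[i] <- r
    subtree_nodes[[i]] <- subtree_node_ids(S, r, sz[r])
    total_red <- total_red + sz[r]
  }
  # evolving tree: original T node ids are stable, new nodes appended
  n <- nT + total_red + length(marked)
  parent <- integer(n)
  children <- matrix(0L, n, 2L)
  label <- rep(NA_character_, n)
  parent[seq_len(nT)] <- T_tree$parent
  children[seq_len(nT), ] <- T_tree$children
  label[seq_len(nT)] <- T_tree$label
  root <- T_tree$root
  provenance <- c(rep("original", nT), rep("", n - nT))
  grafts <- vector("list", length(marked))
  k <- nT
  is_marked <- logical(length(S$parent))
  is_marked[marked] <- TRUE
  slot <- integer(length(S$parent))
  slot[marked] <- seq_along(marked)
  pre <- preorder_nodes(S)
  g <- 0L
  # shared old-id -> new-id scratch; maximal red subtrees are disjoint,
  # so entries never need resetting between grafts
  newid <- integer(length(S$parent))
  for (v in pre) {
    if (!is_marked[v]) next
    g <- g + 1L
    i <- slot[v]
    nodes <- subtree_nodes[[i]]
    r <- red_child[i]
    # copy the red subtree S(r) into the arrays
    newid[nodes] <- k + seq_along(nodes)
    for (u in nodes) {
      nu <- newid[u]
      label[nu] <- S$label[u]
      if (chS[u, 1L] != 0L) {
        children[nu, ] <- newid[chS[u, ]]
        parent[newid[chS[u, ]]] <- nu
      }
      provenance[nu] <- "copied-red-subtree"
    }
    xr <- newid[r]
    k <- k + length(nodes)
    # new junction node
    k <- k + 1L
    w <- k
    provenance[w] <- "grafted"
    u <- M[v]
    if (u == root) {
      children[w, ] <- c(u, xr)
      parent[u] <- w
      parent[xr] <- w
      root <- w
    } else {
      p <- parent[u]
      children[p, children[p, ] == u] <- w
      parent[w] <- p
      children[w, ] <- c(u, xr)
      parent[u] <- w
      parent[xr] <- w
    }
    grafts[[g]] <- sort(S$label[nodes[!is.na(S$label[nodes])]])
  }
  completed <- rooted_phylo(parent, children, label, root, validate = FALSE)
  list(completed = completed, provenance = provenance,
       grafts = grafts, n_grafts = length(marked))
}

# number of nodes in the subtree below every node (one postorder pass)
subtree_sizes <- function(tree) {
  n <- length(tree$parent)
  sz <- rep(1L, n)
  ch <- tree$children
  for (v in postorder_nodes(tree)) {
    if (ch[v, 1L] != 0L) sz[v] <- 1L + sz[ch[v, 1L]] + sz[ch[v, 2L]]
  }
  sz
}

# node ids of the subtree rooted at v (preorder); n = known subtree size
subtree_node_ids <- function(tree, v, n = length(tree$parent)) {
  out <- integer(n)
  stack <- integer(n)
  stack[1L] <- v
  top <- 1L
  k <- 0L
  ch <- tree$children
  while (top > 0L) {
    u <- stack[top]
    top <- top - 1L
    k <- k + 1L
    out[k] <- u
    if (ch[u, 1L] != 0L) {
      stack[top + 1L] <- ch[u, 1L]
      stack[top + 2L] <- ch[u, 2L]
      top <- top + 2L
    }
  }
  out[seq_len(k)]
}

#' Optimal one-tree completion of a rooted tree (ROT-RF(+))
#'
#' Given rooted binary trees S and T with `leaf_labels(T)` a subset of
#' `leaf_labels(S)`, computes a completion T' of T on the leaf set of S
#' minimizing the Robinson-Foulds distance RF(S, T') over all completions.
#' The algorithm colors S against the leaf set of T, maps green/blue nodes
#' of S into T by least common ancestors, and grafts a copy of each maximal
#' red subtree of S (missing leaves) onto the appropriate edge of T during
#' a pre-order traversal of S. Runs in near-linear time in the size of S.
#'
#' Optimal completions need not be unique; the deterministically chosen one
#' is returned.
#'
#' @param S a `rooted_phylo` (the reference/supertree).
#' @param T_tree a `rooted_phylo` with leaves nested in those of S.
#' @return An object of class `completion_one`: list with `completed` (the
#'   completion of T on the leaf set of S), `rf` (the achieved, minimal RF
#'   distance to S), `provenance` (character vector over nodes of
#'   `completed`: "original", "grafted" or "copied-red-subtree"), `grafts`
#'   (leaf-label sets of the grafted maximal red subtrees) and `n_grafts`.
#' @export
one_tree_completion <- function(S, T_tree) {
  stopifnot(inherits(S, "rooted_phylo"), inherits(T_tree, "rooted_phylo"))
  if (!all(leaf_labels(T_tree) %in% leaf_labels(S)))
    stop("leaf set of T must be a subset of the leaf set of S")
  res <- graft_completion(S, T_tree)
  res$rf <- rf_distance(S, res$completed)
  class(res) <- "completion_one"
  res
}

#' @export
print.completion_one <- function(x, ...) {
  cat("Optimal one-tree completion: RF =", x$rf,
      "(", x$n_grafts, "grafted subtrees )\n")
  cat(" ", write_newick(x$completed), "\n")
  invisible(x)
}

#' Optimal one-tree completion of an unrooted tree (UOT-RF(+))
#'
#' Unrooted analog of [one_tree_completion]: both trees are rooted on the
#' edge of a common leaf (the lexicographically smallest leaf of T), the
#' rooted solver is run, and the root of the result is suppressed. The
#' achieved RF value is provably independent of the choice of rooting leaf;
#' the returned topology may depend on it.
#'
#' @param S an `unrooted_phylo` (>= 3 leaves).
#' @param T_tree an `unrooted_phylo` (>= 3 leaves) with leaves nested in
#'   those of S.
#' @return A `completion_one` whose `completed` tree is unrooted; the extra
#'   field `rooting_leaf` records the leaf used for the reduction.
#' @export
uot_completion <- function(S, T_tree) {
  stopifnot(inherits(S, "unrooted_phylo"), inherits(T_tree, "unrooted_phylo"))
  if (!all(leaf_labels(T_tree) %in% leaf_labels(S)))
    stop("leaf set of T must be a subset of the leaf set of S")
  l <- leaf_labels(T_tree)[1L]
  Sh <- root_at_leaf(S, l)
  Th <- root_at_leaf(T_tree, l)
  res <- graft_completion(Sh, Th)
  rooted_completed <- res$completed
  completed <- unroot(rooted_completed)
  # node ids shift by the dropped root: keep provenance aligned
  keep <- seq_along(rooted_completed$parent)[-rooted_completed$root]
  structure(list(completed = completed,
                 rf = rf_distance(S, completed),
                 provenance = res$provenance[keep],
                 grafts = res$grafts,
                 n_grafts = res$n_grafts,
                 rooting_leaf = l),
            class = "completion_one")
}

#' Test whether a clade is extraneous
#'
#' A clade is extraneous (with respect to trees S and T with partially
#' overlapping leaf sets) when it contains leaves private to S and leaves
#' private to T but no leaves common to both. Such clades pair up
#' missing-only subtrees from the two trees; they can lower the RF distance
#' between completions but have no support in either input topology.
#'
#' @param clade non-empty character vector of leaf labels.
#' @param s_leaves,t_leaves the leaf-label sets of S and T.
#' @return `TRUE` or `FALSE`.
#' @export
is_extraneous_clade <- function(clade, s_leaves, t_leaves) {
  if (length(clade) == 0L) stop("clade must be non-empty")
  common <- intersect(s_leaves, t_leaves)
  length(intersect(clade, setdiff(s_leaves, t_leaves))) > 0L &&
    length(intersect(clade, setdiff(t_leaves, s_leaves))) > 0L &&
    length(intersect(clade, common)) == 0L
}

#' Find extraneous clades or splits in a completed tree
#'
#' For a rooted tree, returns every clade that is extraneous with respect
#' to the leaf sets of S and T. For an unrooted tree, splits are judged via
#' the clades of the tree rooted at a common leaf; the verdict does not
#' depend on which common leaf is chosen.
#'
#' @param tree a `rooted_phylo` or `unrooted_phylo` on (a subset of) the
#'   union leaf set.
#' @param s_leaves,t_leaves the leaf-label sets of the two input trees.
#' @param rooting_leaf for unrooted input, a leaf in the common leaf set to
#'   root at (default: lexicographically smallest common leaf).
#' @return A list of offending clades (character vectors); empty when the
#'   tree is extraneous-free.
#' @export
find_extraneous <- function(tree, s_leaves, t_leaves, rooting_leaf = NULL) {
  if (inherits(tree, "unrooted_phylo")) {
    common <- sort(intersect(s_leaves, t_leaves))
    common <- intersect(common, leaf_labels(tree))
    if (length(common) == 0L)
      stop("no common leaf available to root the unrooted check")
    if (is.null(rooting_leaf)) rooting_leaf <- common[1L]
    if (!(rooting_leaf %in% common))
      stop("rooting_leaf must be a common leaf present in the tree")
    tree <- root_at_leaf(tree, rooting_leaf)
  }
  cs <- clade_set(tree)
  bad <- vapply(cs$elements, is_extraneous_clade, logical(1L),
                s_leaves = s_leaves, t_leaves = t_leaves)
  cs$elements[bad]
}

#' Extraneous-clade-free two-tree completion (EF-R-RF(+))
#'
#' Given rooted binary trees S and T with partially overlapping leaf sets,
#' computes completions S' of S and T' of T on the union leaf set such that
#' neither tree contains an extraneous clade and RF(S', T') is minimal over
#' all extraneous-clade-free completion pairs. The algorithm first
#' completes T on the union with respect to S (grafting the maximal red
#' subtrees of S into T), then completes S with respect to that completed
#' tree. Requires at least one common leaf; with none, every completion
#' pair contains extraneous clades and the problem has no solution.
#'
#' @param S,T_tree rooted binary trees with a non-empty common leaf set.
#' @return An object of class `completion_two`: list with `completed_S`,
#'   `completed_T` (trees on the union leaf set), `rf` (= RF(S', T'),
#'   minimal), `provenance_S`, `provenance_T`, `grafts_S`, `grafts_T` (the
#'   maximal red subtrees grafted into each tree).
#' @export
two_tree_completion_ef <- function(S, T_tree) {
  stopifnot(inherits(S, "rooted_phylo"), inherits(T_tree, "rooted_phylo"))
  if (length(intersect(leaf_labels(S), leaf_labels(T_tree))) == 0L)
    stop("no extraneous-free completion exists: S and T share no leaves")
  step1 <- graft_completion(S, T_tree)      # T' on the union
  step2 <- graft_completion(step1$completed, S)  # S' on the union
  structure(list(completed_S = step2$completed,
                 completed_T = step1$completed,
                 rf = rf_distance(step2$completed, step1$completed),
                 provenance_S = step2$provenance,
                 provenance_T = step1$provenance,
                 grafts_S = step2$grafts,
                 grafts_T = step1$grafts),
            class = "completion_two")
}

#' @export
print.completion_two <- function(x, ...) {
  cat("Optimal extraneous-free two-tree completion: RF =", x$rf, "\n")
  cat("  S':", write_newick(x$completed_S), "\n")
  cat("  T':", write_newick(x$completed_T), "\n")
  invisible(x)
}

#' Extraneous-split-free two-tree completion (EF-U-RF(+))
#'
#' Unrooted analog of [two_tree_completion_ef]: both trees are rooted on
#' the edge of a common leaf (lexicographically smallest), the rooted
#' two-tree solver is run, and the roots of the results are suppressed.
#' The outputs are extraneous-split-free and the achieved RF value is
#' minimal over all extraneous-split-free completion pairs, independently
#' of the choice of rooting leaf. Requires at least 2 common leaves.
#'
#' @param S,T_tree unrooted binary trees (>= 3 leaves each) sharing at
#'   least 2 leaves.
#' @return A `completion_two` with unrooted completed trees and the extra
#'   field `rooting_leaf`.
#' @export
ef_u_completion <- function(S, T_tree) {
  stopifnot(inherits(S, "unrooted_phylo"), inherits(T_tree, "unrooted_phylo"))
  common <- sort(intersect(leaf_labels(S), leaf_labels(T_tree)))
  if (length(common) < 2L)
    stop("EF-U-RF(+) requires at least 2 common leaves")
  l <- common[1L]
  res <- two_tree_completion_ef(root_at_leaf(S, l), root_at_leaf(T_tree, l))
  cS <- unroot(res$completed_S)
  cT <- unroot(res$completed_T)
  keepS <- seq_along(res$completed_S$parent)[-res$completed_S$root]
  keepT <- seq_along(res$completed_T$parent)[-res$completed_T$root]
  structure(list(completed_S = cS,
                 completed_T = cT,
                 rf = rf_distance(cS, cT),
                 provenance_S = res$provenance_S[keepS],
                 provenance_T = res$provenance_T[keepT],
                 grafts_S = res$grafts_S,
                 grafts_T = res$grafts_T,
                 rooting_leaf = l),
            class = "completion_two")
}
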