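#' Rooted binary phylogenetic trees
#'
#' A `rooted_phylo` is a binary rooted tree with uniquely labeled leaves,
#' stored as flat integer arrays so that all algorithms in this package run
#' in time linear in the number of nodes. Nodes are identified by integers
#' `1..N` where `N = 2 * n_leaves - 1`; node identities are internal and all
#' external exchange is by leaf label.
#'
#' @param parent integer vector of length N; `0L` marks the root.
#' @param children integer matrix N x 2; rows of `0L` mark leaves.
#' @param label character vector of length N; `NA` for internal nodes.
#' @param root integer id of the root node.
#' @param validate check invariants (binary, connected, unique labels).
#'
#' @return An object of class `rooted_phylo`.
#' @export
rooted_phylo <- function(parent, children, label, root, validate = TRUE) {
  tree <- structure(
    list(parent = as.integer(parent),
         children = matrix(as.integer(children), ncol = 2L),
         label = as.character(label),
         root = as.integer(root)),
    class = "rooted_phylo")
  if (validate) validate_rooted_phylo(tree)
  tree
}

#' @rdname rooted_phylo
#' @param tree a `rooted_phylo`.
#' @export
validate_rooted_phylo <- function(tree) {
  stopifnot(inherits(tree, "rooted_phylo"))
  n <- length(tree$parent)
  if (n < 1L) stop("tree must have at least one node")
  if (nrow(tree$children) != n || length(tree$label) != n)
    stop("inconsistent array lengths")
  if (sum(tree$parent == 0L) != 1L || tree$parent[tree$root] != 0L)
    stop("tree must have exactly one root")
  leaf <- tree$children[, 1L] == 0L
  if (any(leaf != (tree$children[, 2L] == 0L)))
    stop("internal nodes must have exactly two children")
  if (any(is.na(tree$label[leaf])) || anyDuplicated(tree$label[leaf]))
    stop("every leaf must carry a unique label")
  if (any(grepl("[(),;:]", tree$label[leaf])))
    stop("leaf labels must not contain Newick reserved characters '(),;:'")
  if (sum(!leaf) != sum(leaf) - 1L)
    stop("binary rooted tree must have n_leaves - 1 internal nodes")
  # parent/children mutual consistency + connectivity
  for (col in 1:2) {
    ch <- tree$children[!leaf, col]
    if (any(tree$parent[ch] != which(!leaf)))
      stop("parent/children maps are inconsistent")
  }
  if (length(preorder_nodes(tree)) != n)
    stop("tree is not connected")
  invisible(tree)
}

is_leaf <- function(tree) tree$children[, 1L] == 0L

#' Number of leaves of a tree
#' @param tree a `rooted_phylo` or `unrooted_phylo`.
#' @export
n_leaves <- function(tree) UseMethod("n_leaves")

#' @export
n_leaves.rooted_phylo <- function(tree) sum(is_leaf(tree))

#' Leaf labels of a tree (sorted)
#' @param tree a `rooted_phylo` or `unrooted_phylo`.
#' @export
leaf_labels <- function(tree) UseMethod("leaf_labels")

#' @export
leaf_labels.rooted_phylo <- function(tree) sort(tree$label[is_leaf(tree)])

# Pre-order node sequence (parents before children), iterative.
preorder_nodes <- function(tree) {
  n <- length(tree$parent)
  out <- integer(n)
  stack <- integer(n)
  stack[1L] <- tree$root
  top <- 1L
  k <- 0L
  ch <- tree$children
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    k <- k + 1L
    out[k] <- v
    c1 <- ch[v, 1L]
    if (c1 != 0L) {
      stack[top + 1L] <- ch[v, 2L]
      stack[top + 2L] <- c1
      top <- top + 2L
    }
  }
  out[seq_len(k)]
}

# Children-first node sequence (every child precedes its parent).
postorder_nodes <- function(tree) rev(preorder_nodes(tree))

# Single-leaf tree.
leaf_tree <- function(label) {
  rooted_phylo(parent = 0L, children = matrix(c(0L, 0L), ncol = 2L),
               label = label, root = 1L, validate = FALSE)
}

# For each node, the lexicographically smallest descendant leaf label.
min_desc_label <- function(tree) {
  n <- length(tree$parent)
  m <- character(n)
  ord <- postorder_nodes(tree)
  ch <- tree$children
  for (v in ord) {
    if (ch[v, 1L] == 0L) m[v] <- tree$label[v]
    else {
      a <- m[ch[v, 1L]]; b <- m[ch[v, 2L]]
      m[v] <- if (a <= b) a else b
    }
  }
  m
}

#' Clades of a rooted tree
#'
#' One clade (set of descendant leaf labels) per node, including all
#' singletons and the full leaf set. For a binary tree on n leaves there are
#' exactly `2n - 1` clades.
#'
#' @param tree a `rooted_phylo`.
#' @return An object of class `clade_set`: a list with `elements` (a list of
#'   sorted label vectors) and `keys` (canonical comma-joined strings).
#' @export
clade_set <- function(tree) {
  stopifnot(inherits(tree, "rooted_phylo"))
  n <- length(tree$parent)
  elems <- vector("list", n)
  ord <- postorder_nodes(tree)
  ch <- tree$children
  for (v in ord) {
    elems[[v]] <- if (ch[v, 1L] == 0L) tree$label[v]
      else sort(c(elems[[ch[v, 1L]]], elems[[ch[v, 2L]]]))
  }
  structure(list(elements = elems,
                 keys = vapply(elems, paste, "", collapse = ",")),
            class = "clade_set")
}

#' @export
print.clade_set <- function(x, ...) {
  cat("Clade set with", length(x$elements), "clades\n")
  for (k in sort(x$keys)) cat(" ", k, "\n")
  invisible(x)
}

#' @export
print.rooted_phylo <- function(x, ...) {
  cat("Rooted binary tree:", n_leaves(x), "leaves\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

#' Restrict a tree to a subset of its leaves
#'
#' Returns the leaf-induced subtree `T[L]`: the minimal subtree spanning the
#' leaves in `L`, with non-root degree-two nodes suppressed. For a rooted
#' tree the result is rooted at the most recent common ancestor of `L`.
#'
#' @param tree a `rooted_phylo` or `unrooted_phylo`.
#' @param L character vector of leaf labels, a subset of the tree's leaves;
#'   at least 1 label (rooted) or 3 (unrooted).
#' @return A tree of the same rootedness with leaf set exactly `L`.
#' @export
restrict <- function(tree, L) UseMethod("restrict")

#' @export
restrict.rooted_phylo <- function(tree, L) {
  L <- unique(as.character(L))
  if (!all(L %in% tree$label[is_leaf(tree)]))
    stop("L must be a subset of the tree's leaf labels")
  if (length(L) < 1L) stop("L must contain at least one label")
  n <- length(tree$parent)
  cnt <- integer(n)
  ord <- postorder_nodes(tree)
  ch <- tree$children
  keepleaf <- !is.na(tree$label) & tree$label %in% L
  # new node ids, assigned children-first
  map <- integer(n)
  np <- integer(2L * length(L) - 1L)
  nc <- matrix(0L, 2L * length(L) - 1L, 2L)
  nl <- rep(NA_character_, 2L * length(L) - 1L)
  k <- 0L
  for (v in ord) {
    if (ch[v, 1L] == 0L) {
      if (keepleaf[v]) {
        cnt[v] <- 1L
        k <- k + 1L
        map[v] <- k
        nl[k] <- tree$label[v]
      }
    } else {
      a <- ch[v, 1L]; b <- ch[v, 2L]
      cnt[v] <- cnt[a] + cnt[b]
      if (cnt[a] > 0L && cnt[b] > 0L) {
        k <- k + 1L
        map[v] <- k
        nc[k, ] <- c(map[a], map[b])
        np[map[a]] <- k
        np[map[b]] <- k
      } else if (cnt[v] > 0L) {
        map[v] <- if (cnt[a] > 0L) map[a] else map[b]
      }
    }
  }
  root <- map[tree$root]
  np[root] <- 0L
  rooted_phylo(np[seq_len(k)], nc[seq_len(k), , drop = FALSE],
               nl[seq_len(k)], root, validate = FALSE)
}
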