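#' Read a tree from a Newick string
#'
#' Parses a single Newick statement (terminated by `;`). Branch lengths and
#' internal node labels are accepted and discarded: all algorithms in this
#' package are purely topological. Rootedness is an explicit choice, never
#' inferred from the shape of the string.
#'
#' @param text a Newick string.
#' @param rooted if `TRUE`, require a strictly bifurcating representation
#'   and return a [rooted_phylo]; if `FALSE`, return an [unrooted_phylo]
#'   (a basal trifurcation is the standard representation; a bifurcating
#'   basal node is accepted and suppressed).
#' @return A `rooted_phylo` or `unrooted_phylo`.
#' @export
parse_newick <- function(text, rooted = TRUE) {
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";"))
    stop("malformed Newick: input must be a single statement ending in ';'")
  if (rooted && !grepl("(", text, fixed = TRUE)) {
    # single-leaf tree, e.g. "a;"
    lab <- sub(";$", "", text)
    lab <- gsub("^'|'$", "", trimws(lab))
    if (!nzchar(lab) || grepl("[(),;:]", lab))
      stop("malformed Newick: invalid leaf label")
    return(leaf_tree(lab))
  }
  ph <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(ph) || !inherits(ph, "phylo"))
    stop("malformed Newick: could not parse input")
  ntip <- length(ph$tip.label)
  if (anyDuplicated(ph$tip.label))
    stop("duplicate leaf label: ",
         ph$tip.label[duplicated(ph$tip.label)][1L])
  if (any(!nzchar(ph$tip.label)))
    stop("malformed Newick: empty leaf label")
  if (rooted) {
    if (ph$Nnode != ntip - 1L)
      stop("rooted input must be strictly bifurcating")
    from_ape_rooted(ph)
  } else {
    if (ntip < 3L)
      stop("unrooted trees must have at least 3 leaves")
    if (ph$Nnode == ntip - 1L) {
      # bifurcating basal node: suppress it
      unroot(from_ape_rooted(ph))
    } else if (ph$Nnode == ntip - 2L) {
      from_ape_unrooted(ph)
    } else {
      stop("unrooted input must be binary (basal trifurcation allowed)")
    }
  }
}

# ape 'phylo' (binary, rooted shape) -> rooted_phylo
from_ape_rooted <- function(ph) {
  ntip <- length(ph$tip.label)
  n <- ntip + ph$Nnode
  parent <- integer(n)
  children <- matrix(0L, n, 2L)
  parent[ph$edge[, 2L]] <- ph$edge[, 1L]
  for (i in seq_len(nrow(ph$edge))) {
    p <- ph$edge[i, 1L]
    slot <- if (children[p, 1L] == 0L) 1L else 2L
    children[p, slot] <- ph$edge[i, 2L]
  }
  if (any(children[(ntip + 1L):n, 2L] == 0L) ||
      any(tabulate(ph$edge[, 1L], nbins = n) > 2L))
    stop("rooted input must be strictly bifurcating")
  label <- c(ph$tip.label, rep(NA_character_, ph$Nnode))
  tree <- rooted_phylo(parent, children, label, root = ntip + 1L,
                       validate = FALSE)
  validate_rooted_phylo(tree)
}

# ape 'phylo' with basal trifurcation -> unrooted_phylo
from_ape_unrooted <- function(ph) {
  ntip <- length(ph$tip.label)
  n <- ntip + ph$Nnode
  label <- c(ph$tip.label, rep(NA_character_, ph$Nnode))
  tree <- unrooted_phylo(ph$edge, label, validate = FALSE)
  validate_unrooted_phylo(tree)
}

#' Write a tree as a canonical Newick string
#'
#' Output is deterministic: at every node, children are serialized in
#' lexicographic order of their smallest descendant leaf label; unrooted
#' trees are written as a basal trifurcation at the internal node adjacent
#' to the overall smallest leaf label. Branch lengths are never emitted.
#' `parse_newick(write_newick(t))` is topologically equal to `t`.
#'
#' @param tree a `rooted_phylo` or `unrooted_phylo`.
#' @return A Newick string ending in `;`.
#' @export
write_newick <- function(tree) UseMethod("write_newick")

#' @export
write_newick.rooted_phylo <- function(tree) {
  paste0(nwk_subtree(tree, tree$root, min_desc_label(tree)), ";")
}

nwk_subtree <- function(tree, v, mins) {
  if (tree$children[v, 1L] == 0L) return(tree$label[v])
  a <- tree$children[v, 1L]
  b <- tree$children[v, 2L]
  if (mins[a] > mins[b]) { tmp <- a; a <- b; b <- tmp }
  paste0("(", nwk_subtree(tree, a, mins), ",",
         nwk_subtree(tree, b, mins), ")")
}

#' @export
write_newick.unrooted_phylo <- function(tree) {
  l <- leaf_labels(tree)[1L]
  rt <- root_at_leaf(tree, l)
  mins <- min_desc_label(rt)
  # the root's children are the leaf l and the internal hub u;
  # serialize as a trifurcation at u with l as one of the three subtrees
  rc <- rt$children[rt$root, ]
  lv <- rc[!is.na(rt$label[rc])]
  u <- rc[rc != lv]
  if (rt$children[u, 1L] == 0L) {
    # 2-leaf case cannot occur (>= 3 leaves enforced)
    stop("invalid unrooted tree")
  }
  parts <- c(rt$label[lv],
             nwk_subtree(rt, rt$children[u, 1L], mins),
             nwk_subtree(rt, rt$children[u, 2L], mins))
  keys <- c(rt$label[lv], mins[rt$children[u, 1L]], mins[rt$children[u, 2L]])
  paste0("(", paste(parts[order(keys)], collapse = ","), ");")
}

#' Topological equality of two trees
#'
#' Two rooted trees are equal when they have identical leaf sets and
#' identical clade sets; two unrooted trees when they have identical leaf
#' sets and identical split sets. Child order is immaterial.
#'
#' @param A,B two trees of the same rootedness.
#' @return `TRUE` or `FALSE`.
#' @export
trees_equal <- function(A, B) {
  if (inherits(A, "rooted_phylo") && inherits(B, "rooted_phylo")) {
    setequal(leaf_labels(A), leaf_labels(B)) &&
      setequal(clade_set(A)$keys, clade_set(B)$keys)
  } else if (inherits(A, "unrooted_phylo") && inherits(B, "unrooted_phylo")) {
    setequal(leaf_labels(A), leaf_labels(B)) &&
      setequal(split_set(A)$keys, split_set(B)$keys)
  } else {
    stop("trees must have the same rootedness")
  }
}
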