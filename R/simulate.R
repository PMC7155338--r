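#' Random binary tree by sequential leaf insertion
#'
#' Grows a tree by inserting the given labels in order, each at a uniformly
#' random insertion position: any edge or the above-root position for a
#' rooted tree (`2m - 1` choices on an m-leaf tree), any edge for an
#' unrooted tree (`2m - 3` choices). Deterministic given the seed.
#'
#' @param labels character vector of distinct leaf labels; at least 1
#'   (rooted) or 3 (unrooted).
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param rooted grow a rooted (`TRUE`) or unrooted (`FALSE`) tree.
#' @return A `rooted_phylo` or `unrooted_phylo`.
#' @export
random_binary_tree <- function(labels, seed = NULL, rooted = TRUE) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("labels must be distinct")
  if (!is.null(seed)) set.seed(seed)
  if (rooted) {
    if (length(labels) < 1L) stop("need at least one label")
    random_rooted_tree(labels)
  } else {
    if (length(labels) < 3L) stop("need at least 3 labels for an unrooted tree")
    random_unrooted_tree(labels)
  }
}

# sequential insertion with preallocated arrays: O(n)
random_rooted_tree <- function(labels) {
  nl <- length(labels)
  n <- 2L * nl - 1L
  parent <- integer(n)
  children <- matrix(0L, n, 2L)
  label <- rep(NA_character_, n)
  label[1L] <- labels[1L]
  root <- 1L
  k <- 1L
  if (nl >= 2L) {
    for (i in 2:nl) {
      v <- sample.int(k, 1L)      # attachment node: edge above v, or new root
      leaf <- k + 1L
      w <- k + 2L
      label[leaf] <- labels[i]
      if (v == root) {
        children[w, ] <- c(v, leaf)
        parent[v] <- w
        parent[leaf] <- w
        root <- w
      } else {
        p <- parent[v]
        children[p, children[p, ] == v] <- w
        parent[w] <- p
        children[w, ] <- c(v, leaf)
        parent[v] <- w
        parent[leaf] <- w
      }
      k <- k + 2L
    }
  }
  rooted_phylo(parent, children, label, root, validate = FALSE)
}

random_unrooted_tree <- function(labels) {
  nl <- length(labels)
  n <- 2L * nl - 2L
  # start from the 3-leaf star; grow by subdividing a random edge
  edge <- matrix(0L, n - 1L, 2L)
  label <- rep(NA_character_, n)
  hub <- 4L
  edge[1:3, ] <- cbind(rep(hub, 3L), 1:3)
  label[1:3] <- labels[1:3]
  ne <- 3L
  nn <- 4L
  if (nl >= 4L) {
    for (i in 4:nl) {
      e <- sample.int(ne, 1L)
      leaf <- nn + 1L
      mid <- nn + 2L
      label[leaf] <- labels[i]
      b <- edge[e, 2L]
      edge[e, 2L] <- mid            # a -- mid
      edge[ne + 1L, ] <- c(mid, b)  # mid -- b
      edge[ne + 2L, ] <- c(mid, leaf)
      ne <- ne + 2L
      nn <- nn + 2L
    }
  }
  unrooted_phylo(edge, label, validate = FALSE)
}

#' Generate a synthetic completion instance
#'
#' Emulates the partially overlapping inputs of the completion problems: a
#' base tree is grown on the union leaf set, S is its restriction to the
#' union minus the T-only leaves, and T is its restriction to the union
#' minus the S-only leaves, optionally perturbed by random leaf
#' prune-regraft moves to inject topological discordance. With
#' `n_spr = 0` the two trees are restrictions of a common tree and are
#' therefore conflict-free.
#'
#' @param n_union total number of leaves in the union.
#' @param n_only_s,n_only_t numbers of leaves private to S and to T
#'   (`n_only_s + n_only_t < n_union`).
#' @param n_spr number of random leaf prune-regraft perturbations applied
#'   to T.
#' @param seed optional integer seed.
#' @param rooted generate rooted (`TRUE`) or unrooted (`FALSE`) trees.
#' @return List with trees `S` and `T` and the label sets `union`,
#'   `only_s`, `only_t`.
#' @export
make_instance <- function(n_union, n_only_s = 0L, n_only_t = 0L, n_spr = 0L,
                          seed = NULL, rooted = TRUE) {
  stopifnot(n_only_s >= 0L, n_only_t >= 0L, n_spr >= 0L)
  if (n_only_s + n_only_t >= n_union)
    stop("n_only_s + n_only_t must be smaller than n_union")
  if (!is.null(seed)) set.seed(seed)
  labels <- sprintf("t%03d", seq_len(n_union))
  min_sz <- if (rooted) 1L else 3L
  if (n_union - n_only_t < min_sz || n_union - n_only_s < min_sz)
    stop("restrictions would fall below the minimum tree size")
  base <- random_binary_tree(labels, rooted = rooted)
  only_t <- if (n_only_t > 0L) sample(labels, n_only_t) else character(0)
  only_s <- if (n_only_s > 0L)
    sample(setdiff(labels, only_t), n_only_s) else character(0)
  S <- restrict(base, setdiff(labels, only_t))
  T_tree <- restrict(base, setdiff(labels, only_s))
  if (n_spr > 0L) for (i in seq_len(n_spr)) T_tree <- leaf_regraft(T_tree)
  list(S = S, T = T_tree, union = labels,
       only_s = sort(only_s), only_t = sort(only_t))
}

# prune a random leaf and re-insert it at a random position
leaf_regraft <- function(tree) {
  labs <- leaf_labels(tree)
  if (inherits(tree, "rooted_phylo")) {
    if (length(labs) < 3L) return(tree)
    l <- sample(labs, 1L)
    pruned <- restrict(tree, setdiff(labs, l))
    v <- sample.int(length(pruned$parent), 1L)
    tree_add(pruned, v, leaf_tree(l))
  } else {
    if (length(labs) < 4L) return(tree)
    l <- sample(labs, 1L)
    pruned <- restrict(tree, setdiff(labs, l))
    e <- sample.int(nrow(pruned$edge), 1L)
    unrooted_insert_leaf(pruned, e, l)
  }
}

unrooted_insert_leaf <- function(tree, e, lab) {
  n <- length(tree$label)
  edge <- tree$edge
  leaf <- n + 1L
  mid <- n + 2L
  b <- edge[e, 2L]
  edge[e, 2L] <- mid
  edge <- rbind(edge, c(mid, b), c(mid, leaf))
  unrooted_phylo(edge, c(tree$label, lab, NA_character_), validate = FALSE)
}

#' Restriction-based RF distance (RF(-))
#'
#' The traditional way to compare trees with non-identical leaf sets:
#' restrict both trees to their common leaf set and take the RF distance of
#' the restrictions.
#'
#' @param A,B two trees of the same rootedness with at least 1 (rooted) or
#'   3 (unrooted) common leaves.
#' @return A non-negative even integer.
#' @export
rf_minus <- function(A, B) {
  common <- intersect(leaf_labels(A), leaf_labels(B))
  min_sz <- if (inherits(A, "rooted_phylo")) 1L else 3L
  if (length(common) < min_sz)
    stop("common leaf set too small for RF(-)")
  rf_distance(restrict(A, common), restrict(B, common))
}

#' Completion-based RF distance (RF(+))
#'
#' RF distance after optimally completing the input tree I onto the leaf
#' set of the supertree S: the achieved minimum of [one_tree_completion]
#' (rooted) or [uot_completion] (unrooted).
#'
#' @param S the supertree; `I` an input tree with leaves nested in S's.
#' @param I the input tree.
#' @return A non-negative even integer.
#' @export
rf_plus <- function(S, I) {
  if (inherits(S, "rooted_phylo")) one_tree_completion(S, I)$rf
  else uot_completion(S, I)$rf
}

#' Classify input-tree pairs by RF(-) / RF(+) ranking discordance
#'
#' For every unordered pair of input trees, compares their orderings by
#' RF(-) and by RF(+) distance to the supertree: a pair is Type-1 when the
#' two strict orderings are opposite, Type-2 when the RF(-) distances tie
#' but the RF(+) distances differ, and Type-3 when the RF(+) distances tie
#' but the RF(-) distances differ. Pairs where both distances tie (or both
#' agree strictly) fall in no type. The reported percentage is
#' `100 * (type1 + type2 + type3) / total_pairs`, rounded half-up to 2
#' decimals.
#'
#' @param supertree a tree whose leaf set contains every input tree's.
#' @param inputs a list of at least 2 trees of the same rootedness.
#' @return An object of class `pair_classification`: list with `n_trees`,
#'   `type1`, `type2`, `type3`, `total_pairs`, `pct`, and the per-tree
#'   distance table `distances` (data.frame: tree, rf_minus, rf_plus).
#' @export
classify_pairs <- function(supertree, inputs) {
  if (length(inputs) < 2L) stop("need at least 2 input trees")
  slabs <- leaf_labels(supertree)
  for (I in inputs) {
    if (!all(leaf_labels(I) %in% slabs))
      stop("every input's leaf set must be contained in the supertree's")
  }
  rfm <- vapply(inputs, function(I) rf_minus(supertree, I), numeric(1L))
  rfp <- vapply(inputs, function(I) rf_plus(supertree, I), numeric(1L))
  n <- length(inputs)
  t1 <- t2 <- t3 <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dm <- sign(rfm[i] - rfm[j])
      dp <- sign(rfp[i] - rfp[j])
      if (dm != 0L && dp != 0L && dm == -dp) t1 <- t1 + 1L
      else if (dm == 0L && dp != 0L) t2 <- t2 + 1L
      else if (dp == 0L && dm != 0L) t3 <- t3 + 1L
    }
  }
  pair_classification(n, t1, t2, t3,
    distances = data.frame(tree = seq_len(n), rf_minus = rfm, rf_plus = rfp))
}

#' @rdname classify_pairs
#' @param n_trees,type1,type2,type3 pair counts (used to assemble a
#'   classification from precomputed counts).
#' @param distances optional per-tree distance table.
#' @export
pair_classification <- function(n_trees, type1, type2, type3,
                                distances = NULL) {
  total <- n_trees * (n_trees - 1L) / 2
  if (type1 + type2 + type3 > total)
    stop("type counts exceed the number of pairs")
  structure(list(n_trees = n_trees, type1 = type1, type2 = type2,
                 type3 = type3, total_pairs = total,
                 pct = round_half_up(100 * (type1 + type2 + type3) / total, 2L),
                 distances = distances),
            class = "pair_classification")
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.pair_classification <- function(x, ...) {
  cat("Pair classification over", x$n_trees, "input trees\n")
  cat("  Type-1 (opposite orderings):", x$type1, "\n")
  cat("  Type-2 (RF(-) tied, RF(+) not):", x$type2, "\n")
  cat("  Type-3 (RF(+) tied, RF(-) not):", x$type3, "\n")
  cat("  Total pairs:", x$total_pairs, "\n")
  cat("  Percentage of Type-1/2/3 pairs:", sprintf("%.2f%%", x$pct), "\n")
  invisible(x)
}
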