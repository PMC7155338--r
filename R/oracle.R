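#' Enumerate all completions of a rooted tree
#'
#' Exhaustive reference generator used to verify optimality on small
#' instances. Missing leaves are inserted sequentially in the given order;
#' each insertion considers every node of the current tree as an attachment
#' point (every edge plus the above-root position: `2m - 1` positions for
#' an m-leaf tree). Every completion topology is emitted at least once;
#' duplicates across insertion-position vectors are possible and tolerated.
#'
#' A hard size guard (total leaves <= 12) prevents accidental exponential
#' runs.
#'
#' @param T_tree a `rooted_phylo`.
#' @param extra character vector of new leaf labels, disjoint from the
#'   leaves of `T_tree`.
#' @return A list of `rooted_phylo` completions.
#' @export
enumerate_completions <- function(T_tree, extra) {
  stopifnot(inherits(T_tree, "rooted_phylo"))
  extra <- as.character(extra)
  if (length(intersect(leaf_labels(T_tree), extra)) || anyDuplicated(extra))
    stop("extra labels must be new and distinct")
  if (n_leaves(T_tree) + length(extra) > 12L)
    stop("size guard exceeded: at most 12 total leaves")
  acc <- list(T_tree)
  for (lab in extra) {
    nxt <- vector("list", 0L)
    for (tr in acc) {
      for (v in seq_along(tr$parent)) {
        nxt[[length(nxt) + 1L]] <- tree_add(tr, v, leaf_tree(lab))
      }
    }
    acc <- nxt
  }
  acc
}

#' Brute-force minimum for rooted one-tree completion
#'
#' Directly minimizes RF(S, T') over every completion T' of T on the leaf
#' set of S, by exhaustive enumeration. Obviously correct; used to verify
#' [one_tree_completion] on small instances (size guard: 12 leaves).
#'
#' @param S,T_tree rooted trees with `leaf_labels(T_tree)` a subset of
#'   `leaf_labels(S)`.
#' @return List with `rf` (the exact minimum) and `tree` (one argmin
#'   completion).
#' @export
brute_one_tree <- function(S, T_tree) {
  stopifnot(inherits(S, "rooted_phylo"), inherits(T_tree, "rooted_phylo"))
  if (!all(leaf_labels(T_tree) %in% leaf_labels(S)))
    stop("leaf set of T must be a subset of the leaf set of S")
  extra <- sort(setdiff(leaf_labels(S), leaf_labels(T_tree)))
  best <- NULL
  best_rf <- Inf
  for (cand in enumerate_completions(T_tree, extra)) {
    d <- rf_distance(S, cand)
    if (d < best_rf) {
      best_rf <- d
      best <- cand
    }
  }
  list(rf = best_rf, tree = best)
}

# deduplicate a list of trees by canonical serialization
dedupe_trees <- function(trees) {
  keys <- vapply(trees, write_newick, "")
  trees[!duplicated(keys)]
}

#' Brute-force minimum for rooted two-tree completion
#'
#' Minimizes RF(S', T') over all pairs of completions of S and T on the
#' union leaf set. With `ef_only = TRUE`, pairs where either tree contains
#' an extraneous clade are skipped, giving the exact optimum of the
#' extraneous-clade-free problem. Guard: at most 10 union leaves (the pair
#' enumeration is a product space).
#'
#' @param S,T_tree rooted trees.
#' @param ef_only restrict to extraneous-clade-free completion pairs.
#' @return List with `rf` (exact minimum) and `pair` (one argmin pair of
#'   trees), or `rf = Inf` if no admissible pair exists.
#' @export
brute_two_tree <- function(S, T_tree, ef_only = FALSE) {
  stopifnot(inherits(S, "rooted_phylo"), inherits(T_tree, "rooted_phylo"))
  s_leaves <- leaf_labels(S)
  t_leaves <- leaf_labels(T_tree)
  union_labs <- union(s_leaves, t_leaves)
  if (length(union_labs) > 10L)
    stop("size guard exceeded: at most 10 union leaves")
  if (ef_only && length(intersect(s_leaves, t_leaves)) == 0L)
    stop("ef_only with disjoint leaf sets: no admissible pair")
  compS <- dedupe_trees(enumerate_completions(S, sort(setdiff(t_leaves, s_leaves))))
  compT <- dedupe_trees(enumerate_completions(T_tree, sort(setdiff(s_leaves, t_leaves))))
  if (ef_only) {
    okS <- vapply(compS, function(x)
      length(find_extraneous(x, s_leaves, t_leaves)) == 0L, logical(1L))
    okT <- vapply(compT, function(x)
      length(find_extraneous(x, s_leaves, t_leaves)) == 0L, logical(1L))
    compS <- compS[okS]
    compT <- compT[okT]
  }
  keysS <- lapply(compS, function(x) clade_set(x)$keys)
  keysT <- lapply(compT, function(x) clade_set(x)$keys)
  best_rf <- Inf
  best <- NULL
  for (i in seq_along(compS)) {
    ki <- keysS[[i]]
    for (j in seq_along(compT)) {
      kj <- keysT[[j]]
      shared <- sum(ki %in% kj)
      d <- (length(ki) - shared) + (length(kj) - shared)
      if (d < best_rf) {
        best_rf <- d
        best <- list(compS[[i]], compT[[j]])
      }
    }
  }
  list(rf = best_rf, pair = best)
}

#' Brute-force minima for unrooted completion problems
#'
#' Exhaustively minimizes the unrooted RF distance (split-set symmetric
#' difference) over unrooted completions. Candidate completions are
#' generated by sequential leaf insertion on a rooted representation and
#' unrooted afterwards (provably exhaustive), but the objective is
#' evaluated directly on split sets, independently of the rooting reduction
#' used by the fast solvers.
#'
#' @param S,T_tree unrooted trees.
#' @param mode `"one-tree"` (leaves of T nested in S: minimize over
#'   completions of T) or `"ef-two-tree"` (partial overlap: minimize over
#'   extraneous-split-free completion pairs on the union).
#' @return List with `rf` (exact minimum); for `"one-tree"` also `tree`,
#'   for `"ef-two-tree"` also `pair`.
#' @export
brute_unrooted <- function(S, T_tree, mode = c("one-tree", "ef-two-tree")) {
  mode <- match.arg(mode)
  stopifnot(inherits(S, "unrooted_phylo"), inherits(T_tree, "unrooted_phylo"))
  s_leaves <- leaf_labels(S)
  t_leaves <- leaf_labels(T_tree)
  if (mode == "one-tree") {
    if (!all(t_leaves %in% s_leaves))
      stop("leaf set of T must be a subset of the leaf set of S")
    cands <- unrooted_completions(T_tree, sort(setdiff(s_leaves, t_leaves)))
    keysS <- split_set(S)$keys
    best_rf <- Inf
    best <- NULL
    for (cand in cands) {
      k <- split_set(cand)$keys
      shared <- sum(k %in% keysS)
      d <- (length(k) - shared) + (length(keysS) - shared)
      if (d < best_rf) { best_rf <- d; best <- cand }
    }
    list(rf = best_rf, tree = best)
  } else {
    common <- intersect(s_leaves, t_leaves)
    if (length(common) < 2L)
      stop("ef-two-tree mode requires at least 2 common leaves")
    if (length(union(s_leaves, t_leaves)) > 10L)
      stop("size guard exceeded: at most 10 union leaves")
    candS <- unrooted_completions(S, sort(setdiff(t_leaves, s_leaves)))
    candT <- unrooted_completions(T_tree, sort(setdiff(s_leaves, t_leaves)))
    okS <- vapply(candS, function(x)
      length(find_extraneous(x, s_leaves, t_leaves)) == 0L, logical(1L))
    okT <- vapply(candT, function(x)
      length(find_extraneous(x, s_leaves, t_leaves)) == 0L, logical(1L))
    candS <- candS[okS]
    candT <- candT[okT]
    keysS <- lapply(candS, function(x) split_set(x)$keys)
    keysT <- lapply(candT, function(x) split_set(x)$keys)
    best_rf <- Inf
    best <- NULL
    for (i in seq_along(candS)) {
      ki <- keysS[[i]]
      for (j in seq_along(candT)) {
        kj <- keysT[[j]]
        shared <- sum(ki %in% kj)
        d <- (length(ki) - shared) + (length(kj) - shared)
        if (d < best_rf) {
          best_rf <- d
          best <- list(candS[[i]], candT[[j]])
        }
      }
    }
    list(rf = best_rf, pair = best)
  }
}

# all distinct unrooted completions of T with the extra labels, via rooted
# sequential insertion at a fixed leaf rooting + unrooting
unrooted_completions <- function(T_tree, extra) {
  if (length(extra) == 0L) return(list(T_tree))
  l <- leaf_labels(T_tree)[1L]
  rooted <- enumerate_completions(root_at_leaf(T_tree, l), extra)
  dedupe_trees(lapply(rooted, unroot))
}
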