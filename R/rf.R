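#' Robinson-Foulds distance between two trees on the same leaf set
#'
#' The RF distance is the cardinality of the symmetric difference of the two
#' trees' clade sets (rooted) or split sets (unrooted). The value is the
#' unhalved symmetric-difference count; trivial clades/splits are included
#' in the sets but cancel for trees on equal leaf sets. For binary trees the
#' distance is always even, and zero exactly when the trees are equal.
#'
#' For rooted trees the computation runs in linear time: the leaves are
#' relabeled by one tree's traversal order, under which every clade of that
#' tree is a contiguous integer interval, and clades of the other tree are
#' matched by interval keys.
#'
#' @param A,B two trees of the same rootedness with identical leaf sets.
#' @return A non-negative even integer.
#' @export
rf_distance <- function(A, B) {
  if (inherits(A, "rooted_phylo") && inherits(B, "rooted_phylo")) {
    rf_rooted(A, B)
  } else if (inherits(A, "unrooted_phylo") && inherits(B, "unrooted_phylo")) {
    if (!setequal(leaf_labels(A), leaf_labels(B)))
      stop("trees must have identical leaf sets")
    ka <- split_set(A)$keys
    kb <- split_set(B)$keys
    length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  } else {
    stop("trees must have the same rootedness")
  }
}

rf_rooted <- function(A, B) {
  labsA <- A$label[is_leaf(A)]
  if (!setequal(labsA, B$label[is_leaf(B)]))
    stop("trees must have identical leaf sets")
  nl <- length(labsA)
  # leaf ids in order of A's preorder: every clade of A is an interval
  ordA <- preorder_nodes(A)
  leavesA <- ordA[is_leaf(A)[ordA]]
  id <- seq_len(nl)
  names(id) <- A$label[leavesA]
  keyA <- interval_keys(A, id, nl)$key
  ivB <- interval_keys(B, id, nl)
  shared <- sum(!is.na(match(ivB$key[ivB$contig], keyA)))
  (length(A$parent) - shared) + (length(B$parent) - shared)
}

# per-node (lo, hi, size) of descendant leaf ids; key = lo*(nl+1)+hi for
# contiguous clades, NA otherwise
interval_keys <- function(tree, id, nl) {
  n <- length(tree$parent)
  lo <- integer(n); hi <- integer(n); sz <- integer(n)
  ord <- postorder_nodes(tree)
  ch <- tree$children
  leaf_id <- unname(id[tree$label])  # vectorized (hashed) name lookup
  for (v in ord) {
    if (ch[v, 1L] == 0L) {
      lo[v] <- hi[v] <- leaf_id[v]
      sz[v] <- 1L
    } else {
      a <- ch[v, 1L]; b <- ch[v, 2L]
      lo[v] <- min(lo[a], lo[b])
      hi[v] <- max(hi[a], hi[b])
      sz[v] <- sz[a] + sz[b]
    }
  }
  contig <- sz == hi - lo + 1L
  key <- as.numeric(lo) * (nl + 1) + hi
  key[!contig] <- NA_real_
  list(key = key, contig = contig)
}

#' Constant-time least-common-ancestor index
#'
#' Builds an Euler-tour + sparse-table range-minimum structure over a rooted
#' tree, supporting O(1) [lca_query] after O(n log n) preprocessing. The
#' index is valid only for the tree it was built on.
#'
#' @param tree a `rooted_phylo`.
#' @return An object of class `lca_index`.
#' @export
lca_build <- function(tree) {
  stopifnot(inherits(tree, "rooted_phylo"))
  n <- length(tree$parent)
  dep <- integer(n)
  ord <- preorder_nodes(tree)
  pa <- tree$parent
  for (v in ord) if (pa[v] != 0L) dep[v] <- dep[pa[v]] + 1L
  m <- 2L * n - 1L
  euler <- integer(m)
  first <- integer(n)
  ch <- tree$children
  stack_node <- integer(n + 1L)
  stack_state <- integer(n + 1L)
  top <- 1L
  stack_node[1L] <- tree$root
  k <- 0L
  while (top > 0L) {
    v <- stack_node[top]
    s <- stack_state[top]
    k <- k + 1L
    euler[k] <- v
    if (s == 0L) first[v] <- k
    if (ch[v, 1L] != 0L && s < 2L) {
      stack_state[top] <- s + 1L
      top <- top + 1L
      stack_node[top] <- ch[v, s + 1L]
      stack_state[top] <- 0L
    } else {
      top <- top - 1L
    }
  }
  depth_e <- dep[euler]
  K <- floor(log2(m))
  tab <- vector("list", K + 1L)
  tab[[1L]] <- seq_len(m)
  if (K >= 1L) {
    for (j in seq_len(K)) {
      len <- 2L^(j - 1L)
      prev <- tab[[j]]
      a <- prev[seq_len(m - 2L * len + 1L)]
      b <- prev[seq.int(1L + len, m - len + 1L)]
      take_a <- depth_e[a] <= depth_e[b]
      r <- b
      r[take_a] <- a[take_a]
      tab[[j + 1L]] <- r
    }
  }
  structure(list(euler = euler, depth_e = depth_e, first = first,
                 tab = tab, pow2 = 2L^(0:K),
                 flog = as.integer(floor(log2(seq_len(m))))),
            class = "lca_index")
}

#' @rdname lca_build
#' @param idx an `lca_index` built by [lca_build].
#' @param u,v node ids of the indexed tree.
#' @return `lca_query` returns the node id of the least common ancestor;
#'   it is symmetric in `u`, `v`, and `lca_query(idx, u, u) == u`.
#' @export
lca_query <- function(idx, u, v) {
  i <- idx$first[u]
  j <- idx$first[v]
  if (i > j) { t <- i; i <- j; j <- t }
  k <- idx$flog[j - i + 1L]
  t1 <- idx$tab[[k + 1L]][i]
  t2 <- idx$tab[[k + 1L]][j - idx$pow2[k + 1L] + 1L]
  idx$euler[if (idx$depth_e[t1] <= idx$depth_e[t2]) t1 else t2]
}
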