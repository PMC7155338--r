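# shorthand constructors
rp <- function(x) parse_newick(x, rooted = TRUE)
up <- function(x) parse_newick(x, rooted = FALSE)

clade_keys <- function(tree) sort(clade_set(tree)$keys)
is_leaf_nodes <- function(tree) tree$children[, 1L] == 0L
split_keys <- function(tree) sort(split_set(tree)$keys)

# naive LCA by ancestor walk, independent of the Euler-tour index
naive_lca <- function(tree, u, v) {
  anc <- function(w) {
    out <- w
    while (tree$parent[w] != 0L) {
      w <- tree$parent[w]
      out <- c(out, w)
    }
    out
  }
  au <- anc(u)
  av <- anc(v)
  au[au %in% av][1L]
}

# random nested one-tree instance (rooted or unrooted)
random_nested_instance <- function(n_union, n_missing, n_spr, rooted = TRUE) {
  make_instance(n_union, n_only_s = n_missing, n_only_t = 0L,
                n_spr = n_spr, rooted = rooted)
}

# frozen instance where the unrestricted two-tree optimum (6) is strictly
# below the extraneous-clade-free optimum (8): two leaves private to each
# tree, four shared
gap_instance <- function() {
  list(S = rp("(((((b,e),h),d),f),g);"),
       T = rp("(((a,c),(e,h)),(b,f));"))
}
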