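test_that("color_and_mark implements the green/red/blue rules", {
  S <- rp("((a,b),(c,d));")
  col <- color_and_mark(S, c("a", "b"))
  labs <- S$label
  leaf_of <- function(x) which(!is.na(labs) & labs == x)
  expect_equal(col$color[leaf_of("a")], "green")
  expect_equal(col$color[leaf_of("b")], "green")
  expect_equal(col$color[leaf_of("c")], "red")
  expect_equal(col$color[leaf_of("d")], "red")
  expect_equal(col$color[S$parent[leaf_of("a")]], "green")
  expect_equal(col$color[S$parent[leaf_of("c")]], "red")
  expect_equal(col$color[S$root], "blue")
  expect_identical(col$marked, S$root)

  # full overlap: everything green, nothing marked
  col2 <- color_and_mark(S, c("a", "b", "c", "d"))
  expect_true(all(col2$color == "green"))
  expect_length(col2$marked, 0L)

  # interleaved: two marked cherries, blue unmarked root
  S3 <- rp("((a,c),(b,d));")
  col3 <- color_and_mark(S3, c("a", "b"))
  expect_equal(sort(col3$color[!is_leaf_nodes(S3)]), c("blue", "blue", "blue"))
  expect_length(col3$marked, 2L)
  expect_false(S3$root %in% col3$marked)

  expect_error(color_and_mark(S, character(0)), "non-empty")
  expect_error(color_and_mark(S, "z"), "subset")
})

test_that("a blue node never has two red children", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    S <- random_binary_tree(sprintf("x%02d", 1:n), rooted = TRUE)
    keep <- sample(leaf_labels(S), sample(1:(n - 1L), 1))
    col <- color_and_mark(S, keep)
    internal <- which(!is_leaf_nodes(S))
    nred <- (col$color[S$children[internal, 1L]] == "red") +
            (col$color[S$children[internal, 2L]] == "red")
    expect_false(any(col$color[internal] == "blue" & nred == 2L))
    # marked nodes are exactly the blue nodes with one red child
    expect_setequal(col$marked, internal[col$color[internal] == "blue" & nred == 1L])
  }
})

test_that("lca_mapping maps green leaves to their twins and internals to LCAs", {
  S <- rp("((a,b),(c,d));")
  T1 <- rp("(a,b);")
  col <- color_and_mark(S, leaf_labels(T1))
  M <- lca_mapping(S, col, T1, lca_build(T1))
  expect_identical(M[S$root], T1$root)
  ab <- S$parent[which(!is.na(S$label) & S$label == "a")]
  expect_identical(M[ab], T1$root)
  # green leaf maps to the same-label leaf of T
  la_S <- which(!is.na(S$label) & S$label == "a")
  la_T <- which(!is.na(T1$label) & T1$label == "a")
  expect_identical(M[la_S], la_T)
  # red nodes have no mapping
  lc <- which(!is.na(S$label) & S$label == "c")
  expect_true(is.na(M[lc]))

  S2 <- rp("((a,c),(b,d));")
  col2 <- color_and_mark(S2, c("a", "b"))
  M2 <- lca_mapping(S2, col2, T1, lca_build(T1))
  ac <- S2$parent[which(!is.na(S2$label) & S2$label == "a")]
  bd <- S2$parent[which(!is.na(S2$label) & S2$label == "b")]
  expect_identical(M2[ac], which(!is.na(T1$label) & T1$label == "a"))
  expect_identical(M2[bd], which(!is.na(T1$label) & T1$label == "b"))
  expect_identical(M2[S2$root], T1$root)
})

test_that("tree_add grafts onto the parent edge or above the root", {
  T1 <- rp("(a,b);")
  la <- which(!is.na(T1$label) & T1$label == "a")
  lb <- which(!is.na(T1$label) & T1$label == "b")
  expect_true(trees_equal(tree_add(T1, la, rp("c;")), rp("((a,c),b);")))
  expect_true(trees_equal(tree_add(T1, T1$root, rp("c;")), rp("((a,b),c);")))
  expect_true(trees_equal(tree_add(T1, lb, rp("(c,d);")),
                          rp("(a,(b,(c,d)));")))
  expect_error(tree_add(T1, la, rp("a;")), "disjoint")
  # restriction to the original leaves recovers the original tree
  out <- tree_add(T1, la, rp("(c,d);"))
  expect_true(trees_equal(restrict(out, c("a", "b")), T1))
})

test_that("one_tree_completion reproduces the worked examples", {
  S <- rp("((a,b),(c,d));")
  r1 <- one_tree_completion(S, rp("(a,b);"))
  expect_equal(r1$rf, 0L)
  expect_true(trees_equal(r1$completed, S))

  r2 <- one_tree_completion(S, rp("((a,c),b);"))
  expect_equal(r2$rf, 2L)
  expect_true(trees_equal(r2$completed, rp("((a,(c,d)),b);")))

  S3 <- rp("((a,c),(b,d));")
  r3 <- one_tree_completion(S3, rp("(a,b);"))
  expect_equal(r3$rf, 0L)
  expect_true(trees_equal(r3$completed, S3))

  # full leaf set: nothing to graft
  T4 <- rp("((a,c),(b,d));")
  r4 <- one_tree_completion(S, T4)
  expect_equal(r4$rf, rf_distance(S, T4))
  expect_true(trees_equal(r4$completed, T4))
  expect_equal(r4$n_grafts, 0L)

  expect_error(one_tree_completion(rp("(a,b);"), rp("(a,c);")), "subset")
})

test_that("completions are valid and provenance records maximal red subtrees", {
  set.seed(32)
  for (i in 1:20) {
    nu <- sample(5:10, 1)
    inst <- random_nested_instance(nu, sample(1:3, 1), sample(0:2, 1))
    r <- one_tree_completion(inst$S, inst$T)
    # definition of a completion: restriction recovers the input
    expect_true(trees_equal(restrict(r$completed, leaf_labels(inst$T)),
                            inst$T))
    expect_identical(r$rf, rf_distance(inst$S, r$completed))
    # each grafted subtree is a maximal red subtree of S
    col <- color_and_mark(inst$S, leaf_labels(inst$T))
    internal <- which(inst$S$children[, 1L] != 0L)
    marked_red_children <- vapply(col$marked, function(v) {
      ch <- inst$S$children[v, ]
      ch[col$color[ch] == "red"][1L]
    }, integer(1L))
    maximal_red <- lapply(marked_red_children, function(r0)
      sort(leaf_labels(inst$S)[leaf_labels(inst$S) %in%
        inst$S$label[rfplus:::subtree_node_ids(inst$S, r0)]]))
    expect_setequal(lapply(r$grafts, paste, collapse = ","),
                    lapply(maximal_red, paste, collapse = ","))
    expect_equal(r$n_grafts, length(col$marked))
    # provenance partitions the nodes of the completed tree
    expect_length(r$provenance, length(r$completed$parent))
    expect_true(all(r$provenance %in%
      c("original", "grafted", "copied-red-subtree")))
    expect_equal(sum(r$provenance == "grafted"), r$n_grafts)
  }
})

test_that("uot_completion solves the unrooted worked examples", {
  Su <- up("((a,b),c,d);")
  r1 <- uot_completion(Su, up("(a,b,c);"))
  expect_equal(r1$rf, 0L)
  expect_true(trees_equal(r1$completed, Su))

  # full overlap
  Tu <- up("((a,c),b,d);")
  r2 <- uot_completion(Su, Tu)
  expect_equal(r2$rf, rf_distance(Su, Tu))
  expect_true(trees_equal(r2$completed, Tu))

  # 5-leaf tree with splits ab|cde and abc|de, completed from the star
  S5 <- up("((a,b),c,(d,e));")
  r3 <- uot_completion(S5, up("(a,b,c);"))
  expect_equal(r3$rf, 0L)
  expect_true(trees_equal(r3$completed, S5))
})

test_that("extraneous clade detection follows the definition", {
  s_only <- c("c", "d"); t_only <- c("i", "j"); common <- c("a", "b")
  s_leaves <- c(common, s_only)
  t_leaves <- c(common, t_only)
  expect_true(is_extraneous_clade(c("c", "i"), s_leaves, t_leaves))
  expect_false(is_extraneous_clade(c("a", "c", "i"), s_leaves, t_leaves))
  expect_false(is_extraneous_clade(c("c", "d"), s_leaves, t_leaves))
  expect_error(is_extraneous_clade(character(0), s_leaves, t_leaves))

  # a hand-built completion pairing two missing-only subtrees as siblings
  bad <- rp("((a,(c,i)),b);")
  found <- find_extraneous(bad, s_leaves = c("a", "b", "c"),
                           t_leaves = c("a", "b", "i"))
  expect_length(found, 1L)
  expect_setequal(found[[1L]], c("c", "i"))

  # all leaves common: never extraneous
  expect_length(find_extraneous(rp("((a,b),c);"),
                                c("a", "b", "c"), c("a", "b", "c")), 0L)
})

test_that("two_tree_completion_ef reproduces the worked examples", {
  r1 <- two_tree_completion_ef(rp("((a,c),b);"), rp("((a,i),b);"))
  expect_equal(r1$rf, 0L)
  expect_true(trees_equal(r1$completed_S, rp("(((a,c),i),b);")))
  expect_true(trees_equal(r1$completed_T, rp("(((a,c),i),b);")))

  r2 <- two_tree_completion_ef(rp("((a,b),(c,x));"), rp("((a,c),(b,y));"))
  expect_equal(r2$rf, 2L)
  expect_true(trees_equal(r2$completed_S, rp("((a,(b,y)),(c,x));")))
  expect_true(trees_equal(r2$completed_T, rp("((a,(c,x)),(b,y));")))

  # identical leaf sets: identity completions
  A <- rp("((a,b),c);"); B <- rp("((a,c),b);")
  r3 <- two_tree_completion_ef(A, B)
  expect_true(trees_equal(r3$completed_S, A))
  expect_true(trees_equal(r3$completed_T, B))
  expect_equal(r3$rf, rf_distance(A, B))

  expect_error(two_tree_completion_ef(rp("(a,b);"), rp("(c,d);")),
               "no extraneous-free completion")
})

test_that("EF solver outputs are valid, extraneous-free completions", {
  set.seed(33)
  for (i in 1:15) {
    inst <- make_instance(sample(6:9, 1), n_only_s = sample(1:2, 1),
                          n_only_t = sample(1:2, 1), n_spr = sample(0:2, 1))
    sl <- leaf_labels(inst$S); tl <- leaf_labels(inst$T)
    r <- two_tree_completion_ef(inst$S, inst$T)
    expect_true(trees_equal(restrict(r$completed_S, sl), inst$S))
    expect_true(trees_equal(restrict(r$completed_T, tl), inst$T))
    expect_length(find_extraneous(r$completed_S, sl, tl), 0L)
    expect_length(find_extraneous(r$completed_T, sl, tl), 0L)
    expect_identical(r$rf, rf_distance(r$completed_S, r$completed_T))
  }
})

test_that("ef_u_completion is valid and extraneous-split-free", {
  set.seed(34)
  done <- 0
  for (i in 1:30) {
    inst <- make_instance(sample(7:9, 1), n_only_s = sample(1:2, 1),
                          n_only_t = sample(1:2, 1), n_spr = sample(0:2, 1),
                          rooted = FALSE)
    sl <- leaf_labels(inst$S); tl <- leaf_labels(inst$T)
    if (length(intersect(sl, tl)) < 2L) next
    r <- ef_u_completion(inst$S, inst$T)
    expect_true(trees_equal(restrict(r$completed_S, sl), inst$S))
    expect_true(trees_equal(restrict(r$completed_T, tl), inst$T))
    expect_length(find_extraneous(r$completed_S, sl, tl), 0L)
    expect_length(find_extraneous(r$completed_T, sl, tl), 0L)
    # the verdict does not depend on the common rooting leaf
    for (l in intersect(sl, tl))
      expect_length(find_extraneous(r$completed_S, sl, tl,
                                    rooting_leaf = l), 0L)
    done <- done + 1
    if (done >= 10) break
  }
  expect_gte(done, 5)
})

test_that("the unrooted solvers' rf is invariant to the rooting leaf", {
  # re-derive the completion under every admissible rooting by hand and
  # compare the achieved RF to the solver's
  set.seed(35)
  for (i in 1:8) {
    inst <- random_nested_instance(sample(6:8, 1), sample(1:2, 1),
                                   sample(0:2, 1), rooted = FALSE)
    r <- uot_completion(inst$S, inst$T)
    for (l in leaf_labels(inst$T)) {
      rooted_res <- one_tree_completion(root_at_leaf(inst$S, l),
                                        root_at_leaf(inst$T, l))
      expect_identical(rf_distance(inst$S, unroot(rooted_res$completed)),
                       r$rf)
    }
  }
})
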