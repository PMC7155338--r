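---
title: "Optimal tree completion under Robinson–Foulds distance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal tree completion under Robinson-Foulds distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfplus)
```

## The problem

Comparing phylogenies is routine in evolutionary biology, but the standard
distance measures assume both trees carry the same leaves. In practice —
supertree construction, database search, clustering of gene trees — the two
trees usually have *non-identical* leaf sets. Two responses exist:

* **RF(−)**: restrict both trees to their common leaf set and take the
  Robinson–Foulds distance of the restrictions. This throws away every
  taxon present in only one tree.
* **RF(+)**: *complete* each tree by adding its missing leaves, choosing
  the completion that minimizes the RF distance between the resulting
  trees, and report that minimum. This uses all topological information in
  both trees, and its range scales with the union rather than the
  intersection of the leaf sets, so large and small input trees are scored
  on a common footing.

Here the RF distance between trees $S$ and $T$ on one leaf set is the
unhalved symmetric-difference count
$|\mathrm{Clade}(S)\,\Delta\,\mathrm{Clade}(T)|$ for rooted trees and
$|\mathrm{Split}(S)\,\Delta\,\mathrm{Split}(T)|$ for unrooted trees; a
*completion* of $T$ on $L' \supseteq \mathrm{Le}(T)$ is a tree $T'$ with
leaf set $L'$ whose leaf-induced subtree $T'[\mathrm{Le}(T)]$ equals $T$.
All trees are binary with uniquely labeled leaves; non-binary input is
rejected rather than resolved, since the solved problems are defined on
binary trees and any polytomy-resolution policy would silently change the
optimum.

`rfplus` implements exact, near-linear-time solvers for four completion
problems:

1. **Rooted one-tree completion** (`one_tree_completion`):
   $\mathrm{Le}(T) \subseteq \mathrm{Le}(S)$, both rooted; complete $T$ to
   minimize $RF(S, T')$.
2. **Unrooted one-tree completion** (`uot_completion`): the same with
   unrooted trees.
3. **Extraneous-clade-free two-tree completion**
   (`two_tree_completion_ef`): both rooted trees have private leaves;
   complete both on the union so that neither contains an *extraneous
   clade* and $RF(S', T')$ is minimal.
4. **Extraneous-split-free unrooted completion** (`ef_u_completion`): the
   unrooted analog.

## The one-tree algorithm

The solver never searches: the optimum has a constructive form.

1. **Coloring.** Each node of $S$ is colored in one post-order pass:
   *green* if every leaf below it is also in $T$, *red* if none is, *blue*
   otherwise. A blue node with exactly one red child is *marked*; the
   subtree under that red child is a *maximal red subtree* — a maximal
   block of taxa absent from $T$ that is monophyletic in $S$. (A blue node
   can never have two red children: two red children would force the
   parent red.)
2. **LCA mapping.** Every green or blue node $v$ of $S$ is mapped to
   $M(v)$, the least common ancestor in $T$ of the $T$-present leaves
   below $v$. Bottom-up, $M(v)$ is the LCA of the mappings of $v$'s
   non-red children, one O(1) query per node against a precomputed index.
3. **Grafting.** $S$ is traversed in pre-order; at each marked node $v$ a
   copy of its maximal red subtree is grafted onto the *current* parent
   edge of $M(v)$ in the evolving tree (`tree_add`), i.e. immediately
   above $M(v)$. Because ancestors of $v$ in $S$ are processed first,
   their grafts end up farther from $M(v)$ than grafts for descendants —
   the stacking order the optimality argument requires. When
   $M(v)$ is the current root, a new root is created instead.

Each maximal red subtree appears as-is in the completion, every clade of
$S$ that *can* be matched by some completion is matched, and the result
maximizes the number of matched clades — hence minimizes RF. The returned
tree carries per-node provenance (`original`, `grafted`,
`copied-red-subtree`), which the tests use to assert that grafted subtrees
are exactly the maximal red subtrees.

Optimal completions are generally not unique. The package returns the
deterministically constructed one and compares completions by RF value,
validity and extraneous-freeness, never by serialization.

### Unrooted reduction

Rooting two same-leaf-set unrooted trees on the edge of the same leaf
$\ell$ puts their splits and clades in bijection, preserving RF. The
unrooted solvers therefore root both inputs at a common leaf — the
lexicographically smallest, for reproducibility — run the rooted solver,
and suppress the root. The achieved RF value is provably independent of
the choice of $\ell$ (the returned topology may depend on it, which is
documented in the function help); the test suite asserts this invariance
over every admissible rooting leaf.

### Two trees with partial overlap

When both trees have private leaves, unconstrained minimization can pair a
missing-only subtree of $S$ with a missing-only subtree of $T$ into shared
clades that contain no leaf common to $S$ and $T$. Such *extraneous*
clades lower the distance while being supported by neither input topology
(the package's oracle exhibits a concrete instance where the unrestricted
optimum is strictly below the extraneous-free one; see
`scripts/acceptance.R`'s `extraneous_gap`). The extraneous-free variant
forbids them, and is solved by two applications of the one-tree engine:
first complete $T$ on the union with respect to $S$ (coloring $S$ by the
leaves it shares with $T$), then complete $S$ with respect to that
completed tree. Both outputs are extraneous-free by construction, and the
pair attains the minimum over all extraneous-free pairs. At least one
common leaf is required — with none, every completion pair contains
extraneous clades and the problem has no solution (the solvers raise an
error saying so). The unrooted variant additionally needs two common
leaves and judges splits through a common-leaf rooting; the verdict is
independent of which common leaf is used.

## Numerical and engineering choices

* **RF distance.** The value is the unhalved symmetric-difference
  cardinality, with trivial clades/splits included (they cancel for equal
  leaf sets). For rooted trees the implementation relabels leaves
  1..n in one tree's traversal order, under which every clade of that tree
  is a contiguous interval; clades of the other tree are matched by
  $(\mathrm{lo}, \mathrm{hi}, \mathrm{size})$ interval keys, giving O(n)
  behavior. The tests cross-check this against the direct clade-set
  symmetric difference, and the unrooted distance against an independent
  implementation (`phangorn::RF.dist`).
* **LCA index.** Euler tour + sparse-table range-minimum: O(n log n)
  build, O(1) query. A true O(n) preprocessing scheme exists, but the
  contract tested is correctness and near-linear scaling, and the sparse
  table is simpler to verify (the suite compares it against a naive
  ancestor walk on trees of up to 64 nodes).
* **Canonical serialization.** `write_newick` orders children by their
  lexicographically smallest descendant leaf label and writes unrooted
  trees as a basal trifurcation at the internal node adjacent to the
  overall smallest leaf, so identical topologies serialize to identical
  bytes across runs. Branch lengths are parsed and discarded throughout:
  the algorithms are purely topological.
* **Degenerate sizes.** Rooted trees may consist of a single leaf (a
  completion target can be one taxon); unrooted trees require at least 3
  leaves, below which the degree-1/3 invariant is undefined, and such
  inputs are rejected.
* **Scale.** Trees are flat integer arrays (parent, child pair, label);
  traversals are iterative. The acceptance suite completes a
  100,000-leaf/50,000-leaf instance in a few seconds on one core.

## The brute-force oracle

Optimality claims are verified, not assumed. `enumerate_completions`
inserts missing leaves sequentially, trying all `2m - 1` attachment
positions per step, which provably emits every completion topology
(duplicates allowed; deduplicated by canonical serialization where it
matters). `brute_one_tree`, `brute_two_tree` and `brute_unrooted`
minimize RF over that space directly — for unrooted problems the
objective is evaluated on split sets, independent of the rooting
reduction the fast solvers use, so the two routes stay independent. Hard
size guards (12 leaves; 10 for pair spaces) keep the oracles exhaustive
but bounded. The test and acceptance suites compare solver and oracle on
hundreds of random instances per problem (300 rooted one-tree, 200
unrooted one-tree, 150 per two-tree variant, instance sizes 4–8 union
leaves); any disagreement is a hard failure.

## What the generator emulates

`make_instance` grows a base tree on the union leaf set by uniform
sequential leaf insertion, takes $S$ and $T$ as leaf-set restrictions of
it, and perturbs $T$ with `n_spr` random leaf prune–regraft moves. This
emulates the situation the completion problems address — partially
overlapping taxon sets with controllable topological discordance — and
with `n_spr = 0` produces conflict-free instances on which completions
provably achieve RF 0 (asserted in tests). Leaf prune–regraft is used
rather than general SPR because it preserves binarity trivially and no
particular discordance model is prescribed by the problem; uniform
insertion makes the 3-leaf marginal exactly uniform, which the tests
check. What it does *not* emulate: real data features such as unequal
taxon-sampling biases, correlated gene-tree discordance, or realistic
tree-shape (e.g. birth–death) distributions — passing tests show
algorithmic correctness on the modeled instance class, not robustness of
biological conclusions.

## Ranking experiments

`classify_pairs` reproduces the ranking-discordance methodology: given a
supertree and input trees, each input gets an RF(−) and an RF(+) distance
to the supertree, and every unordered pair of inputs is classified —
Type-1 when the two strict orderings are opposite, Type-2 when RF(−) ties
but RF(+) does not, Type-3 when RF(+) ties but RF(−) does not. Pairs tied
under both measures fall in no class, per the literal definitions. The
reported percentage is $100\,(T_1+T_2+T_3)/\binom{n}{2}$, rounded half-up
to two decimals. The published experiments ran against supertrees built
from three real datasets; those datasets and the supertree method are out
of scope here, so the package's experiment uses a synthetic true tree as
the supertree stand-in (the classification logic is independent of how
the supertree was obtained), while `pair_classification` recomputes the
published tables' totals and percentages from their per-dataset counts.

## Limitations

* The *unrestricted* two-tree problems (extraneous clades allowed) have no
  known efficient algorithm; the package provides only the exhaustive
  small-instance oracle for them.
* Non-binary trees are rejected, not resolved.
* Weighted (branch-length) RF variants and completion enumeration are out
  of scope.
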