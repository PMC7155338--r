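# rfplus

Optimal phylogenetic tree completion under the Robinson–Foulds (RF)
distance, for comparing trees with **non-identical leaf sets**.

When two phylogenies share only part of their taxa, the traditional
approach — restrict both to the common leaf set and compare (the
**RF(−)** distance) — discards every taxon found in only one tree. The
alternative implemented here is the completion-based **RF(+)** distance:
add the missing leaves to each tree so as to *minimize* the RF distance
between the completed trees, and report that minimum. RF(+) uses all
topological information in both trees and ranges over the union rather
than the intersection of the leaf sets, which matters wherever trees of
different sizes are ranked against a reference — supertree construction,
phylogenetic database search, clustering of gene trees.

For binary trees $S$, $T$ (rooted or unrooted, uniquely leaf-labeled),
with $RF(\cdot,\cdot)$ the unhalved clade-set (rooted) or split-set
(unrooted) symmetric-difference count, the package solves exactly, in
near-linear time:

* **One-tree completion** ($\mathrm{Le}(T) \subseteq \mathrm{Le}(S)$):
  find a completion $T'$ of $T$ on $\mathrm{Le}(S)$ minimizing
  $RF(S, T')$ — `one_tree_completion()` (rooted), `uot_completion()`
  (unrooted).
* **Extraneous-free two-tree completion** (partially overlapping leaf
  sets): find completions $S'$, $T'$ on
  $\mathrm{Le}(S)\cup\mathrm{Le}(T)$ minimizing $RF(S',T')$ such that no
  clade/split pairs private-to-$S$ taxa with private-to-$T$ taxa without
  any shared taxon — `two_tree_completion_ef()` (rooted),
  `ef_u_completion()` (unrooted).

The optimum is constructed, not searched: the reference tree is colored
green/red/blue by leaf presence, maximal "red" subtrees (monophyletic
blocks of missing taxa) are located, each is mapped into the other tree by
a constant-time least-common-ancestor index, and copies are grafted in a
single pre-order pass. Exhaustive brute-force reference solvers
(`brute_one_tree()`, `brute_two_tree()`, `brute_unrooted()`) verify
optimality on small instances, a generator (`make_instance()`) produces
partially overlapping instances with controlled discordance, and
`classify_pairs()` implements RF(−)/RF(+) ranking-discordance analysis of
input trees against a supertree.

## Worked example

```r
library(rfplus)
S  <- parse_newick("((a,b),(c,d));")   # reference, 4 leaves
T1 <- parse_newick("((a,c),b);")       # input, missing leaf d
one_tree_completion(S, T1)
#> Optimal one-tree completion: RF = 2 ( 1 grafted subtrees )
#>   ((a,(c,d)),b);
```

The solver grafts `d` as the sibling of `c` (the missing leaf's optimal
position given where `c` sits in `T1`), and no completion does better:
the completed tree disagrees with `S` in exactly one clade on each side
(`{a,b}` vs `{a,c,d}`), so the minimal RF(+) distance is 2. Compare
`rf_minus(S, T1)`, which restricts both trees to `{a,b,c}` and also
returns 2 — but from less information. On larger instances the two
measures genuinely diverge; `classify_pairs()` quantifies how often their
rankings disagree.

With leaves private to *both* trees:

```r
two_tree_completion_ef(parse_newick("((a,b),(c,x));"),
                       parse_newick("((a,c),(b,y));"))
#> Optimal extraneous-free two-tree completion: RF = 2
#>   S': ((a,(b,y)),(c,x));
#>   T': ((a,(c,x)),(b,y));
```

A command-line front-end is installed as `exec/rfplus`:

```sh
rfplus complete1 --rooted -s S.nwk -t T.nwk -o out.nwk --report r.json --oracle
rfplus simulate --n-union 40 --only-s 10 --spr 4 --seed 42 -o sim/
rfplus rank --supertree S.nwk --inputs trees/ -o report.json
```

Commands exit 0 on success, 1 on data errors (malformed Newick, violated
preconditions), 2 on usage errors; `--oracle` cross-checks a solver run
against the brute-force reference on small inputs.

See `vignettes/rf-plus-completion.Rmd` for the model, the algorithms and
the design decisions.

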