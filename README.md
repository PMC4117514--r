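# multriplet

Building and comparing multi-labeled phylogenetic trees (MUL trees) from
rooted triplets.

A MUL tree is a rooted binary phylogenetic tree in which several leaves may
carry the same taxon label — the natural shape of a gene tree whose leaves
have been relabeled by species, as in studies of polyploids, biogeography
and host–parasite cospeciation.  The basic inference problem the package
addresses is the *smallest MUL tree from rooted triplets* (SMRT) problem:

> Given a set *t* of rooted triplets *xy|z* over a label set *L*, find a
> MUL tree *T* with label set exactly *L* that is consistent with every
> triplet in *t* and minimizes the number of leaf duplications
> dup(*T*) = *n*(*T*) − |*M*(*T*)|.

SMRT is NP-hard, and — more importantly for practitioners — even its exact
solution need not satisfy the consistency principle: the triplets extracted
from a MUL tree frequently admit a *smaller* consistent MUL tree, so triplet
information alone cannot identify the source tree.  The package provides
everything needed to study this phenomenon quantitatively:

* **`mtrt()`** — a heuristic for SMRT: an Aho-style top-down recursion in
  which the components of the triplet *auxiliary graph* (edge {x, y} for
  every triplet *xy|z*) are split when the graph is disconnected, and a
  minimum-size minimal vertex separator (found by a greedy variant of the
  classical enumerate-and-expand algorithm, scored by
  *w(S) = α·|t(S)|/|t| + ||L₁|−|L₂||/|L′|*) is duplicated onto both sides
  when it is connected.
* **`smallest_multree()`** — an exhaustive exact SMRT solver (compiled
  enumeration with triplet-based pruning) for small label sets, usable as an
  optimality oracle.
* **Rooted triplet distances** — `triplet_distance(a, b)` is half the size
  of the symmetric difference of the triplet encodings *t*(T₁), *t*(T₂);
  with `multiset = TRUE` it uses the encoding *multisets* *mt*(T), which
  count how many times each triplet embeds and therefore separate MUL trees
  that the set-based distance cannot.
* **`simulate_mul_tree()`** — a multispecies-coalescent simulator (Yule
  species tree, random gene-to-species assignment, coalescent gene tree,
  leaves relabeled by species) producing the synthetic MUL trees used in
  the experiments.
* **`run_experiment()`** — the experiment harness: simulate, extract all
  triplets, reconstruct, and compare (duplication classes, both distances,
  isomorphism), with broom-style `tidy()`/`glance()` summaries and an
  `autoplot()` method.

## A worked example

```r
library(multriplet)

t_in <- simulate_mul_tree(sim_config(n_genes = 10, n_species = 4, seed = 7))
t_in
#> MUL tree: 10 leaves, 4 distinct labels, dup = 6
#>   ((s01,((((s02,s03),s02),s03),s03)),((s02,(s04,s04)),s04));

trips <- triplet_set(t_in)   # all 7 distinct triplets embedded in t_in
t_out <- mtrt(trips, leaf_labels(t_in))
t_out
#> MUL tree: 5 leaves, 4 distinct labels, dup = 1
#>   ((s01,(s02,s03)),(s02,s04));

compare_trees(t_in, t_out)
#>   dup_in dup_out dup_class dR  dpR isomorphic
#> 1      6       1      less  0 23.5      FALSE

attr(smallest_multree(trips, leaf_labels(t_in)), "dup")
#> [1] 1
```

The reconstruction is consistent with every input triplet and needs only
one duplication instead of six — here the heuristic's output is provably
optimal (`smallest_multree()` agrees) — yet it is *not* the source tree:
`dR = 0` says the two trees embed exactly the same triplets, while
`dpR = 23.5` (the multiset distance) reveals that they embed them with very
different multiplicities.  That gap between "consistent with the data" and
"equal to the truth" is precisely the consistency-principle failure the
package is designed to expose.

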