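---
title: "Reconstructing multi-labeled trees from rooted triplets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing multi-labeled trees from rooted triplets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multriplet)
```

## The objects

A **MUL tree** is a rooted binary phylogenetic tree whose leaves carry
taxon labels that may repeat.  Writing $n(T)$ for the number of leaves and
$M(T)$ for the set of distinct labels, the number of **leaf duplications**
is $\mathrm{dup}(T) = n(T) - |M(T)|$, i.e. the total over labels of
(occurrences − 1).  MUL trees arise whenever a gene tree's leaves are
relabeled by the species carrying the gene copies: polyploid complexes,
multi-copy gene families, area cladograms, host–parasite systems.

A **rooted triplet** $xy|z$ on three distinct labels asserts that $x$ and
$y$ are closer to each other than either is to $z$.  A triplet is
**consistent** with a MUL tree when some choice of one leaf occurrence per
label realizes it as an embedded subtree: the lca of the chosen $x$ and $y$
leaves is a proper descendant of the lca of all three.  The set of all
consistent triplets is the **triplet encoding** $t(T)$; because a triplet
can embed through several occurrence triples, the **encoding multiset**
$mt(T)$ additionally records each triplet's number of embeddings.
`multriplet` stores triplet sets as tibbles (`x`, `y`, `z`, optionally the
multiplicity `n`), with the cherry pair canonicalized to `x < y`.

In a rooted *binary* tree, any three leaves with pairwise distinct labels
resolve exactly one triplet (the pair with the deepest lca is the cherry),
so `triplet_multiset()` simply scans all $\binom{n}{3}$ leaf triples; the
test suite pins this against a direct occurrence-triple count implemented
over `ape`'s independent lca machinery.

## The smallest-MUL-tree problem and the MTRT-style heuristic

Given triplets $t$ over labels $L$, the smallest-MUL-tree problem asks for
a MUL tree on exactly $L$, consistent with every triplet, minimizing
duplications.  The problem is NP-hard; `mtrt()` implements a heuristic that
generalizes Aho's BUILD recursion.  The **auxiliary graph** $G(t)$ on the
current labels has an edge $\{x, y\}$ for every triplet $xy|z$.  The
recursion on $(L', t')$:

1. $|L'| = 1$: a leaf; $|L'| = 2$: a cherry (a triplet needs three labels,
   so $t'$ is necessarily empty here — asserted).
2. $t' = \emptyset$, $|L'| \ge 3$: any topology is consistent; a
   caterpillar over the lexicographically sorted labels is returned so runs
   are reproducible.
3. $G(t')$ disconnected: its components are grouped into two sides and the
   recursion descends with the induced triplet sets.  No duplication is
   introduced, and on the dense encoding of an ordinary (singly-labeled)
   tree this branch alone fires at every level, so the heuristic reduces
   exactly to BUILD and returns the source tree with dup 0 (a property the
   suite asserts for random trees with 4–12 leaves).
4. $G(t')$ connected: a vertex **separator** must be duplicated.  Minimal
   separators of minimum size are enumerated greedily (below), each is
   scored, and the winner $S$ yields the split $L_1 = X_1 \cup S$,
   $L_2 = X_2 \cup S$, where $X_1, X_2$ group the components of
   $G - S$.
5. $G(t')$ complete: no separator exists.  One label is duplicated and hung
   directly off the root (below).

### Which triplets descend into the children

For the split $L_1, L_2$ with $S = L_1 \cap L_2$, child $i$ receives the
triplets whose three labels lie in $L_i$, **except** every triplet whose
outgroup lies in $S$.  The exception is what makes the recursion sound
*and* economical: once $S$ is repeated on both sides of the root, a triplet
$xy|z$ with $z \in S$ is automatically consistent — its cherry $\{x,y\}$ is
an edge of $G$, and edges never join the two exclusive sides, so the cherry
embeds inside one child while the other side's copy of $z$ supplies the
outgroup above it.  (Triplets entirely inside $S$ are the special case.)
This was a genuinely open design point: the narrower rule that only drops
the wholly-inside-$S$ triplets is also sound, but it forces children to
realize outgroups the root split has already discharged, and in our
measurements it inflated duplication counts by factors of 2–10 on dense
encodings.  The broader rule is provably safe by the embedding argument
above and is what the package ships.

Triplets whose cherry lies in one side but whose outgroup lies only in the
*other* side are consistent by the same cross-side argument and are
likewise never passed down.

### Greedy minimal-separator enumeration

Enumerating all minimal separators can take exponential time, so
`min_separators()` runs the classical two-phase enumeration greedily.
Phase one seeds the family: for every vertex $v$ and every component $C$ of
$G - N[v]$, the neighborhood $N(C)$ is a minimal separator.  Let $k$ be the
smallest size seen.  Phase two expands: for a separator $S$ and $x \in S$,
the neighborhoods of the components of $G - (S \cup N(x))$ are again
minimal separators; a generated separator is kept only if its size is at
most $k$, and $k$ is lowered whenever a smaller one appears.  When the
queue empties, the separators of size exactly $k$ are returned (empty for a
complete graph).  The greedy restriction can in principle miss a
minimum-size separator reachable only through larger intermediates; the
test suite cross-checks the family against `igraph`'s exact minimum-size
enumeration on random graphs and asserts every returned set is a genuine
minimal separator.

### Scoring competing separators

Several minimum-size separators usually exist.  Each is scored by

$$ w(S) \;=\; \alpha \,\frac{|t(S)|}{\max(1, |t'|)} \;+\;
   \frac{\bigl||L_1| - |L_2|\bigr|}{|L'|}, $$

where $t(S)$ is the set of triplets wholly inside $S$.  The first term
penalizes triplet-rich separators (their triplets are dropped from the
recursion, and a separator that swallows much of the signal tends to force
duplications later); the second prefers balanced splits.  Reducing
duplications matters more than balance, so the first term carries the
larger weight, $\alpha = 2$ by default (`alpha` argument).  Ties are broken
by the lexicographically smallest sorted separator, keeping runs
deterministic.  Two details of $w$ were undecidable from first principles
(count triplets *inside* versus *touching* $S$; balance on $L_i$ versus
$X_i$); the package uses inside-$S$ and $L_i$, and the suite
regression-locks the resulting values on fixed instances.

### Grouping components into two sides

A binary root has exactly two children, however many components the graph
breaks into.  Components are sorted by decreasing size (ties by smallest
member) and assigned greedily to the currently smaller side.  Any grouping
preserves consistency — triplets never span two components — so this is
purely a balance heuristic, and it is deterministic.

### Complete auxiliary graphs

A complete graph admits no separator, yet a consistent MUL tree always
exists once labels may repeat.  The fallback duplicates the single label
$b$ that occurs most often as an outgroup and attaches the extra copy
directly to the root: every triplet $xy|b$ becomes automatically consistent
(cherry below one side, the spare $b$ outside it), those triplets are
dropped, and the recursion re-runs on the same label set.  Each step costs
exactly one duplication and strictly shrinks the triplet set, so
termination is immediate.  Two rejected alternatives are worth recording:
duplicating a *single* label as a separator cannot split a complete graph
at all (no progress), and duplicating a whole triplet's three labels costs
three duplications per step and measured catastrophically on dense
instances.

The output is consistent with every input triplet by construction; the
test suite nevertheless asserts it on more than ten thousand randomized
instances, since this is the one property the method must never lose.

## The exact solver

`smallest_multree()` makes the optimality claims testable.  For
$d = 0, 1, \dots$ it enumerates every leaf multiset over $L$ with $d$ extra
copies, and every rooted binary tree on each multiset, returning the first
consistent tree; the result provably attains the minimum duplication count
within budget, with ties broken by canonical form.  The enumeration
(compiled, in `src/`) inserts leaves sequentially — the $j$-th leaf on any
of the $2j-3$ attachment positions — and prunes with the key invariant
that later insertions never change the relative ancestor order of existing
lcas: once all occurrences of a triplet's three labels are placed, its
satisfiability is decided for good, so each input triplet is checked
exactly once along any search path and failures cut whole subtrees.  A
pure-R enumerator over multiset bipartitions (`enumerate_multrees`), with
canonical-form deduplication, provides the independent cross-check: both
routes agree on duplication counts and canonical winners over random
instances.

`search_budget()` caps the search: `max_labels` (7), `max_dup` (3), and
`max_nodes` (2·10⁷ visited enumeration states — a cap on actual work, since
pruning makes the closed-form $(2m-3)!!$ count uninformative).  Exceeding
any cap raises an explicit error; the solver never returns an unproven
answer, and the experiment harness records budget failures per dataset and
excludes them from agreement denominators.

## Triplet distances

For trees on the same taxa set,
$d_R(T_1, T_2) = |t(T_1) \,\Delta\, t(T_2)|/2$ and
$d'_R(T_1, T_2) = |mt(T_1) \,\Delta\, mt(T_2)|/2$, where the multiset
symmetric difference takes the absolute difference of multiplicities
element-wise and its size is the sum.  Both accept triplet tibbles in place
of trees, so tree-vs-set and set-vs-set distances come from the same
function.  $d'_R$ dominates $d_R$, is a pseudometric, and is *not* a
metric: exhaustive search over 5-leaf MUL trees (run in the test suite)
finds non-isomorphic pairs with identical encoding multisets, e.g.
`((((a,a),b),b),c)` versus `((((a,b),a),b),c)`.  The halving convention
makes a one-sided difference of $2k$ triplets read as distance $k$; the
suite asserts the halving relation structurally on random pairs.  Distances
require equal taxa sets by default (`check_taxa = FALSE` relaxes to the
union).

## The simulator

`simulate_mul_tree()` emulates the standard multi-copy protocol: a species
tree, a random gene-to-species association, coalescent gene trees inside
the species tree, and relabeling of gene leaves by species.

* **Species tree**: Yule, by the backward construction — while $k$ lineages
  remain, an $\mathrm{Exp}(k\lambda)$ epoch elapses and a uniform pair
  merges ($\lambda$ = `speciation_rate`, default 1).  The expected root age
  is $\sum_{k=2}^{n} 1/(k\lambda)$, which the suite checks by Monte Carlo.
* **Association**: each species receives one guaranteed gene copy and the
  remaining $n_\text{genes} - n_\text{species}$ copies are assigned
  uniformly at random, so every label occurs and
  $\mathrm{dup}(T) = n_\text{genes} - n_\text{species}$ exactly.  (This
  guarantee scheme is not the uniform distribution over surjections; the
  difference is immaterial for the experiments and keeps generation
  rejection-free.)
* **Coalescent**: within a population of $k$ lineages, merging happens at
  rate $\binom{k}{2}/\theta$ (`theta`, default 1); lineages pool at species
  divergences and a common ancestor is forced above the root.  Lineages of
  different species therefore never coalesce below the species' divergence,
  which the suite checks in the $\theta \to 0$ limit.

What the generator does *not* emulate: gene flow, hybridization, loss,
non-ultrametric species trees, or any reconciliation-based placement of
duplications.  Passing tests on these synthetic trees therefore says
nothing about data whose multi-labeling arises from processes other than
multi-copy sampling under the coalescent.

## The experiments, and the sizes they use

`run_experiment()` simulates datasets, extracts the full triplet set of
each source tree, reconstructs with `mtrt()`, verifies consistency, and
records duplication counts and classes (output fewer / equal / more than
the source), both distances, isomorphism, and optionally the exact
solver's result.  `glance()` aggregates percentages;
`cross_classification()` crosses the duplication classes with
$d'_R = 0$ versus $d'_R \neq 0$ — the informative cross because
$d'_R = 0$ with distinct trees is exactly the non-uniqueness phenomenon
above.

The shipped experiment sizes — 100 datasets with 5–30 gene copies (species
drawn from $3 \dots \lfloor n/2 \rfloor$) for the duplication comparison,
and 50 datasets with 5–9 gene copies over 5–7 species for the
exact-agreement comparison — keep a full run in seconds on one core while
leaving the per-dataset problem large enough that the auxiliary graph
passes through disconnected, connected and complete regimes.  Dataset $i$
is seeded with $\texttt{seed} + i - 1$, so runs are reproducible and
individually re-derivable.

## Numerical and degenerate-input choices

* All tie-breaks (children in canonical forms, separator choice, component
  grouping, caterpillar order, the exact solver's winner) are lexicographic
  in C-locale (radix) order; identical inputs give identical outputs.
* Separator scores are compared with a $10^{-12}$ guard so that
  floating-point noise cannot override the lexicographic tie-break.
* Branch lengths and internal labels in input Newick are accepted and
  discarded; every method is topology-only.  Writers emit no lengths.
* Single-label trees are represented as a root with one leaf child (the
  `(a);` convention), and `mtrt()` on one label returns such a tree;
  two-label calls return a cherry.
* Empty triplet tables are legal everywhere and produce caterpillars
  (`mtrt`), zero distances against themselves, and empty encodings.
* Newick syntax errors report the character offset of the first unbalanced
  parenthesis or empty label; non-binary nodes are rejected rather than
  auto-resolved, since a polytomy has no unambiguous triplet encoding.

## Known limitations

* The heuristic carries no approximation guarantee; on adversarial
  instances it can exceed the optimum even where the exact solver proves a
  small answer exists.
* The exact solver is exponential and honest about it: beyond 7 labels or
  3 duplications (or past the node cap) it refuses rather than answers.
* The set distance $d_R$ requires no normalization here; neither distance
  is scaled by the number of triplets, so values grow with taxa counts and
  are comparable only between trees on the same label set.
* `min_separators()` is greedy; its family is correct (every member is a
  minimal separator) but not guaranteed exhaustive, and in rare graphs its
  minimum size may exceed the true minimum.
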