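# Independent oracles used to pin expected values.  These deliberately take
# different code paths from the package internals: lca/depth computations go
# through ape (getMRCA, dist.nodes on unit branch lengths), and the smallest
# MUL tree is found by plain enumeration + consistency filtering.

rand_triplet_set <- function(labs, m) {
  rows <- t(replicate(m, sample(labs, 3L)))
  triplets(rows[, 1L], rows[, 2L], rows[, 3L])
}

# occurrence-triple count of xy|z straight from the embedding definition
brute_multiplicity <- function(tree, x, y, z) {
  tree <- as_multree(tree)
  phy <- tree
  class(phy) <- "phylo"
  phy$edge.length <- rep(1, nrow(phy$edge))
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  depth <- ape::dist.nodes(phy)[root, ]
  occ <- function(lab) which(phy$tip.label == lab)
  mrca2 <- function(a, b) if (a == b) a else ape::getMRCA(phy, c(a, b))
  count <- 0L
  for (xi in occ(x)) for (yj in occ(y)) for (zk in occ(z)) {
    axy <- mrca2(xi, yj)
    axyz <- ape::getMRCA(phy, unique(c(xi, yj, zk)))
    if (depth[axy] > depth[axyz]) count <- count + 1L
  }
  count
}

# exhaustive smallest-MUL-tree search via the R enumerator
r_smallest_multree <- function(trips, labs, max_dup = 2L) {
  for (d in 0:max_dup) {
    cons <- character(0)
    for (e in multriplet:::multiset_choices(length(labs), d)) {
      ms <- sort(c(labs, labs[e]))
      for (tr in enumerate_multrees(ms))
        if (all(is_consistent(tr, trips)))
          cons <- c(cons, canonical_form(tr))
    }
    if (length(cons)) return(list(dup = d, canonical = min(cons)))
  }
  NULL
}

rand_multree <- function(n_genes, n_species, seed) {
  simulate_mul_tree(sim_config(n_genes, min(n_species, n_genes),
                               seed = seed))
}
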