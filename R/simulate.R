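#' Configuration for the MUL tree simulator
#'
#' The simulator emulates the classical multi-copy protocol: a species tree
#' is drawn, each of `n_genes` gene copies is assigned to a species (every
#' species receives at least one copy), gene lineages coalesce backward in
#' time inside the species tree, and finally each gene leaf is relabeled by
#' its species — producing a rooted binary MUL tree whose duplicated labels
#' are exactly the species carrying several gene copies.
#'
#' @param n_genes Number of gene copies (leaves of the MUL tree); typical
#'   study sizes run from 5 to 50.
#' @param n_species Number of species (distinct labels), at least 2 and at
#'   most `n_genes`.
#' @param theta Coalescent intensity: within a population of `k` lineages,
#'   pairwise coalescences occur at total rate `choose(k, 2) / theta`.
#' @param speciation_rate Birth rate of the Yule species tree.
#' @param seed Integer seed making the whole simulation reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes, n_species, theta = 1, speciation_rate = 1,
                       seed = NULL) {
  n_genes <- as.integer(n_genes)
  n_species <- as.integer(n_species)
  stopifnot(n_species >= 2L, n_genes >= n_species,
            theta > 0, speciation_rate > 0)
  structure(list(n_genes = n_genes, n_species = n_species, theta = theta,
                 speciation_rate = speciation_rate, seed = seed),
            class = "sim_config")
}

#' Simulate an ultrametric Yule species tree
#'
#' Backward construction of the pure-birth tree conditioned on `n` tips:
#' while `k` lineages remain, an exponential epoch of rate
#' `k * speciation_rate` elapses and a uniformly chosen pair merges.  The
#' expected root age is therefore `sum_{k=2..n} 1 / (k * rate)`.
#'
#' @param n_species Number of tips (>= 2); tips are labeled `s01`, `s02`, ...
#' @param speciation_rate Birth rate (per lineage).
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` with branch lengths.
#' @export
simulate_species_tree <- function(n_species, speciation_rate = 1,
                                  seed = NULL) {
  stopifnot(n_species >= 2L)
  if (!is.null(seed)) set.seed(seed)
  nwk <- sprintf("s%02d", seq_len(n_species))
  age <- numeric(n_species)
  t <- 0
  k <- n_species
  while (k > 1L) {
    t <- t + stats::rexp(1L, rate = k * speciation_rate)
    pair <- sort(sample.int(k, 2L))
    i <- pair[1L]; j <- pair[2L]
    nwk[i] <- sprintf("(%s:%.10f,%s:%.10f)", nwk[i], t - age[i],
                      nwk[j], t - age[j])
    age[i] <- t
    nwk <- nwk[-j]
    age <- age[-j]
    k <- k - 1L
  }
  ape::read.tree(text = paste0(nwk[1L], ";"))
}

#' Simulate a MUL tree under the multispecies coalescent
#'
#' Draws a Yule species tree, assigns gene copies to species (one guaranteed
#' copy per species, the remainder uniform), coalesces the gene lineages
#' backward in time — lineages of a population merge pairwise at rate
#' `choose(k, 2) / theta`, populations pool at species divergences, and a
#' common ancestor is forced above the root — and relabels every gene leaf
#' by its species.  The result is a rooted binary MUL tree `T` with
#' `n(T) = n_genes` leaves over the `n_species` species labels, so
#' `dup(T) = n_genes - n_species` always.
#'
#' @param cfg A [sim_config()].
#' @return A [multree][as_multree] with attribute `provenance`: a list with
#'   the config, the species tree (`phylo`), and the gene-to-species
#'   assignment tibble.
#' @examples
#' t <- simulate_mul_tree(sim_config(8, 3, seed = 1))
#' dup_count(t)  # 5
#' @export
simulate_mul_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sp <- simulate_species_tree(cfg$n_species, cfg$speciation_rate)
  species <- sp$tip.label

  n_extra <- cfg$n_genes - cfg$n_species
  assignment <- c(seq_len(cfg$n_species),
                  if (n_extra > 0L)
                    sample.int(cfg$n_species, n_extra, replace = TRUE))
  assignment <- sample(assignment)  # shuffle gene order
  assign_tbl <- tibble::tibble(gene = seq_len(cfg$n_genes),
                               species = species[assignment])

  ntip <- cfg$n_species
  bt <- ape::branching.times(sp)
  ages <- numeric(ntip + sp$Nnode)
  ages[as.integer(names(bt))] <- bt
  kids <- children_map(sp)

  # population id (species-tree node) -> list of lineage newick fragments
  pops <- vector("list", ntip + sp$Nnode)
  for (s in seq_len(ntip))
    pops[[s]] <- as.list(rep(species[s], sum(assignment == s)))

  coalesce <- function(lins, t0, t1) {
    k <- length(lins)
    t <- t0
    while (k > 1L) {
      t <- t + stats::rexp(1L, rate = choose(k, 2) / cfg$theta)
      if (t > t1) break
      pair <- sort(sample.int(k, 2L))
      lins[[pair[1L]]] <- paste0("(", lins[[pair[1L]]], ",",
                                 lins[[pair[2L]]], ")")
      lins[[pair[2L]]] <- NULL
      k <- k - 1L
    }
    lins
  }

  internal <- order(ages[(ntip + 1L):(ntip + sp$Nnode)]) + ntip
  for (v in internal) {
    pooled <- list()
    for (ch in kids[[v]])
      pooled <- c(pooled, coalesce(pops[[ch]], ages[ch], ages[v]))
    pops[[v]] <- pooled
  }
  root <- ntip + 1L
  final <- coalesce(pops[[root]], ages[root], Inf)
  stopifnot(length(final) == 1L)

  out <- parse_newick(paste0(final[[1L]], ";"))
  attr(out, "provenance") <- list(config = cfg, species_tree = sp,
                                  assignment = assign_tbl)
  out
}
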