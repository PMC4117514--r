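#' Compare a reconstructed MUL tree with its source tree
#'
#' Computes the duplication counts of both trees, the duplication class
#' (`"less"`, `"equal"` or `"greater"`: whether the reconstruction has
#' fewer, as many, or more duplications than the source), the set-based and
#' multiset-based rooted triplet distances, and whether the two trees are
#' isomorphic.  Isomorphic trees always have multiset distance 0; the
#' converse can fail, which is exactly the phenomenon the multiset distance
#' was introduced to study.
#'
#' @param t_in The source (input) MUL tree.
#' @param t_out The reconstructed (output) MUL tree; must carry the same
#'   label set.
#' @return A one-row tibble with columns `dup_in`, `dup_out`, `dup_class`,
#'   `dR`, `dpR`, `isomorphic`.
#' @examples
#' compare_trees("((a,b),(b,c));", "((a,b),(b,c));")
#' @export
compare_trees <- function(t_in, t_out) {
  t_in <- as_multree(t_in)
  t_out <- as_multree(t_out)
  if (!setequal(leaf_labels(t_in), leaf_labels(t_out)))
    stop("label sets differ between input and output trees", call. = FALSE)
  di <- dup_count(t_in)
  do <- dup_count(t_out)
  tibble::tibble(
    dup_in = di,
    dup_out = do,
    dup_class = factor(if (do < di) "less" else if (do == di) "equal"
                       else "greater",
                       levels = c("less", "equal", "greater")),
    dR = triplet_distance(t_in, t_out),
    dpR = triplet_distance(t_in, t_out, multiset = TRUE),
    isomorphic = is_isomorphic(t_in, t_out)
  )
}

#' Run a simulation experiment on the triplet-based MUL tree heuristic
#'
#' For each of `n_datasets` replicates: simulate a MUL tree (gene and
#' species counts drawn uniformly from the given ranges, dataset `i` seeded
#' with `seed + i - 1`), extract its full triplet set, run [mtrt()] on it,
#' and compare output with source via [compare_trees()].  With
#' `mode = "both"` the exact solver [smallest_multree()] is also run; its
#' budget violations are recorded per dataset (`exact_solved = FALSE`) and
#' excluded from the agreement denominator.  Every output tree is asserted
#' to be consistent with its full input triplet set.
#'
#' @param n_datasets Number of simulated datasets.
#' @param seed Base seed; dataset `i` uses `seed + i - 1`.
#' @param genes_range Length-2 integer range for the number of gene copies.
#' @param species_range Length-2 range for the number of species, or `NULL`
#'   for the default `3 .. max(3, floor(n_genes / 2))`; the draw is always
#'   capped at `n_genes`.
#' @param theta,speciation_rate Passed to [sim_config()].
#' @param alpha Separator-score weight for [mtrt()].
#' @param mode `"heuristic"` or `"both"` (also run the exact solver).
#' @param budget [search_budget()] for `mode = "both"`.
#' @return An object of class `smrt_experiment`; see [tidy.smrt_experiment()]
#'   for the per-dataset records and [glance.smrt_experiment()] for the
#'   aggregate summary.
#' @examples
#' ex <- run_experiment(3, seed = 1, genes_range = c(5, 8))
#' glance(ex)
#' @export
run_experiment <- function(n_datasets, seed = 1L,
                           genes_range = c(5L, 30L),
                           species_range = NULL,
                           theta = 1, speciation_rate = 1, alpha = 2,
                           mode = c("heuristic", "both"),
                           budget = search_budget()) {
  mode <- match.arg(mode)
  records <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    seed_i <- seed + i - 1L
    set.seed(seed_i)
    draw <- function(v) v[sample.int(length(v), 1L)]  # safe for length 1
    ng <- draw(genes_range[1L]:genes_range[2L])
    sr <- if (is.null(species_range)) c(3L, max(3L, ng %/% 2L))
          else species_range
    lo <- max(2L, sr[1L])
    hi <- max(lo, min(sr[2L], ng))
    ns <- draw(lo:hi)
    t_in <- simulate_mul_tree(sim_config(ng, ns, theta = theta,
                                         speciation_rate = speciation_rate,
                                         seed = seed_i))
    trips <- triplet_set(t_in)
    t0 <- proc.time()[["elapsed"]]
    t_out <- mtrt(trips, leaf_labels(t_in), alpha = alpha)
    runtime <- proc.time()[["elapsed"]] - t0
    if (!all(is_consistent(t_out, trips)))
      stop("internal error: heuristic output inconsistent with its input ",
           "triplets (dataset ", i, ")")
    rec <- compare_trees(t_in, t_out)
    rec$dataset <- i
    rec$seed <- seed_i
    rec$n_genes <- ng
    rec$n_species <- ns
    rec$runtime_s <- runtime
    if (mode == "both") {
      ex <- tryCatch(smallest_multree(trips, leaf_labels(t_in), budget),
                     error = function(e) e)
      if (inherits(ex, "error")) {
        rec$exact_solved <- FALSE
        rec$dup_exact <- NA_integer_
      } else {
        rec$exact_solved <- TRUE
        rec$dup_exact <- attr(ex, "dup")
      }
    }
    records[[i]] <- rec
  }
  records <- dplyr::bind_rows(records)
  records <- dplyr::relocate(records, dataset, seed, n_genes, n_species)
  structure(list(records = records, mode = mode, seed = seed),
            class = "smrt_experiment")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-dataset records of an experiment
#'
#' @param x An object returned by [run_experiment()].
#' @param ... Unused.
#' @return The per-dataset tibble of comparison records.
#' @export
tidy.smrt_experiment <- function(x, ...) x$records

#' One-row summary of an experiment
#'
#' Percentages of datasets in which the heuristic output has fewer
#' (`pct_less`), as many (`pct_equal`) or more (`pct_greater`) duplications
#' than the source tree; `pct_le = pct_less + pct_equal`; percentages of
#' isomorphic reconstructions and of multiset-distance-0 pairs; and, when
#' the exact solver ran, the number solved within budget and the percentage
#' of those on which heuristic and exact duplication counts agree.
#'
#' @inheritParams tidy.smrt_experiment
#' @return A one-row tibble.
#' @export
glance.smrt_experiment <- function(x, ...) {
  r <- x$records
  n <- nrow(r)
  out <- tibble::tibble(
    n_datasets = n,
    pct_less = 100 * mean(r$dup_class == "less"),
    pct_equal = 100 * mean(r$dup_class == "equal"),
    pct_greater = 100 * mean(r$dup_class == "greater"),
    pct_le = 100 * mean(r$dup_out <= r$dup_in),
    pct_isomorphic = 100 * mean(r$isomorphic),
    pct_dpR_zero = 100 * mean(r$dpR == 0)
  )
  if (x$mode == "both") {
    solved <- r[r$exact_solved, , drop = FALSE]
    out$n_exact_solved <- nrow(solved)
    out$pct_exact_agree <-
      if (nrow(solved) > 0L) 100 * mean(solved$dup_out == solved$dup_exact)
      else NA_real_
  }
  out
}

#' Cross-classification of duplication class by multiset distance
#'
#' Counts datasets in the cross of the duplication classes (output with
#' fewer / equal / more duplications than the source) with whether the
#' multiset triplet distance between output and source is zero — the
#' standard way of summarizing how often a triplet-based reconstruction
#' returns the source tree itself versus a genuinely different but
#' triplet-consistent tree.
#'
#' @inheritParams tidy.smrt_experiment
#' @return A tibble with columns `dup_class`, `dpR_zero`, `count`.
#' @export
cross_classification <- function(x) {
  r <- tidy(x)
  out <- dplyr::count(r, dup_class,
                      dpR_zero = factor(dpR == 0, levels = c(TRUE, FALSE)),
                      name = "count", .drop = FALSE)
  out$dpR_zero <- as.logical(as.character(out$dpR_zero))
  tibble::as_tibble(out)
}

#' @export
print.smrt_experiment <- function(x, ...) {
  cat("MUL-tree reconstruction experiment (", nrow(x$records),
      " datasets, mode = ", x$mode, ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Plot an experiment summary
#'
#' Bar chart of the duplication classes, filled by whether the multiset
#' triplet distance between source and reconstruction is zero.
#'
#' @param object An object returned by [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smrt_experiment <- function(object, ...) {
  r <- tidy(object)
  r$dpR_zero <- ifelse(r$dpR == 0, "d'_R = 0", "d'_R > 0")
  ggplot2::ggplot(r, ggplot2::aes(x = dup_class, fill = dpR_zero)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "duplications of output vs source",
                  y = "datasets", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
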