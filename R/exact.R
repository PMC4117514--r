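#' Search budget for the exact solver
#'
#' The exhaustive smallest-MUL-tree search is exponential; the budget keeps
#' it inside what a desk machine handles.  `max_labels` bounds the size of
#' the label set, `max_dup` the number of extra leaf copies tried, and
#' `max_nodes` the total number of enumeration states visited across the
#' whole search (the pruned enumerator typically visits a tiny fraction of
#' the (2m-3)!! tree shapes).  Exceeding the budget raises an explicit
#' error, never a wrong answer.
#'
#' @param max_labels Maximum number of distinct labels (default 7).
#' @param max_dup Maximum number of duplications to try (default 3).
#' @param max_nodes Cap on visited enumeration states (default 2e7).
#' @return A `search_budget` list.
#' @export
search_budget <- function(max_labels = 7L, max_dup = 3L, max_nodes = 2e7) {
  stopifnot(max_labels >= 1L, max_dup >= 0L, max_nodes > 0)
  structure(list(max_labels = as.integer(max_labels),
                 max_dup = as.integer(max_dup),
                 max_nodes = as.numeric(max_nodes)),
            class = "search_budget")
}

double_factorial_odd <- function(k) {
  # k!! for odd k >= -1
  if (k <= 0L) return(1)
  prod(seq(1, k, by = 2))
}

#' Enumerate all rooted binary MUL trees on a leaf multiset
#'
#' Generates every rooted binary tree over the given leaf label multiset
#' exactly once up to isomorphism (children are unordered), by recursive
#' bipartition of the multiset with canonical-form deduplication.  On `m`
#' distinct leaves this yields the classical (2m-3)!! shapes.  Intended for
#' small cases (oracles, searches for counterexample pairs); the number of
#' shapes is capped via `max_shapes`.
#'
#' @param labels Character vector, the leaf label multiset (repeats allowed).
#' @param max_shapes Refuse enumeration when (2m-3)!! exceeds this cap.
#' @return A list of [multree][as_multree] objects, in canonical order.
#' @examples
#' length(enumerate_multrees(c("a", "b", "c")))     # 3
#' length(enumerate_multrees(c("a", "a", "b")))     # 2
#' @export
enumerate_multrees <- function(labels, max_shapes = 2e5) {
  labels <- sort(as.character(labels))
  m <- length(labels)
  stopifnot(m >= 1L)
  if (double_factorial_odd(2L * m - 3L) > max_shapes)
    stop("enumeration budget exceeded: (2m-3)!! = ",
         format(double_factorial_odd(2L * m - 3L), big.mark = ","),
         " shapes for m = ", m, call. = FALSE)
  cache <- new.env(parent = emptyenv())
  frags <- enum_fragments(labels, cache)
  lapply(sort(frags), function(f) parse_newick(paste0(
    if (m == 1L) paste0("(", f, ")") else f, ";")))
}

enum_fragments <- function(labs, cache) {
  key <- paste(labs, collapse = "\r")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(labs)
  if (n == 1L) return(labs)
  res <- character(0)
  for (sz in seq_len(n - 1L)) {
    # force the first leaf into side A so each split is seen once per
    # index choice; identical label multisets still collapse via unique()
    idx <- if (sz == 1L) matrix(integer(0), nrow = 0L)
           else utils::combn(2:n, sz - 1L)
    picks <- if (sz == 1L) list(1L)
             else lapply(seq_len(ncol(idx)), function(c) c(1L, idx[, c]))
    for (A in picks) {
      fa <- enum_fragments(sort(labs[A]), cache)
      fb <- enum_fragments(sort(labs[-A]), cache)
      for (a in fa) for (b in fb)
        res <- c(res, if (a <= b) paste0("(", a, ",", b, ")")
                      else paste0("(", b, ",", a, ")"))
    }
  }
  res <- unique(res)
  cache[[key]] <- res
  res
}

#' Exact smallest MUL tree consistent with a triplet set
#'
#' Solves the smallest-MUL-tree problem by brute force within a
#' [search_budget()]: for increasing duplication counts `d = 0, 1, ...`, it
#' enumerates every leaf multiset over `L` with `d` extra copies and every
#' rooted binary tree on it (with triplet-based pruning, in compiled code),
#' returning the first consistent tree found.  The result provably attains
#' the minimum number of duplications among MUL trees within the budget;
#' ties are broken by canonical form, so the output is deterministic.
#'
#' @param trips A triplet tibble.
#' @param labels The label set `L` (defaults to the labels in `trips`).
#' @param budget A [search_budget()].
#' @return A [multree][as_multree] with attribute `dup` (the minimum
#'   duplication count) and `nodes` (enumeration states visited).
#' @examples
#' t <- triplets(c("a", "b"), c("b", "c"), c("c", "a"))
#' dup_count(smallest_multree(t))  # 1
#' @export
smallest_multree <- function(trips, labels = NULL, budget = search_budget()) {
  trips <- as_triplet_table(trips)
  occurring <- sort(unique(c(trips$x, trips$y, trips$z)))
  if (is.null(labels)) labels <- occurring
  labels <- sort(unique(as.character(labels)))
  if (!all(occurring %in% labels))
    stop("triplet labels outside the label set: ",
         paste(setdiff(occurring, labels), collapse = ", "), call. = FALSE)
  K <- length(labels)
  if (K > budget$max_labels)
    stop("budget exceeded: ", K, " labels > max_labels = ",
         budget$max_labels, call. = FALSE)
  ids <- stats::setNames(seq_len(K), labels)
  tm <- cbind(ids[trips$x], ids[trips$y], ids[trips$z])
  storage.mode(tm) <- "integer"

  nodes_left <- budget$max_nodes
  nodes_used <- 0
  for (d in 0:budget$max_dup) {
    extras <- multiset_choices(K, d)
    best <- NULL
    for (e in extras) {
      leaf_ids <- sort(c(seq_len(K), e))
      res <- exact_search_cpp(as.integer(leaf_ids), tm, labels, nodes_left)
      nodes_used <- nodes_used + res$nodes
      nodes_left <- nodes_left - res$nodes
      if (res$aborted)
        stop("search budget exhausted after ",
             format(nodes_used, big.mark = ","),
             " enumeration states (d = ", d, ")", call. = FALSE)
      if (res$found && (is.null(best) || res$newick < best))
        best <- res$newick
    }
    if (!is.null(best)) {
      if (!grepl("(", best, fixed = TRUE))  # single-leaf tree
        best <- paste0("(", sub(";$", "", best), ");")
      out <- parse_newick(best)
      attr(out, "dup") <- d
      attr(out, "nodes") <- nodes_used
      return(out)
    }
  }
  stop("no consistent MUL tree within budget (max_dup = ",
       budget$max_dup, ")", call. = FALSE)
}

# all multisets of size d over 1..K, as non-decreasing integer vectors
multiset_choices <- function(K, d) {
  if (d == 0L) return(list(integer(0)))
  rec <- function(lo, d) {
    if (d == 0L) return(list(integer(0)))
    out <- list()
    for (v in lo:K)
      for (rest in rec(v, d - 1L))
        out[[length(out) + 1L]] <- c(v, rest)
    out
  }
  rec(1L, d)
}
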