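#' Auxiliary (Aho) graph of a triplet set
#'
#' The auxiliary graph on a label set `L'` has one vertex per label and an
#' undirected edge `{x, y}` whenever some triplet `xy|z` is present.  Its
#' connectivity drives the top-down recursion of [mtrt()]: connected
#' components can be separated at the root without duplicating any label,
#' whereas a connected graph forces labels (a vertex separator) to be
#' repeated on both sides.
#'
#' @param trips A triplet tibble.
#' @param labels Character vector: the current label set `L'` (every triplet
#'   label must belong to it).
#' @return An `igraph` undirected graph with vertex names `labels`.
#' @examples
#' g <- aux_graph(triplets(c("a", "c"), c("b", "d"), c("c", "e")),
#'                letters[1:5])
#' igraph::components(g)$no
#' @export
aux_graph <- function(trips, labels) {
  labels <- sort(unique(as.character(labels)))
  trips <- as_triplet_table(trips)
  out <- unique(c(trips$x, trips$y, trips$z))
  if (!all(out %in% labels))
    stop("triplet labels outside the label set: ",
         paste(setdiff(out, labels), collapse = ", "), call. = FALSE)
  edges <- unique(trips[, c("x", "y")])
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = labels))
}

## ---- internal adjacency-list engine --------------------------------------
## The recursion works on many small graphs; plain named lists of neighbor
## vectors avoid per-call graph-object overhead.  The igraph objects built
## by aux_graph() remain the public surface.

adj_from_trips <- function(trips, labels) {
  adj <- stats::setNames(vector("list", length(labels)), labels)
  if (nrow(trips) > 0L) {
    e <- unique(paste(trips$x, trips$y, sep = "\r"))
    e <- strsplit(e, "\r", fixed = TRUE)
    for (p in e) {
      adj[[p[1L]]] <- c(adj[[p[1L]]], p[2L])
      adj[[p[2L]]] <- c(adj[[p[2L]]], p[1L])
    }
  }
  lapply(adj, unique)
}

adj_components <- function(adj, verts) {
  unseen <- stats::setNames(rep(TRUE, length(verts)), verts)
  comps <- list()
  for (v in verts) {
    if (!unseen[[v]]) next
    queue <- v
    unseen[[v]] <- FALSE
    comp <- character(0)
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, u)
      for (w in adj[[u]])
        if (w %in% verts && unseen[[w]]) {
          unseen[[w]] <- FALSE
          queue <- c(queue, w)
        }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# greedy variant of the minimal-separator enumeration, on adjacency lists
min_seps_adj <- function(adj, verts) {
  verts <- sort(verts)
  nbrs <- function(vs) unique(unlist(adj[vs], use.names = FALSE))
  seps_from_removal <- function(removed) {
    rest <- setdiff(verts, removed)
    if (length(rest) == 0L) return(list())
    lapply(adj_components(adj, rest),
           function(C) sort(intersect(setdiff(nbrs(C), C), verts)))
  }

  found <- new.env(parent = emptyenv())
  queue <- list()
  add <- function(S) {
    if (length(S) == 0L) return(invisible())
    key <- paste(S, collapse = "\r")
    if (!is.null(found[[key]])) return(invisible())
    found[[key]] <- S
    queue[[length(queue) + 1L]] <<- S
    invisible()
  }
  for (v in verts)
    for (S in seps_from_removal(c(v, nbrs(v)))) add(S)
  if (length(queue) == 0L) return(list())  # complete graph
  k <- min(lengths(queue))

  i <- 1L
  while (i <= length(queue)) {
    S <- queue[[i]]
    i <- i + 1L
    if (length(S) > k) next
    for (x in S)
      for (S2 in seps_from_removal(union(S, nbrs(x))))
        if (length(S2) <= k) {
          add(S2)
          if (length(S2) < k) k <- length(S2)
        }
  }
  all_seps <- as.list(found)
  all_seps <- unname(all_seps[order(names(all_seps), method = "radix")])
  Filter(function(S) length(S) == k, all_seps)
}

#' Greedy enumeration of minimum-size minimal separators
#'
#' A separator of a connected graph is a vertex subset whose removal
#' disconnects it; a minimal separator has no proper subset doing the same
#' for the same pair of components.  Enumerating all minimal separators can
#' take exponential time, so this routine runs the classical
#' generate-and-expand enumeration greedily: close neighborhoods of vertices
#' seed an initial family (for every vertex `v` and component `C` of
#' `G - N[v]`, the neighborhood `N(C)` is a minimal separator), `k` is the
#' smallest size seen, and expansion of a separator `S` by a vertex `x` (the
#' neighborhoods of the components of `G - (S` \eqn{\cup} `N(x))`) only
#' keeps separators of size at most `k`, updating `k` whenever a smaller
#' one appears.  The separators of size exactly `k` found when the
#' expansion queue empties are returned.
#'
#' @param g A connected `igraph` graph with at least 3 vertices.
#' @return A list of character vectors (sorted label subsets), in
#'   lexicographic order; empty for a complete graph, which has no
#'   separator.
#' @examples
#' g <- igraph::make_ring(4)
#' igraph::V(g)$name <- letters[1:4]
#' min_separators(g)
#' @export
min_separators <- function(g) {
  if (!igraph::is_connected(g))
    stop("separator enumeration needs a connected graph", call. = FALSE)
  verts <- igraph::V(g)$name
  if (length(verts) < 3L) stop("need at least 3 vertices", call. = FALSE)
  el <- igraph::as_edgelist(g)
  adj <- stats::setNames(vector("list", length(verts)), sort(verts))
  for (r in seq_len(nrow(el))) {
    adj[[el[r, 1L]]] <- c(adj[[el[r, 1L]]], el[r, 2L])
    adj[[el[r, 2L]]] <- c(adj[[el[r, 2L]]], el[r, 1L])
  }
  min_seps_adj(lapply(adj, unique), sort(verts))
}

#' Group connected components into the two sides of a root split
#'
#' MUL trees are binary, so however many components the auxiliary graph
#' breaks into, they must be grouped into exactly two non-empty sides.  The
#' grouping is a deterministic greedy balance: components are sorted by
#' decreasing size (ties by lexicographically smallest member) and assigned
#' one by one to the currently smaller side (ties to the first side).
#'
#' @param components A list of character vectors (disjoint label sets), at
#'   least two.
#' @return A list with elements `X1` and `X2`, sorted label vectors; `X1`
#'   contains the overall lexicographically smallest label.
#' @export
partition_components <- function(components) {
  if (length(components) < 2L)
    stop("need at least two components to partition", call. = FALSE)
  comps <- lapply(components, sort)
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1), 1L),
               method = "radix")
  comps <- comps[ord]
  side1 <- character(0)
  side2 <- character(0)
  for (C in comps) {
    if (length(side1) <= length(side2)) side1 <- c(side1, C)
    else side2 <- c(side2, C)
  }
  side1 <- sort(side1)
  side2 <- sort(side2)
  if (side2[1L] < side1[1L]) list(X1 = side2, X2 = side1)
  else list(X1 = side1, X2 = side2)
}

#' Score a candidate separator
#'
#' Among the minimum-size separators of a connected auxiliary graph, MTRT
#' picks the one minimizing
#' \deqn{w(S) = \alpha \frac{|t(S)|}{\max(1, |t|)} +
#'   \frac{||L_1| - |L_2||}{|L'|}}
#' where `t(S)` is the set of triplets wholly inside `S`, and `L1`, `L2` are
#' the two sides `X1 U S`, `X2 U S` of the induced split.  The first term
#' penalizes separators that swallow many triplets (those triplets are
#' dropped from the recursion, and a triplet-rich separator tends to force
#' duplications); the second favours a balanced split.  Reducing
#' duplications matters more, so the first term gets the bigger weight
#' (`alpha = 2` by default).
#'
#' @param S Character vector: the separator labels.
#' @param trips The current triplet tibble.
#' @param labels The current label set `L'`.
#' @param sides A list with `X1`, `X2` (from [partition_components()] on the
#'   components of the graph minus `S`).
#' @param alpha Weight of the triplet term (default 2).
#' @return The numeric score `w` (lower is better).
#' @export
score_separator <- function(S, trips, labels, sides, alpha = 2) {
  l1 <- length(union(sides$X1, S))
  l2 <- length(union(sides$X2, S))
  alpha * nrow(induce_triplets(trips, S)) / max(1L, nrow(trips)) +
    abs(l1 - l2) / length(labels)
}

caterpillar_newick <- function(labels) {
  labels <- sort(labels)
  out <- labels[1L]
  for (l in labels[-1L]) out <- paste0("(", out, ",", l, ")")
  out
}

#' Build a MUL tree consistent with a triplet set (MTRT heuristic)
#'
#' Top-down Aho-style recursion.  On label set `L'` with triplet set `t`:
#' a single label is a leaf and two labels a cherry; an empty triplet set on
#' three or more labels yields a deterministic caterpillar over the sorted
#' labels (any topology is consistent).  If the auxiliary graph is
#' disconnected, its components are grouped into two sides and the recursion
#' descends with the induced triplet sets — exactly Aho's BUILD, with no
#' duplication.  If it is connected, a minimum-size minimal separator `S`
#' with the best score [score_separator()] is duplicated onto both sides:
#' the recursion descends on `L_i = X_i U S` with the induced triplet sets
#' from which every triplet whose outgroup lies in `S` has been removed —
#' once `S` appears on both sides of the root such a triplet is
#' automatically consistent: its cherry embeds within one child (cherries
#' are graph edges, which never cross the split) and the other side's copy
#' of the outgroup sits outside that child.  If the auxiliary graph is
#' complete no separator exists; the fallback duplicates the single label
#' that is most often an outgroup, hangs the extra copy directly off the
#' root (making every triplet with that outgroup automatically consistent),
#' and recurses on the full label set with those triplets dropped — one
#' duplication per step, and the triplet set strictly shrinks, so the
#' recursion terminates.  The output is always a binary MUL tree on exactly
#' `L`, consistent with every input triplet, and identical across runs (all
#' tie-breaks are lexicographic).
#'
#' @param trips A triplet tibble (the input set `t`).
#' @param labels Character vector: the full label set `L`.  Defaults to the
#'   labels occurring in `trips`.
#' @param alpha Separator-score weight, see [score_separator()].
#' @return A [multree][as_multree] on label set `L`.
#' @examples
#' t <- triplets(c("a", "b"), c("b", "c"), c("c", "a"))
#' tr <- mtrt(t)
#' dup_count(tr)               # 1: label b is duplicated
#' all(is_consistent(tr, t))   # TRUE
#' @export
mtrt <- function(trips, labels = NULL, alpha = 2) {
  trips <- as_triplet_table(trips)
  occurring <- sort(unique(c(trips$x, trips$y, trips$z)))
  if (is.null(labels)) labels <- occurring
  labels <- sort(unique(as.character(labels)))
  if (length(labels) < 1L) stop("need at least one label", call. = FALSE)
  if (!all(occurring %in% labels))
    stop("triplet labels outside the label set: ",
         paste(setdiff(occurring, labels), collapse = ", "), call. = FALSE)
  nwk <- mtrt_rec(trips, labels, alpha)
  if (length(labels) == 1L) nwk <- paste0("(", nwk, ")")
  parse_newick(paste0(nwk, ";"))
}

mtrt_rec <- function(trips, labels, alpha) {
  labels <- sort(labels)
  if (length(labels) == 1L) return(labels)
  if (length(labels) == 2L) {
    stopifnot(nrow(trips) == 0L)  # a triplet needs 3 distinct labels
    return(paste0("(", labels[1L], ",", labels[2L], ")"))
  }
  if (nrow(trips) == 0L) return(caterpillar_newick(labels))

  adj <- adj_from_trips(trips, labels)
  comps <- adj_components(adj, labels)
  if (length(comps) >= 2L) {
    sides <- partition_components(comps)
    return(paste0(
      "(", mtrt_rec(induce_triplets(trips, sides$X1), sides$X1, alpha),
      ",", mtrt_rec(induce_triplets(trips, sides$X2), sides$X2, alpha),
      ")"))
  }

  seps <- min_seps_adj(adj, labels)
  if (length(seps) > 0L) {
    best <- NULL
    best_w <- Inf
    for (S in seps) {
      sides <- partition_components(adj_components(adj, setdiff(labels, S)))
      w <- score_separator(S, trips, labels, sides, alpha)
      if (w < best_w - 1e-12) {  # ties resolved by lexicographic order of S
        best_w <- w
        best <- list(S = S, sides = sides)
      }
    }
    S <- best$S
    L1 <- sort(union(best$sides$X1, S))
    L2 <- sort(union(best$sides$X2, S))
    # Triplets whose outgroup lies in S are automatically consistent once S
    # is repeated on both sides of the root: their cherry embeds inside one
    # child (an edge of the graph never crosses the two sides), and the
    # other side's copy of the outgroup lies outside that child.  Dropping
    # them (the wholly-in-S triplets are the special case with all three
    # labels in S) leaves the children free of constraints the root split
    # has already discharged.
    kept <- trips[!(trips$z %in% S), , drop = FALSE]
    return(paste0(
      "(", mtrt_rec(induce_triplets(kept, L1), L1, alpha),
      ",", mtrt_rec(induce_triplets(kept, L2), L2, alpha),
      ")"))
  }

  # Complete auxiliary graph: no separator exists.  Duplicate one label b,
  # hanging an extra copy directly off the root: every triplet with
  # outgroup b is then automatically consistent (its cherry embeds in the
  # other child, below the root, with the extra b outside), so those
  # triplets can be dropped and the recursion continues on the full label
  # set with a strictly smaller triplet set.  Costs exactly one duplication
  # per step; b is the most frequent outgroup (ties lexicographic).
  counts <- table(trips$z)
  b <- names(counts)[counts == max(counts)][1L]
  remaining <- trips[trips$z != b, , drop = FALSE]
  paste0("(", mtrt_rec(remaining, labels, alpha), ",", b, ")")
}
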