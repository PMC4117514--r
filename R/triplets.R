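#' Rooted triplets as tibbles
#'
#' A rooted triplet `xy|z` is a binary rooted tree on three distinct taxa in
#' which `x` and `y` are closer to each other than either is to `z`.  This
#' package stores triplets as tibbles with columns `x`, `y`, `z` (the cherry
#' pair `{x, y}` and the outgroup `z`) and, for multisets, a positive integer
#' multiplicity column `n`.  The cherry pair is unordered: rows are
#' canonicalized so that `x < y`, and duplicate rows are merged.
#'
#' @param x,y,z Character vectors (recycled) naming the cherry pair and the
#'   outgroup of each triplet.
#' @param n Optional positive integer multiplicities (default 1); only
#'   retained when `multiset = TRUE`.
#' @param multiset If `TRUE` return a triplet multiset (with an `n` column);
#'   otherwise a plain triplet set.
#' @return A tibble with columns `x`, `y`, `z` (and `n` for multisets).
#' @examples
#' triplets(c("a", "b"), c("b", "c"), c("c", "a"))
#' @export
triplets <- function(x, y, z, n = 1L, multiset = FALSE) {
  x <- as.character(x); y <- as.character(y); z <- as.character(z)
  len <- max(length(x), length(y), length(z))
  if (len == 0L) return(empty_triplets(multiset))
  x <- rep_len(x, len); y <- rep_len(y, len); z <- rep_len(z, len)
  n <- rep_len(as.integer(n), len)
  if (any(x == y | x == z | y == z))
    stop("a triplet needs three distinct labels", call. = FALSE)
  if (any(n < 1L)) stop("multiplicities must be >= 1", call. = FALSE)
  swap <- x > y
  if (any(swap)) {
    tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
  }
  o <- order(x, y, z, method = "radix")
  x <- x[o]; y <- y[o]; z <- z[o]; n <- n[o]
  key <- paste(x, y, z, sep = "\r")
  first <- !duplicated(key)
  tb <- tibble::tibble(x = x[first], y = y[first], z = z[first])
  if (multiset)
    tb$n <- as.integer(rowsum(n, factor(key, levels = key[first]))[, 1L])
  tb
}

triplet_key <- function(tb) paste(tb$x, tb$y, tb$z, sep = "\r")

# canonical per-row keys, preserving input order (cherry pair unordered)
query_keys <- function(x, y, z) {
  x <- as.character(x); y <- as.character(y); z <- as.character(z)
  if (any(x == y | x == z | y == z))
    stop("a triplet needs three distinct labels", call. = FALSE)
  paste(pmin(x, y), pmax(x, y), z, sep = "\r")
}

empty_triplets <- function(multiset = FALSE) {
  tb <- tibble::tibble(x = character(), y = character(), z = character())
  if (multiset) tb$n <- integer()
  tb
}

# accept trees, triplet tibbles (with or without n); return canonical tibble
as_triplet_table <- function(obj, multiset = FALSE) {
  if (inherits(obj, "multree") || inherits(obj, "phylo") ||
      (is.character(obj) && length(obj) == 1L)) {
    return(if (multiset) triplet_multiset(obj) else triplet_set(obj))
  }
  if (is.data.frame(obj)) {
    stopifnot(all(c("x", "y", "z") %in% names(obj)))
    n <- if ("n" %in% names(obj)) obj$n else 1L
    return(triplets(obj$x, obj$y, obj$z, n, multiset = multiset))
  }
  stop("expected a MUL tree or a triplet tibble", call. = FALSE)
}

#' Triplet encodings of a MUL tree
#'
#' Every choice of three leaves with pairwise-distinct labels in a rooted
#' binary MUL tree resolves exactly one rooted triplet: the pair whose lca is
#' deepest forms the cherry.  `triplet_multiset()` counts, for each triplet
#' `xy|z`, the number of such leaf occurrence triples realizing it (the
#' triplet encoding multiset `mt(T)`); `triplet_set()` is its underlying set
#' (the triplet encoding `t(T)`); `triplet_multiplicity()` looks up single
#' triplets.
#'
#' @inheritParams write_newick
#' @param x,y,z Labels of the triplet(s) queried (vectors are recycled).
#' @return `triplet_set()`: tibble `x`, `y`, `z`; `triplet_multiset()`: the
#'   same plus multiplicity `n`; `triplet_multiplicity()`: integer vector of
#'   occurrence counts (0 when the triplet is not consistent with the tree).
#' @examples
#' triplet_set(parse_newick("((a,b),(c,d));"))
#' triplet_multiplicity(parse_newick("((a,b),((a,b),c));"), "a", "b", "c")
#' @export
triplet_multiset <- function(tree) {
  tree <- as_multree(tree)
  ntip <- n_leaves(tree)
  labs <- tree$tip.label
  if (ntip < 3L || length(unique(labs)) < 3L) return(empty_triplets(TRUE))
  D <- lca_depth_matrix(tree)
  cmb <- utils::combn(ntip, 3L)
  i <- cmb[1L, ]; j <- cmb[2L, ]; k <- cmb[3L, ]
  dij <- D[cbind(i, j)]; dik <- D[cbind(i, k)]; djk <- D[cbind(j, k)]
  li <- labs[i]; lj <- labs[j]; lk <- labs[k]
  distinct <- li != lj & li != lk & lj != lk
  # exactly one of the three pairwise lcas is strictly deepest in a binary tree
  cherry_ij <- distinct & dij > dik & dij > djk
  cherry_ik <- distinct & dik > dij & dik > djk
  cherry_jk <- distinct & djk > dij & djk > dik
  tb <- tibble::tibble(
    x = c(li[cherry_ij], li[cherry_ik], lj[cherry_jk]),
    y = c(lj[cherry_ij], lk[cherry_ik], lk[cherry_jk]),
    z = c(lk[cherry_ij], lj[cherry_ik], li[cherry_jk])
  )
  if (nrow(tb) == 0L) return(empty_triplets(TRUE))
  triplets(tb$x, tb$y, tb$z, multiset = TRUE)
}

#' @rdname triplet_multiset
#' @export
triplet_set <- function(tree) {
  tb <- triplet_multiset(tree)
  tb$n <- NULL
  tb
}

#' @rdname triplet_multiset
#' @export
triplet_multiplicity <- function(tree, x, y, z) {
  enc <- triplet_multiset(tree)
  out <- enc$n[match(query_keys(x, y, z), triplet_key(enc))]
  out[is.na(out)] <- 0L
  out
}

#' Is a triplet consistent with (embeddable in) a MUL tree?
#'
#' A triplet `xy|z` is consistent with a MUL tree when some choice of leaf
#' occurrences of `x`, `y` and `z` realizes it as an embedded subtree, i.e.
#' the lca of the chosen `x` and `y` leaves is a proper descendant of the lca
#' of all three.  Triplets whose labels do not all occur in the tree are
#' inconsistent.
#'
#' @inheritParams write_newick
#' @param trips A triplet tibble (one row per triplet to test).
#' @return A logical vector, one entry per row of `trips`.
#' @examples
#' is_consistent(parse_newick("((a,b),c);"), triplets("a", "b", "c"))
#' @export
is_consistent <- function(tree, trips) {
  if (!is.data.frame(trips)) trips <- as_triplet_table(trips)
  if (nrow(trips) == 0L) return(logical(0))
  enc <- triplet_set(tree)
  !is.na(match(query_keys(trips$x, trips$y, trips$z), triplet_key(enc)))
}

#' Induced triplet set
#'
#' Restricts a triplet set (or multiset) to the triplets whose three labels
#' all lie in a given label subset.
#'
#' @param trips A triplet tibble.
#' @param labels Character vector of labels to restrict to.
#' @return The filtered tibble.
#' @export
induce_triplets <- function(trips, labels) {
  trips[trips$x %in% labels & trips$y %in% labels & trips$z %in% labels, ,
        drop = FALSE]
}

#' Multiset symmetric difference and size
#'
#' The symmetric difference of two multisets has, at each element, the
#' absolute difference of the two multiplicities; its size is the sum of the
#' resulting multiplicities.  Triplet sets are treated as multisets with all
#' multiplicities 1.
#'
#' @param m1,m2 Triplet tibbles (multisets; an `n` column of 1s is assumed if
#'   absent) or MUL trees (converted via [triplet_multiset()]).
#' @return `multiset_symdiff()`: a triplet multiset tibble;
#'   `multiset_size()`: the integer total multiplicity.
#' @export
multiset_symdiff <- function(m1, m2) {
  m1 <- as_triplet_table(m1, multiset = TRUE)
  m2 <- as_triplet_table(m2, multiset = TRUE)
  j <- dplyr::full_join(m1, m2, by = c("x", "y", "z"),
                        suffix = c("1", "2"))
  n1 <- ifelse(is.na(j$n1), 0L, j$n1)
  n2 <- ifelse(is.na(j$n2), 0L, j$n2)
  j$n <- abs(n1 - n2)
  out <- j[j$n > 0L, c("x", "y", "z", "n")]
  dplyr::arrange(tibble::as_tibble(out), x, y, z)
}

#' @rdname multiset_symdiff
#' @param m A triplet multiset tibble.
#' @export
multiset_size <- function(m) {
  m <- as_triplet_table(m, multiset = TRUE)
  sum(m$n)
}

#' Rooted triplet distances between MUL trees
#'
#' The set-based rooted triplet distance between two trees on the same taxa
#' set is half the size of the symmetric difference of their triplet
#' encodings `t(T1)` and `t(T2)`.  Because a triplet can be embedded several
#' times in a MUL tree, the set-based distance can vanish on genuinely
#' different MUL trees; the multiset variant (`multiset = TRUE`) instead
#' halves the size of the multiset symmetric difference of the encoding
#' multisets `mt(T1)` and `mt(T2)` and separates such pairs by their
#' multiplicities.  Either argument may also be a triplet tibble, so the
#' distance between a tree and a triplet (multi)set, or between two
#' (multi)sets, uses the same function.
#'
#' @param a,b MUL trees or triplet tibbles.
#' @param multiset If `TRUE` compute the multiset-based distance, otherwise
#'   the set-based distance.
#' @param check_taxa Require both arguments to cover the same label set
#'   (default `TRUE`, matching the definition "on taxa set L").
#' @return A non-negative number (multiples of 1/2).
#' @examples
#' triplet_distance("((a,b),c);", "(a,(b,c));")              # 1
#' triplet_distance("((a,b),c);", "((a,b),c);", multiset = TRUE) # 0
#' @export
triplet_distance <- function(a, b, multiset = FALSE, check_taxa = TRUE) {
  ta <- as_triplet_table(a, multiset = multiset)
  tb <- as_triplet_table(b, multiset = multiset)
  if (check_taxa) {
    la <- triplet_universe(a, ta)
    lb <- triplet_universe(b, tb)
    if (!setequal(la, lb))
      stop("taxa sets differ; only in first: {",
           paste(setdiff(la, lb), collapse = ", "),
           "}, only in second: {",
           paste(setdiff(lb, la), collapse = ", "), "}", call. = FALSE)
  }
  if (!multiset) {
    ta$n <- 1L
    tb$n <- 1L
  }
  multiset_size(multiset_symdiff(ta, tb)) / 2
}

triplet_universe <- function(obj, trips) {
  if (inherits(obj, "multree") || inherits(obj, "phylo") ||
      (is.character(obj) && length(obj) == 1L))
    return(leaf_labels(as_multree(obj)))
  sort(unique(c(trips$x, trips$y, trips$z)))
}

#' Read and write triplet tables
#'
#' Plain-text TSV dialect: one triplet per line as `x<TAB>y<TAB>z` meaning
#' `xy|z`, with an optional fourth integer column holding the multiplicity
#' (default 1).  Lines starting with `#` are comments.  The reader
#' canonicalizes the cherry pair order and merges duplicate rows; the writer
#' sorts rows lexicographically.
#'
#' @param file Path to a TSV file.
#' @param multiset Keep multiplicities (`TRUE`) or return the underlying set.
#' @param trips A triplet tibble to write.
#' @return `read_triplets()`: a triplet tibble; `write_triplets()`: the file
#'   path, invisibly.
#' @export
read_triplets <- function(file, multiset = FALSE) {
  # rows may or may not carry the optional multiplicity column; silence the
  # ragged-row note and validate the parsed columns ourselves below
  raw <- withCallingHandlers(
    readr::read_tsv(file, col_names = FALSE, comment = "#",
                    col_types = readr::cols(.default = "c"),
                    progress = FALSE),
    warning = function(w) {
      if (inherits(w, "vroom_parse_issue")) invokeRestart("muffleWarning")
    })
  if (nrow(raw) == 0L) return(empty_triplets(multiset))
  if (ncol(raw) < 3L)
    stop("triplet TSV needs at least 3 columns", call. = FALSE)
  n <- if (ncol(raw) >= 4L) {
    v <- suppressWarnings(as.integer(raw[[4L]]))
    v[is.na(raw[[4L]])] <- 1L  # rows without the optional 4th column
    if (anyNA(v)) stop("non-integer multiplicity column", call. = FALSE)
    v
  } else 1L
  triplets(trimws(raw[[1L]]), trimws(raw[[2L]]), trimws(raw[[3L]]),
           n, multiset = multiset)
}

#' @rdname read_triplets
#' @export
write_triplets <- function(trips, file) {
  trips <- as_triplet_table(trips, multiset = TRUE)
  trips <- dplyr::arrange(trips, x, y, z)
  readr::write_tsv(trips, file, col_names = FALSE, progress = FALSE)
  invisible(file)
}
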