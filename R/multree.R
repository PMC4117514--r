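#' Rooted binary multi-labeled trees (MUL trees)
#'
#' A MUL tree is a rooted binary phylogenetic tree whose leaves carry taxon
#' labels that are allowed to repeat (e.g. several gene copies of one
#' species).  `multree` objects are `phylo`-compatible: they hold the usual
#' `edge` matrix, `tip.label` vector and `Nnode` count, so `ape` tools that
#' only look at topology (plotting, `write.tree`, ...) work on them.  Branch
#' lengths and internal labels are never stored: all methods in this package
#' are topology-only.
#'
#' @param x An object to convert: a `phylo`, a Newick string, or a `multree`.
#' @return A `multree` object (classes `c("multree", "phylo")`).
#' @seealso [parse_newick()], [write_newick()], [dup_count()],
#'   [canonical_form()]
#' @export
as_multree <- function(x) {
  if (inherits(x, "multree")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_newick(x))
  if (inherits(x, "phylo")) {
    x$edge.length <- NULL
    x$node.label <- NULL
    x$tip.label <- trimws(x$tip.label)
    class(x) <- c("multree", "phylo")
    validate_multree(x)
    return(x)
  }
  stop("cannot convert object of class '", paste(class(x), collapse = "/"),
       "' to a multree", call. = FALSE)
}

# Single-leaf trees are represented the way ape writes "(a);": a root node
# with one child leaf.  Everything else must be strictly binary.
validate_multree <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 1L) stop("a MUL tree needs at least one leaf", call. = FALSE)
  if (any(!nzchar(tree$tip.label)))
    stop("empty leaf label", call. = FALSE)
  bad <- grepl("[][(),;:]", tree$tip.label)
  if (any(bad))
    stop("leaf labels may not contain Newick metacharacters: ",
         paste(unique(tree$tip.label[bad]), collapse = ", "), call. = FALSE)
  if (ntip == 1L) return(invisible(tree))
  deg <- tabulate(tree$edge[, 1L], nbins = ntip + tree$Nnode)
  internal <- deg[(ntip + 1L):(ntip + tree$Nnode)]
  if (any(internal != 2L))
    stop("non-binary node: node with ",
         internal[which(internal != 2L)[1L]],
         " children (only rooted binary MUL trees are supported)",
         call. = FALSE)
  invisible(tree)
}

#' Parse a Newick string into a MUL tree
#'
#' Reads a rooted Newick string in which leaf labels need not be unique.
#' Branch lengths and internal node labels are accepted and discarded.
#' Malformed parentheses and empty leaf labels are reported with the
#' character offset at which they were detected; non-binary nodes are
#' rejected.
#'
#' @param text A single Newick string terminated by `;`.
#' @return A [multree][as_multree] object.
#' @examples
#' parse_newick("((a,b),c);")
#' dup_count(parse_newick("((a,b),(a,c));"))
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string", call. = FALSE)
  scan_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree))
    stop("malformed Newick string", call. = FALSE)
  as_multree(tree)
}

# Cheap pre-scan so that syntax errors carry a character offset; anything
# that passes is handed to ape::read.tree.
scan_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  prev <- ""
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at character ", i, call. = FALSE)
      if (prev %in% c("(", ","))
        stop("empty leaf label at character ", i, call. = FALSE)
    }
    if (ch == "," && prev %in% c("(", ",", ""))
      stop("empty leaf label at character ", i, call. = FALSE)
    if (!(ch %in% c(" ", "\t", "\n"))) prev <- ch
  }
  if (depth != 0L)
    stop("unbalanced '(' (", depth, " unclosed) at character ",
         length(chars), call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("Newick string must end with ';'", call. = FALSE)
  invisible(TRUE)
}

#' Write a MUL tree as a Newick string
#'
#' The writer emits topology only (no branch lengths, no internal labels).
#' `parse_newick(write_newick(t))` recovers `t` up to child order.
#'
#' @param tree A [multree][as_multree] (or anything `as_multree()` accepts).
#' @param file Optional path; if supplied the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  tree <- as_multree(tree)
  kids <- children_map(tree)
  ntip <- length(tree$tip.label)
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    paste0("(", paste(vapply(kids[[v]], rec, character(1)), collapse = ","), ")")
  }
  out <- paste0(rec(root_node(tree)), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' @export
print.multree <- function(x, ...) {
  cat("MUL tree: ", n_leaves(x), " leaves, ",
      length(leaf_labels(x)), " distinct labels, dup = ", dup_count(x),
      "\n  ", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Leaf counts and label sets of a MUL tree
#'
#' `n_leaves()` is the number of leaves n(T); `leaf_labels()` is the set of
#' distinct labels M(T); `dup_count()` is the number of leaf duplications
#' dup(T) = n(T) - |M(T)|, i.e. the total over labels of (occurrences - 1).
#'
#' @inheritParams write_newick
#' @return An integer (`n_leaves`, `dup_count`) or character vector of
#'   distinct labels in sorted order (`leaf_labels`).
#' @examples
#' dup_count(parse_newick("((a,b),(b,a));")) # 2
#' @export
dup_count <- function(tree) {
  tree <- as_multree(tree)
  length(tree$tip.label) - length(unique(tree$tip.label))
}

#' @rdname dup_count
#' @export
n_leaves <- function(tree) length(as_multree(tree)$tip.label)

#' @rdname dup_count
#' @export
leaf_labels <- function(tree) sort(unique(as_multree(tree)$tip.label))

#' Canonical form and isomorphism of MUL trees
#'
#' Child order in a MUL tree is non-semantic.  `canonical_form()` returns a
#' Newick-like string that is invariant under any reordering of children
#' (children are sorted by their recursive canonical string), so two MUL
#' trees are equal as rooted leaf-labeled trees exactly when their canonical
#' forms coincide, which is what `is_isomorphic()` tests.
#'
#' @inheritParams write_newick
#' @param t1,t2 MUL trees (or anything `as_multree()` accepts).
#' @return `canonical_form()`: a string; `is_isomorphic()`: a logical.
#' @examples
#' is_isomorphic("((a,b),c);", "(c,(b,a));") # TRUE
#' is_isomorphic("((a,b),c);", "(a,(b,c));") # FALSE
#' @export
canonical_form <- function(tree) {
  tree <- as_multree(tree)
  kids <- children_map(tree)
  ntip <- length(tree$tip.label)
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    paste0("(", paste(sort(vapply(kids[[v]], rec, character(1))),
                      collapse = ","), ")")
  }
  paste0(rec(root_node(tree)), ";")
}

#' @rdname canonical_form
#' @export
is_isomorphic <- function(t1, t2) {
  identical(canonical_form(t1), canonical_form(t2))
}

## ---- internal topology helpers -------------------------------------------

root_node <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip == 1L && is.null(tree$edge)) return(1L)
  ntip + 1L
}

children_map <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  kids
}

# Depth (edges from root) of every node; only depth *comparisons* are used.
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  depth <- integer(nn)
  edge <- tree$edge
  # edges in ape are listed parent-before-child under cladewise order; a
  # simple sweep with re-iteration is robust to any order at these sizes
  repeat {
    new <- depth[edge[, 1L]] + 1L
    if (all(new == depth[edge[, 2L]])) break
    depth[edge[, 2L]] <- new
  }
  depth
}

# Matrix D[i, j] = depth of lca(leaf i, leaf j); diagonal unused.  Built by
# crossing the two child tip sets of each internal node (binary trees only).
lca_depth_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  D <- matrix(0L, ntip, ntip)
  if (ntip < 2L) return(D)
  kids <- children_map(tree)
  depth <- node_depths(tree)
  tipsets <- vector("list", ntip + tree$Nnode)
  rec <- function(v) {
    if (v <= ntip) {
      tipsets[[v]] <<- v
      return(v)
    }
    below <- integer(0)
    for (w in kids[[v]]) below <- c(below, rec(w))
    ch <- kids[[v]]
    if (length(ch) == 2L) {
      A <- tipsets[[ch[1L]]]
      B <- tipsets[[ch[2L]]]
      D[A, B] <<- depth[v]
      D[B, A] <<- depth[v]
    }
    tipsets[[v]] <<- below
    below
  }
  rec(root_node(tree))
  D
}
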