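test_that("the auxiliary graph has one edge class per cherry pair", {
  g <- aux_graph(triplets(c("a", "c"), c("b", "d"), c("c", "e")),
                 letters[1:5])
  expect_equal(igraph::vcount(g), 5L)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::components(g)$no, 3L)

  g0 <- aux_graph(triplets(character(), character(), character()),
                  c("a", "b", "c"))
  expect_equal(igraph::ecount(g0), 0L)
  expect_equal(igraph::components(g0)$no, 3L)

  gp <- aux_graph(triplets(c("a", "b"), c("b", "c"), c("c", "a")),
                  c("a", "b", "c"))
  expect_equal(igraph::components(gp)$no, 1L)

  expect_error(aux_graph(triplets("a", "b", "z"), c("a", "b")), "outside")
})

test_that("greedy enumeration finds minimum-size minimal separators", {
  path <- igraph::graph_from_literal(a - b - c)
  expect_equal(min_separators(path), list("b"))

  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- letters[1:4]
  expect_equal(min_separators(ring), list(c("a", "c"), c("b", "d")))

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(min_separators(k4), list())

  expect_error(min_separators(igraph::graph_from_literal(a - b, c - d)),
               "connected")
})

test_that("every reported separator is a genuine minimal separator", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    g <- igraph::sample_gnp(n, 0.45)
    igraph::V(g)$name <- letters[seq_len(n)]
    if (!igraph::is_connected(g)) next
    seps <- min_separators(g)
    ref <- igraph::min_separators(g)  # exact minimum-size enumeration
    if (length(seps) == 0L) {
      expect_equal(length(ref), 0L)
      next
    }
    ref_keys <- sort(vapply(ref, function(s)
      paste(sort(igraph::as_ids(s)), collapse = ","), character(1)))
    for (S in seps) {
      expect_true(igraph::is_min_separator(g, S))
      expect_true(paste(S, collapse = ",") %in% ref_keys)
    }
    # the greedy family attains the true minimum size
    expect_equal(length(seps[[1L]]), length(igraph::as_ids(ref[[1L]])))
  }
})

test_that("components are grouped into two deterministic balanced sides", {
  p <- partition_components(list(c("a", "b"), c("c", "d"), "e"))
  expect_setequal(c(p$X1, p$X2), letters[1:5])
  expect_equal(sort(unname(lengths(p))), c(2L, 3L))
  expect_true(p$X1[1L] < p$X2[1L])

  p2 <- partition_components(list("x", "a"))
  expect_equal(p2, list(X1 = "a", X2 = "x"))
  # repeated calls are identical (pure function, lexicographic ties)
  expect_identical(p, partition_components(list("e", c("c", "d"), c("a", "b"))))
  expect_error(partition_components(list("a")), "two components")
})

test_that("separator scores follow the two-term weighting", {
  labs <- letters[1:6]
  tt <- triplets(c("a", "a", "b", "c", "d", "e", "b"),
                 c("b", "c", "c", "d", "e", "f", "f"),
                 c("c", "e", "d", "b", "f", "a", "a"))
  # singleton separator: no triplet fits inside, only the balance term
  sides <- list(X1 = c("a", "b"), X2 = c("d", "e", "f"))
  expect_equal(score_separator("c", tt, labs, sides), abs(3 - 4) / 6)
  # balanced splits score lower than unbalanced ones
  s24 <- score_separator("q", triplets(character(), character(), character()),
                         letters[1:5], list(X1 = "a", X2 = c("b", "c", "d")))
  s33 <- score_separator("q", triplets(character(), character(), character()),
                         letters[1:5], list(X1 = c("a", "b"), X2 = c("c", "d")))
  expect_lt(s33, s24)
  # triplet term: alpha * |t(S)| / |t|, frozen on a hand-built case
  tt2 <- triplets(c("a", "a", "d"), c("b", "c", "e"), c("c", "d", "f"))
  w <- score_separator(c("a", "b", "c"), tt2, letters[1:6],
                       list(X1 = c("d", "e"), X2 = "f"))
  expect_equal(w, 2 * 1 / 3 + abs(5 - 4) / 6)
})

test_that("mtrt reproduces hand-worked micro instances", {
  expect_equal(canonical_form(mtrt(triplets("a", "b", "c"))),
               "((a,b),c);")
  # conflicting pair forces one duplication through the separator {b}
  tt <- triplets(c("a", "b"), c("b", "c"), c("c", "a"))
  out <- mtrt(tt)
  expect_equal(canonical_form(out), "((a,b),(b,c));")
  expect_equal(dup_count(out), 1L)
  expect_true(all(is_consistent(out, tt)))
})

test_that("mtrt handles degenerate label sets", {
  empty <- triplets(character(), character(), character())
  expect_equal(n_leaves(mtrt(empty, "a")), 1L)
  expect_equal(canonical_form(mtrt(empty, c("b", "a"))), "(a,b);")
  expect_equal(canonical_form(mtrt(empty, c("c", "a", "b"))), "((a,b),c);")
  expect_error(mtrt(triplets("a", "b", "c"), c("a", "b")), "outside")
})

test_that("mtrt reduces to BUILD on dense encodings of ordinary trees", {
  set.seed(31)
  for (n in 4:12) {
    src <- as_multree(ape::rtree(n, br = NULL))
    out <- mtrt(triplet_set(src), leaf_labels(src))
    expect_equal(dup_count(out), 0L)
    expect_true(is_isomorphic(out, src))
  }
})

test_that("mtrt output is deterministic and always consistent", {
  set.seed(41)
  for (i in 1:60) {
    labs <- letters[seq_len(sample(4:7, 1))]
    tt <- rand_triplet_set(labs, sample(1:8, 1))
    out1 <- mtrt(tt, labs)
    out2 <- mtrt(tt, labs)
    expect_identical(canonical_form(out1), canonical_form(out2))
    expect_true(all(is_consistent(out1, tt)))
    expect_setequal(leaf_labels(out1), labs)
  }
})
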