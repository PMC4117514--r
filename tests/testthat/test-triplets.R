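test_that("triplet tibbles canonicalize the cherry pair", {
  tb <- triplets(c("b", "c"), c("a", "b"), c("c", "a"))
  expect_equal(tb$x, c("a", "b"))
  expect_equal(tb$y, c("b", "c"))
  expect_equal(tb$z, c("c", "a"))
  expect_error(triplets("a", "a", "b"), "distinct")
})

test_that("triplet encodings of small trees are correct", {
  ts <- triplet_set("((a,b),(c,d));")
  expect_equal(nrow(ts), 4L)
  expect_true(all(is_consistent("((a,b),(c,d));",
                                triplets(c("a", "a", "c", "c"),
                                         c("b", "b", "d", "d"),
                                         c("c", "d", "a", "b")))))
  expect_false(is_consistent("((a,b),c);", triplets("a", "c", "b")))

  ts2 <- triplet_set("((a,b),(a,c));")
  expect_equal(paste(ts2$x, ts2$y, ts2$z), c("a b c", "a c b"))
})

test_that("multiplicity counts embedded occurrences", {
  # two same-side (a,b) cherries each embed with the outgroup c
  expect_equal(triplet_multiplicity("((a,b),((a,b),c));", "a", "b", "c"), 2L)
  # absent labels give multiplicity 0
  expect_equal(triplet_multiplicity("((a,b),c);", "a", "b", "d"), 0L)
  # cross-subtree 'a' pairs with 'b' even when same-side pairs fail
  expect_true(is_consistent("((a,c),(b,a));", triplets("a", "b", "c")))
})

test_that("multiplicity matches the brute-force occurrence-triple count", {
  set.seed(5)
  for (i in 1:10) {
    tr <- rand_multree(sample(6:10, 1), sample(3:5, 1), seed = 400 + i)
    enc <- triplet_multiset(tr)
    expect_gt(nrow(enc), 0L)
    pick <- sample(nrow(enc), min(6L, nrow(enc)))
    for (r in pick)
      expect_equal(enc$n[r],
                   brute_multiplicity(tr, enc$x[r], enc$y[r], enc$z[r]))
    # and a few random label triples not necessarily in the encoding
    labs <- leaf_labels(tr)
    if (length(labs) >= 3L) {
      q <- sample(labs, 3L)
      expect_equal(triplet_multiplicity(tr, q[1], q[2], q[3]),
                   brute_multiplicity(tr, q[1], q[2], q[3]))
    }
  }
})

test_that("singly-labeled trees have C(n,3) triplets, all multiplicity 1", {
  set.seed(2)
  for (n in c(5, 8, 10)) {
    tr <- as_multree(ape::rtree(n, br = NULL))
    enc <- triplet_multiset(tr)
    expect_equal(nrow(enc), choose(n, 3))
    expect_true(all(enc$n == 1L))
  }
})

test_that("induced triplet sets restrict to a label subset", {
  s <- triplets(c("a", "c"), c("b", "d"), c("c", "e"))
  expect_equal(nrow(induce_triplets(s, c("a", "b", "c"))), 1L)
  expect_equal(induce_triplets(s, c("a", "b", "c", "d", "e")), s)
  expect_equal(nrow(induce_triplets(s, c("a", "b", "d"))), 0L)
})

test_that("multiset symmetric difference takes absolute count differences", {
  m1 <- triplets(c("a", "a"), c("b", "c"), c("c", "b"), n = c(2L, 1L),
                 multiset = TRUE)
  m2 <- triplets(c("a", "a"), c("b", "d"), c("c", "b"), n = c(1L, 1L),
                 multiset = TRUE)
  sd <- multiset_symdiff(m1, m2)
  expect_equal(multiset_size(sd), 3L)
  expect_equal(multiset_size(multiset_symdiff(m1, m1)), 0L)
  empty <- triplets(character(), character(), character(), multiset = TRUE)
  expect_equal(multiset_size(multiset_symdiff(m1, empty)), 3L)
})

test_that("set distance halves the symmetric difference", {
  expect_equal(triplet_distance("((a,b),c);", "((a,b),c);"), 0)
  expect_equal(triplet_distance("((a,b),c);", "(a,(b,c));"), 1)
  # structural halving: distance always equals |symdiff| / 2
  set.seed(9)
  for (i in 1:8) {
    a <- rand_multree(7, 3, seed = 500 + i)
    b <- rand_multree(8, 3, seed = 600 + i)
    sa <- triplet_set(a)
    sb <- triplet_set(b)
    one_sided <- nrow(dplyr::anti_join(sa, sb, by = c("x", "y", "z"))) +
      nrow(dplyr::anti_join(sb, sa, by = c("x", "y", "z")))
    expect_equal(triplet_distance(a, b), one_sided / 2)
    expect_equal(triplet_distance(a, b, multiset = TRUE),
                 multiset_size(multiset_symdiff(a, b)) / 2)
  }
})

test_that("multiset distance separates equal-set pairs with unequal counts", {
  # frozen from an exhaustive search of 5-leaf MUL trees: same triplet set,
  # one triplet occurring once vs twice
  p1 <- "((((a,b),c),b),a);"
  p2 <- "((((a,b),c),a),b);"
  expect_equal(triplet_distance(p1, p2), 0)
  expect_gt(triplet_distance(p1, p2, multiset = TRUE), 0)
})

test_that("multiset distance dominates set distance and is a pseudometric", {
  set.seed(13)
  trees <- lapply(1:6, function(i) rand_multree(7, 4, seed = 700 + i))
  for (i in 1:6) {
    expect_equal(triplet_distance(trees[[i]], trees[[i]], multiset = TRUE), 0)
    for (j in 1:6) {
      dij <- triplet_distance(trees[[i]], trees[[j]], multiset = TRUE)
      expect_gte(dij, triplet_distance(trees[[i]], trees[[j]]))
      expect_equal(dij, triplet_distance(trees[[j]], trees[[i]],
                                         multiset = TRUE))
      for (k in 1:6)
        expect_lte(dij,
                   triplet_distance(trees[[i]], trees[[k]], multiset = TRUE) +
                     triplet_distance(trees[[k]], trees[[j]], multiset = TRUE))
    }
  }
})

test_that("distances require matching taxa sets", {
  expect_error(triplet_distance("((a,b),c);", "((a,b),d);"), "taxa sets")
  expect_equal(
    triplet_distance("((a,b),c);", "((a,b),d);", check_taxa = FALSE), 1)
})

test_that("triplet TSV round-trips with comments and multiplicities", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line", "b\ta\tc\t2", "a\tc\tb"), f)
  m <- read_triplets(f, multiset = TRUE)
  expect_equal(m$x, c("a", "a"))
  expect_equal(m$y, c("b", "c"))
  expect_equal(m$n, c(2L, 1L))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_triplets(m, f2)
  expect_equal(read_triplets(f2, multiset = TRUE), m)
  # set reading drops multiplicities
  expect_false("n" %in% names(read_triplets(f)))
})
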