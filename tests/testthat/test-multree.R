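test_that("Newick parsing handles repeated labels and discards lengths", {
  t1 <- parse_newick("((a,b),c);")
  expect_s3_class(t1, "multree")
  expect_equal(n_leaves(t1), 3L)
  expect_equal(leaf_labels(t1), c("a", "b", "c"))

  t2 <- parse_newick("((a,b),(a,c));")
  expect_equal(n_leaves(t2), 4L)
  expect_equal(leaf_labels(t2), c("a", "b", "c"))

  # branch lengths and internal labels are accepted and ignored
  t3 <- parse_newick("((a:1.2,b:0.3)n1:4,c:9)root;")
  expect_true(is_isomorphic(t3, t1))
  expect_null(t3$edge.length)
})

test_that("malformed Newick is rejected with a character offset", {
  expect_error(parse_newick("((a,b),c;"), "unbalanced '\\(")
  expect_error(parse_newick("(a,b)),c;"), "unbalanced '\\)' at character 6")
  expect_error(parse_newick("((a,),b);"), "empty leaf label at character 5")
  expect_error(parse_newick("((,a),b);"), "empty leaf label at character 3")
  expect_error(parse_newick("((a,b),c)"), "end with ';'")
})

test_that("non-binary trees are rejected", {
  expect_error(parse_newick("((a,b,c));"), "non-binary")
  expect_error(parse_newick("(a,b,c,d);"), "non-binary")
})

test_that("duplication count is leaves minus distinct labels", {
  expect_equal(dup_count(parse_newick("((a,b),c);")), 0L)
  expect_equal(dup_count(parse_newick("((a,b),(a,c));")), 1L)
  expect_equal(dup_count(parse_newick("((a,b),(b,a));")), 2L)
})

test_that("dup count is additive when joining trees at a new root", {
  set.seed(11)
  for (i in 1:5) {
    a <- rand_multree(sample(4:8, 1), sample(2:4, 1), seed = 100 + i)
    b <- rand_multree(sample(4:8, 1), sample(2:4, 1), seed = 200 + i)
    joined <- parse_newick(paste0(
      "(", sub(";$", "", write_newick(a)), ",",
      sub(";$", "", write_newick(b)), ");"))
    expect_equal(dup_count(joined),
                 n_leaves(a) + n_leaves(b) -
                   length(union(leaf_labels(a), leaf_labels(b))))
  }
})

test_that("canonical form is invariant under child order", {
  expect_true(is_isomorphic("((a,b),c);", "(c,(b,a));"))
  expect_false(is_isomorphic("((a,b),c);", "(a,(b,c));"))
  expect_equal(canonical_form("(c,(b,a));"), "((a,b),c);")
})

test_that("parse/write round-trips simulated MUL trees", {
  for (i in 1:8) {
    tr <- rand_multree(sample(5:15, 1), sample(2:6, 1), seed = 300 + i)
    expect_equal(canonical_form(parse_newick(write_newick(tr))),
                 canonical_form(tr))
  }
})

test_that("a MUL tree is not determined by its triplet multiset", {
  # exhaustive search over all MUL trees on the 5-leaf multiset {a,a,b,b,c}
  # yields a non-isomorphic pair with identical triplet encoding multisets
  trees <- enumerate_multrees(c("a", "a", "b", "b", "c"))
  sig <- vapply(trees, function(t) {
    m <- triplet_multiset(t)
    paste(m$x, m$y, m$z, m$n, collapse = ";")
  }, character(1))
  dup_sig <- sig[duplicated(sig)]
  expect_gt(length(dup_sig), 0L)
  grp <- which(sig == dup_sig[1L])
  expect_false(is_isomorphic(trees[[grp[1L]]], trees[[grp[2L]]]))
  expect_equal(triplet_distance(trees[[grp[1L]]], trees[[grp[2L]]],
                                multiset = TRUE), 0)

  # the frozen pair found by this search
  p1 <- "((((a,a),b),b),c);"
  p2 <- "((((a,b),a),b),c);"
  expect_false(is_isomorphic(p1, p2))
  expect_equal(triplet_distance(p1, p2, multiset = TRUE), 0)
})
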