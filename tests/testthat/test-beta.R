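test_that("unweighted UniFrac matches hand-enumerated branch sets", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  s1 <- c(A = 1, B = 1, C = 0, D = 0)
  s2 <- c(A = 1, B = 0, C = 1, D = 0)
  # unique: B (1), C (1), CD stem (1); observed: + A (1), AB stem (1) = 5
  expect_equal(unweighted_unifrac(s1, s2, tree), 3 / 5)
  expect_equal(unweighted_unifrac(s1, s1, tree), 0)
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(unweighted_unifrac(c(A = 3), c(B = 9), star), 1)
  # presence-only: magnitudes do not matter
  expect_equal(unweighted_unifrac(s1 * 7, s2 * 100, tree),
               unweighted_unifrac(s1, s2, tree))
  expect_error(unweighted_unifrac(c(A = 0), c(B = 0), tree), "empty")
})

test_that("weighted UniFrac matches hand cases and the enumeration oracle", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(weighted_unifrac(c(A = 5), c(B = 2), star), 1)
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  s1 <- c(A = 4, B = 4, C = 0, D = 0)
  expect_equal(weighted_unifrac(s1, s1 * 3, tree), 0)  # same relative abundances
  s2 <- c(A = 2, B = 0, C = 4, D = 2)
  expect_equal(weighted_unifrac(s1, s2, tree),
               oracle_weighted_unifrac(s1, s2, tree), tolerance = 1e-12)
  expect_equal(weighted_unifrac(s1, s2, tree, normalized = FALSE),
               oracle_weighted_unifrac(s1, s2, tree, normalized = FALSE),
               tolerance = 1e-12)
  expect_error(weighted_unifrac(c(A = 0), s2, tree), "positive")
})

test_that("UniFrac metrics are symmetric, bounded, and zero on identity", {
  for (i in 1:10) {
    tree <- random_rooted_tree(8, seed = 300 + i)
    set.seed(400 + i)
    a <- setNames(rpois(8, 2), tree$tip.label)
    b <- setNames(rpois(8, 2), tree$tip.label)
    if (sum(a) == 0) a[1] <- 1
    if (sum(b) == 0) b[2] <- 1
    u1 <- unweighted_unifrac(a, b, tree)
    expect_equal(u1, unweighted_unifrac(b, a, tree))
    expect_true(u1 >= 0 && u1 <= 1)
    w1 <- weighted_unifrac(a, b, tree)
    expect_equal(w1, weighted_unifrac(b, a, tree))
    expect_true(w1 >= 0 && w1 <= 1)
  }
})

test_that("collapsing a zero-length branch changes neither metric", {
  tree <- ape::read.tree(text = "(((A:1,B:1):0,C:2):1,D:3);")
  collapsed <- ape::di2multi(tree, tol = 1e-12)
  a <- c(A = 3, B = 1, C = 2, D = 0)
  b <- c(A = 0, B = 2, C = 1, D = 5)
  expect_equal(unweighted_unifrac(a, b, tree), unweighted_unifrac(a, b, collapsed))
  expect_equal(weighted_unifrac(a, b, tree), weighted_unifrac(a, b, collapsed))
})

test_that("both UniFrac forms agree with independent oracles on random fixtures", {
  skip_if_not_installed("phyloseq")
  for (i in 1:20) {
    n <- sample(5:14, 1)
    tree <- random_rooted_tree(n, seed = 500 + i)
    set.seed(600 + i)
    m <- matrix(rpois(2 * n, 3), 2, n,
                dimnames = list(c("s1", "s2"), tree$tip.label))
    if (sum(m[1, ]) == 0) m[1, 1] <- 1
    if (sum(m[2, ]) == 0) m[2, 2] <- 1
    u <- unweighted_unifrac(m[1, ], m[2, ], tree)
    w <- weighted_unifrac(m[1, ], m[2, ], tree)
    # brute-force enumeration oracle
    expect_equal(u, oracle_unweighted_unifrac(m[1, ], m[2, ], tree),
                 tolerance = 1e-9)
    expect_equal(w, oracle_weighted_unifrac(m[1, ], m[2, ], tree),
                 tolerance = 1e-9)
    # established reference implementation
    ps <- phyloseq::phyloseq(phyloseq::otu_table(m, taxa_are_rows = FALSE),
                             phyloseq::phy_tree(tree))
    expect_equal(u, as.numeric(phyloseq::UniFrac(ps, weighted = FALSE)),
                 tolerance = 1e-9)
    expect_equal(w, as.numeric(phyloseq::UniFrac(ps, weighted = TRUE,
                                                 normalized = TRUE)),
                 tolerance = 1e-9)
  }
})

test_that("unifrac() returns tidy pairs consistent with the pairwise functions", {
  tree <- random_rooted_tree(10, seed = 77)
  tbl <- random_table(4, 10, seed = 78)
  names(tbl)[-1] <- tree$tip.label
  pairs <- unifrac(tbl, tree, weighted = TRUE)
  expect_equal(nrow(pairs), choose(4, 2))
  m <- otu_matrix(tbl)
  for (k in seq_len(nrow(pairs))) {
    expect_equal(pairs$distance[k],
                 weighted_unifrac(m[pairs$sample_a[k], ], m[pairs$sample_b[k], ], tree))
  }
  expect_equal(pairs$similarity, 1 - pairs$distance)
  dm <- distance_matrix(pairs)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
})

test_that("set overlap measures follow set arithmetic", {
  expect_equal(shared_otu_fraction(letters[1:10], letters[1:10]), 1)
  expect_equal(shared_otu_fraction(letters[1:10], LETTERS[1:10]), 0)
  expect_equal(shared_otu_fraction(letters[1:10], c(letters[1:4], "zz")), 0.4)
  expect_error(shared_otu_fraction(character(0), "a"), "nonempty")
  expect_equal(jaccard_index(letters[1:4], letters[3:6]), 2 / 6)
})
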