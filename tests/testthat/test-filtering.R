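test_that("rare-OTU filter keeps exactly the OTUs with dataset-wide total >= 3", {
  tbl <- as_otu_tbl(matrix(
    c(1L, 0L, 1L,
      0L, 2L, 2L),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("g1", "g2"), c("a", "b", "c"))
  ))
  out <- remove_rare_otus(tbl)  # totals a=1 (singleton), b=2 (doubleton), c=3
  expect_identical(otu_ids(out), "c")
  expect_identical(out$sample_id, tbl$sample_id)
  expect_identical(out$c, tbl$c)
})

test_that("rare-OTU filter matches a brute-force total-count filter and is idempotent", {
  tbl <- random_table(8, 100, seed = 3, lambda = 0.35)
  for (min_total in c(1, 3, 7)) {
    got <- remove_rare_otus(tbl, min_total = min_total)
    m <- otu_matrix(tbl)
    keep <- colnames(m)[vapply(colnames(m), function(j) sum(m[, j]) >= min_total,
                               logical(1))]
    expect_identical(otu_ids(got), keep)
    expect_identical(remove_rare_otus(got, min_total = min_total), got)
  }
  # identity on a table with no all-zero OTU columns
  nz <- remove_rare_otus(tbl, min_total = 1)
  expect_identical(remove_rare_otus(nz, min_total = 1), nz)
  expect_error(remove_rare_otus(tbl, min_total = 0), "min_total")
})

test_that("subsampling hits the requested depth exactly and is seeded", {
  tbl <- random_table(5, 30, seed = 21)
  sub <- subsample_counts(tbl, depth = 50, seed = 4)
  expect_true(all(sample_depths(sub)$depth == 50))
  expect_identical(sub, subsample_counts(tbl, depth = 50, seed = 4))
  expect_false(identical(sub, subsample_counts(tbl, depth = 50, seed = 5)))
  # depth equal to every sample's own depth leaves counts unchanged
  eq <- as_otu_tbl(matrix(c(3L, 7L, 2L, 8L), 2, 2, byrow = TRUE,
                          dimnames = list(c("s1", "s2"), c("a", "b"))))
  expect_identical(otu_matrix(subsample_counts(eq, depth = 10, seed = 1)),
                   otu_matrix(eq))
  expect_error(subsample_counts(tbl, depth = 10000), "s1")
})

test_that("subsampled counts follow the hypergeometric expectation", {
  counts <- c(a = 500L, b = 300L, c = 150L, d = 50L)
  tbl <- as_otu_tbl(matrix(counts, 1, dimnames = list("s1", names(counts))))
  depth <- 100
  n_rep <- 2000
  sums <- numeric(length(counts))
  set.seed(99)
  for (r in seq_len(n_rep)) {
    s <- subsample_counts(tbl, depth = depth, keep_zero_otus = TRUE)
    sums <- sums + otu_matrix(s)[1, names(counts)]
  }
  means <- sums / n_rep
  expected <- depth * counts / sum(counts)
  # hypergeometric sd of a single draw / sqrt(n_rep), 4 sigma band
  sdev <- sqrt(depth * (counts / sum(counts)) * (1 - counts / sum(counts)) *
                 (sum(counts) - depth) / (sum(counts) - 1))
  expect_true(all(abs(means - expected) < 4 * sdev / sqrt(n_rep) + 1e-9))
})

test_that("relative-abundance thresholds zero with strict inequality", {
  tbl <- as_otu_tbl(matrix(c(1L, 999L), 1, 2,
                           dimnames = list("s1", c("rare", "dom"))))
  # 1/1000 == 1 per mill exactly: not > threshold, so zeroed
  out <- abundance_threshold(tbl, 1)
  expect_identical(otu_ids(out), "dom")
  # threshold 0 keeps everything nonzero
  expect_identical(abundance_threshold(tbl, 0), tbl)
})

test_that("0.1 per-mill threshold at depth 44901 zeroes counts of 4 and below", {
  counts <- c(lo1 = 1L, lo4 = 4L, hi5 = 5L, big = 44891L)
  tbl <- as_otu_tbl(matrix(counts, 1, dimnames = list("s1", names(counts))))
  out <- abundance_threshold(tbl, 0.1)
  # 4/44901 = 0.089 per mill (<= 0.1, zeroed); 5/44901 = 0.111 per mill (kept)
  expect_identical(otu_ids(out), c("hi5", "big"))
})

test_that("rank aggregation sums families and conserves per-sample depth", {
  tbl <- as_otu_tbl(matrix(
    c(3L, 4L, 5L, 6L, 7L,
      1L, 0L, 2L, 0L, 9L),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("g1", "g2"), paste0("otu", 1:5))
  ))
  tax <- tibble::tibble(
    otu_id = paste0("otu", 1:5),
    lineage = c(rep("Bacteria;P;C;O;FamX;G", 3), rep("Bacteria;P;C;O;FamY;G", 2))
  )
  agg <- aggregate_by_rank(tbl, tax, rank = "family")
  expect_setequal(otu_ids(agg), c("FamX", "FamY"))
  expect_identical(agg$FamX, c(3L + 4L + 5L, 1L + 0L + 2L))
  expect_identical(agg$FamY, c(6L + 7L, 0L + 9L))
  expect_identical(sample_depths(agg)$depth, sample_depths(tbl)$depth)

  # single shared family collapses to the row sums
  tax1 <- tibble::tibble(otu_id = paste0("otu", 1:5),
                         lineage = rep("Bacteria;P;C;O;Fam;G", 5))
  agg1 <- aggregate_by_rank(tbl, tax1)
  expect_identical(agg1$Fam, sample_depths(tbl)$depth)
})

test_that("missing taxonomy buckets to unclassified variants", {
  tbl <- as_otu_tbl(matrix(c(2L, 3L, 4L), 1, 3,
                           dimnames = list("s1", c("known", "shallow", "absent"))))
  tax <- tibble::tibble(
    otu_id = c("known", "shallow"),
    lineage = c("Bacteria;P;C;O;Fam;G", "Bacteria;P2")
  )
  expect_warning(agg <- aggregate_by_rank(tbl, tax, rank = "family"),
                 "absent from the taxonomy")
  expect_setequal(otu_ids(agg), c("Fam", "unclassified_P2", "unclassified"))
  expect_identical(sum(otu_matrix(agg)), 9L)
})
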