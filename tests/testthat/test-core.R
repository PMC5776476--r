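test_that("core extraction follows strict prevalence", {
  m <- matrix(c(
    5L, 2L, 1L,
    5L, 2L, 0L,   # otuC missing from g2
    5L, 2L, 3L
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("g1", "g2", "g3"), c("otuA", "otuB", "otuC")))
  # unequal depths warn
  expect_warning(find_core(as_otu_tbl(m)), "unequal")
  m2 <- matrix(c(
    5L, 2L, 1L,
    6L, 2L, 0L,
    3L, 2L, 3L
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("g1", "g2", "g3"), c("otuA", "otuB", "otuC")))
  core <- find_core(as_otu_tbl(m2))
  expect_setequal(core$core_otu_ids, c("otuA", "otuB"))
  expect_equal(core$core_fraction_of_otus, 2 / 3)
  expect_equal(tidy(core)$core_read_share, c(7 / 8, 8 / 8, 5 / 8))
})

test_that("identical samples make every OTU core with read share one", {
  m <- matrix(rep(c(3L, 2L, 5L), 4), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
  core <- find_core(as_otu_tbl(m))
  expect_setequal(core$core_otu_ids, c("a", "b", "c"))
  expect_true(all(tidy(core)$core_read_share == 1))
})

test_that("lowering the prevalence threshold never shrinks the core", {
  tbl <- subsample_counts(random_table(6, 80, seed = 55, lambda = 1), seed = 1)
  cores <- lapply(c(1, 0.8, 0.5, 0.2), function(p) {
    find_core(tbl, min_prevalence = p)$core_otu_ids
  })
  for (i in seq_len(length(cores) - 1)) {
    expect_true(all(cores[[i]] %in% cores[[i + 1]]))
  }
})

test_that("planted synthetic core is recovered with its configured read share", {
  model <- community_model(n_grains = 8, n_bulk = 0, n_core_otus = 30,
                           n_rare_otus = 200, n_bulk_only_otus = 0,
                           core_read_fraction = 0.6, depth_range = c(8000, 12000),
                           seed = 17)
  sim <- simulate_community(model)
  sub <- subsample_counts(sim$table, seed = 18)
  core <- find_core(sub, grain_ids = grep("^grain", sub$sample_id, value = TRUE))
  planted <- grep("^core_otu", otu_ids(sim$table), value = TRUE)
  expect_setequal(core$core_otu_ids, planted)
  expect_lt(abs(mean(tidy(core)$core_read_share) - 0.6), 0.1)
})

test_that("family breakdown reproduces hand-computed shares and sums to one", {
  m <- matrix(c(
    4L, 2L, 3L, 1L,
    2L, 4L, 3L, 1L
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("g1", "g2"), c("x1", "x2", "y1", "rare")))
  # core = x1, x2, y1 (rare absent from... make rare missing in g2)
  m["g2", "rare"] <- 0L
  m["g2", "x1"] <- 3L  # keep depths equal at 10
  tax <- tibble::tibble(
    otu_id = c("x1", "x2", "y1", "rare"),
    lineage = c("B;P;C;O;FamX;g", "B;P;C;O;FamX;g", "B;P;C;O;FamY;g", "B;P;C;O;FamZ;g")
  )
  tbl <- as_otu_tbl(m)
  core <- find_core(tbl)
  expect_setequal(core$core_otu_ids, c("x1", "x2", "y1"))
  bd <- core_family_breakdown(core, tbl, tax, min_mean_share = 0)
  g1 <- bd[bd$sample_id == "g1", ]
  expect_equal(g1$share[g1$family == "FamX"], 6 / 10)
  expect_equal(g1$share[g1$family == "FamY"], 3 / 10)
  expect_equal(g1$share[g1$family == "non-core"], 1 / 10)
  sums <- tapply(bd$share, bd$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("minor core families are pooled into the other-core bucket", {
  m <- matrix(c(900L, 95L, 5L), 1, 3,
              dimnames = list("g1", c("big", "mid", "tiny")))
  tax <- tibble::tibble(
    otu_id = c("big", "mid", "tiny"),
    lineage = c("B;P;C;O;FamBig;g", "B;P;C;O;FamMid;g", "B;P;C;O;FamTiny;g")
  )
  tbl <- as_otu_tbl(m)
  core <- find_core(tbl)
  bd <- core_family_breakdown(core, tbl, tax, min_mean_share = 0.01)
  expect_true("other core community" %in% bd$family)
  expect_false("FamTiny" %in% bd$family)
  expect_equal(bd$share[bd$family == "other core community"], 5 / 1000)
  # single-family core: one family row equal to the core read share
  tax_one <- tibble::tibble(otu_id = c("big", "mid", "tiny"),
                            lineage = rep("B;P;C;O;OnlyFam;g", 3))
  bd1 <- core_family_breakdown(core, tbl, tax_one, min_mean_share = 0)
  expect_equal(bd1$share[bd1$family == "OnlyFam"],
               tidy(core)$core_read_share)
})
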