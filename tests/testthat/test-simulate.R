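small_model <- function(...) {
  community_model(n_grains = 4, n_bulk = 1, n_core_otus = 20, n_rare_otus = 100,
                  n_bulk_only_otus = 30, depth_range = c(2000, 3000), ...)
}

test_that("community simulation is deterministic under a fixed seed", {
  a <- simulate_community(small_model(seed = 3))
  b <- simulate_community(small_model(seed = 3))
  expect_identical(a$table, b$table)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$taxonomy, b$taxonomy)
  c <- simulate_community(small_model(seed = 4))
  expect_false(identical(a$table, c$table))
})

test_that("a core-only degenerate model puts every OTU in every sample", {
  sim <- simulate_community(community_model(
    n_grains = 3, n_bulk = 1, n_core_otus = 5, n_rare_otus = 0,
    n_bulk_only_otus = 0, rare_occupancy = 1, depth_range = c(500, 500), seed = 1
  ))
  m <- otu_matrix(sim$table)
  expect_true(all(m > 0))
  expect_equal(unname(rowSums(m)), rep(500, 4))
})

test_that("every core OTU is present on every grain and depths are in range", {
  sim <- simulate_community(small_model(seed = 8))
  m <- otu_matrix(sim$table)
  grains <- grep("^grain", rownames(m), value = TRUE)
  core_cols <- grep("^core_otu", colnames(m), value = TRUE)
  expect_true(all(m[grains, core_cols] >= 1))
  d <- rowSums(m)
  expect_true(all(d >= 2000 & d <= 3000))
})

test_that("realized core read share tracks the configured fraction", {
  sim <- simulate_community(community_model(
    n_grains = 17, n_bulk = 0, n_core_otus = 50, n_rare_otus = 400,
    n_bulk_only_otus = 0, core_read_fraction = 0.6,
    depth_range = c(10000, 12000), seed = 7
  ))
  m <- otu_matrix(sim$table)
  core_cols <- grep("^core_otu", colnames(m), value = TRUE)
  share <- rowSums(m[, core_cols]) / rowSums(m)
  expect_true(all(abs(share - 0.6) < 0.1))
})

test_that("rare-OTU occupancy converges to the configured probability", {
  sim <- simulate_community(community_model(
    n_grains = 30, n_bulk = 0, n_core_otus = 5, n_rare_otus = 400,
    n_bulk_only_otus = 0, rare_occupancy = 0.3,
    depth_range = c(5000, 5000), seed = 12
  ))
  m <- otu_matrix(sim$table)
  rare_cols <- grep("^rare_otu", colnames(m), value = TRUE)
  # occupancy of rare OTUs is bounded above by inclusion; detection can miss
  # included low-abundance OTUs, so compare with a generous binomial band
  occ <- mean(colMeans(m[, rare_cols] > 0))
  expect_lt(occ, 0.3 + 3 * sqrt(0.3 * 0.7 / 30))
  expect_gt(occ, 0.1)
})

test_that("the simulated tree covers exactly the table's OTUs", {
  sim <- simulate_community(small_model(seed = 5))
  expect_setequal(sim$tree$tip.label, otu_ids(sim$table))
  expect_true(ape::is.rooted(sim$tree))
  expect_true(all(sim$tree$edge.length > 0))
  expect_setequal(sim$taxonomy$otu_id, otu_ids(sim$table))
})

test_that("model validation rejects impossible configurations", {
  expect_error(community_model(depth_range = c(0, 10)), "depth")
  expect_error(community_model(n_core_otus = 0, n_rare_otus = 0), "n_core_otus")
  expect_error(community_model(core_read_fraction = 1.2), "core_read_fraction")
  expect_error(community_model(rare_occupancy = 0), "rare_occupancy")
  expect_error(spatial_model(exposed_intensity = -1), "non-negative")
  expect_error(spatial_model(window = c(0, 0, 0, 1)), "window")
})

test_that("point patterns are seeded, labelled, and flagged for touching", {
  sm <- spatial_model(window = c(0, 80, 0, 80), seed = 9)
  a <- simulate_point_pattern(sm)
  b <- simulate_point_pattern(sm)
  expect_identical(a$x_um, b$x_um)
  expect_identical(a$patch, b$patch)
  # zero exposed intensity: protected points only
  p <- simulate_point_pattern(spatial_model(window = c(0, 80, 0, 80),
                                            exposed_intensity = 0, seed = 2))
  expect_true(all(p$patch == "protected"))
  # touching flags match a brute-force radius check within class
  m <- as.matrix(dist(cbind(a$x_um, a$y_um)))
  diag(m) <- Inf
  same <- outer(a$patch, a$patch, "==")
  m[!same] <- Inf
  expect_identical(a$touching, unname(apply(m, 1, min) < 1))
})

test_that("a homogeneous Poisson pattern has the right expected count", {
  lam <- 0.09
  pat <- simulate_point_pattern(spatial_model(
    window = c(0, 300, 0, 300), exposed_intensity = 0,
    protected_intensity = lam, protected_patch_fraction = 1,
    cluster_scale = 0, seed = 31
  ))
  n <- nrow(pat)
  mu <- lam * 300^2
  expect_lt(abs(n - mu), 3 * sqrt(mu))
})

test_that("simulated datasets write a complete file set", {
  sim <- simulate_community(small_model(seed = 6))
  dir <- withr::local_tempdir()
  paths <- write_community(sim, dir)
  expect_true(all(file.exists(paths)))
  expect_identical(read_otu_table(paths[["table"]]), sim$table)
  tr <- ape::read.tree(paths[["tree"]])
  expect_setequal(tr$tip.label, otu_ids(sim$table))
  params <- jsonlite::read_json(paths[["params"]])
  expect_equal(params$seed, 6)
})
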