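# Fixture builders shared across test files. Everything is generated in code
# under explicit seeds; no data files.

tiny_table <- function() {
  as_otu_tbl(matrix(
    c(5L, 0L, 2L,
      1L, 3L, 4L),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("g1", "g2"), c("otuA", "otuB", "otuC"))
  ))
}

random_table <- function(n_samples, n_otus, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("otu", seq_len(n_otus))))
  # no all-zero rows
  for (i in which(rowSums(m) == 0)) m[i, 1] <- 1L
  as_otu_tbl(m)
}

random_rooted_tree <- function(n_tips, seed, labels = NULL) {
  set.seed(seed)
  tree <- ape::rtree(n_tips, br = function(k) runif(k, 0.1, 2))
  if (!is.null(labels)) tree$tip.label <- labels
  tree
}

# Independent branch enumeration for UniFrac oracles: for every edge, the set
# of tip labels below it, found by walking each root-to-tip path (no shared
# code with the package's post-order accumulation).
edge_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", nrow(tree$edge))
  for (tip in seq_len(n_tip)) {
    node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      sets[[e]] <- c(sets[[e]], tree$tip.label[tip])
      node <- tree$edge[e, 1]
    }
  }
  sets
}

# Brute-force UniFrac from the edge tip sets.
oracle_unweighted_unifrac <- function(a, b, tree) {
  sets <- edge_tip_sets(tree)
  pres_a <- names(a)[a > 0]
  pres_b <- names(b)[b > 0]
  uniq <- shared <- 0
  for (e in seq_along(sets)) {
    ina <- length(intersect(sets[[e]], pres_a)) > 0
    inb <- length(intersect(sets[[e]], pres_b)) > 0
    if (xor(ina, inb)) uniq <- uniq + tree$edge.length[e]
    if (ina || inb) shared <- shared + tree$edge.length[e]
  }
  uniq / shared
}

oracle_weighted_unifrac <- function(a, b, tree, normalized = TRUE) {
  sets <- edge_tip_sets(tree)
  pa_tot <- sum(a)
  pb_tot <- sum(b)
  num <- den <- 0
  for (e in seq_along(sets)) {
    pa <- sum(a[intersect(sets[[e]], names(a))]) / pa_tot
    pb <- sum(b[intersect(sets[[e]], names(b))]) / pb_tot
    num <- num + tree$edge.length[e] * abs(pa - pb)
    den <- den + tree$edge.length[e] * (pa + pb)
  }
  if (normalized) num / den else num
}

# Brute-force nearest-neighbour distances via the full distance matrix.
oracle_nn <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

# Toy where coverage is fully deterministic: grains are already at the
# common depth (rarefaction to their own depth is the identity), and every
# bulk OTU count exceeds the number of reads ever left out of a bulk
# subsample, so each subsample is guaranteed to contain every bulk OTU.
deterministic_toy <- function() {
  m <- rbind(
    gA = c(o1 = 4L, o2 = 3L, o3 = 3L, o4 = 0L, o5 = 0L, o6 = 0L),
    gB = c(o1 = 5L, o2 = 5L, o3 = 0L, o4 = 0L, o5 = 0L, o6 = 0L),
    gC = c(o1 = 4L, o2 = 0L, o3 = 0L, o4 = 3L, o5 = 3L, o6 = 0L),
    gD = c(o1 = 10L, o2 = 0L, o3 = 0L, o4 = 0L, o5 = 0L, o6 = 0L),
    bk = c(o1 = 3L, o2 = 3L, o3 = 3L, o4 = 3L, o5 = 0L, o6 = 0L)
  )
  as_otu_tbl(m)
}

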