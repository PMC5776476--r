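#' Pairwise UniFrac distances
#'
#' Tree-based community distances between pairs of samples. The unweighted
#' form compares branch presence: a branch counts for a sample if at least one
#' of its descendant leaves has a nonzero count, and the distance is the
#' branch length unique to one sample divided by the branch length observed
#' in at least one. The weighted form compares the fraction of each sample's
#' reads descending through every branch,
#' \deqn{d_W = \frac{\sum_b L_b |p_A(b) - p_B(b)|}{\sum_b L_b (p_A(b) + p_B(b))}}
#' the normalized (alpha = 1) variant, bounded in \[0, 1\]; with
#' `normalized = FALSE` the numerator alone (raw weighted UniFrac) is
#' returned. Both are computed by one post-order pass accumulating descendant
#' read mass per branch.
#'
#' `unifrac()` returns all unordered sample pairs of a table as a tidy
#' tibble; `unweighted_unifrac()` and `weighted_unifrac()` compare two named
#' count vectors. Similarity is reported as `1 - distance`.
#'
#' @param tbl An OTU tibble (see [as_otu_tbl()]).
#' @param tree A rooted [ape::phylo][ape::read.tree] tree whose tips include
#'   every OTU of the table.
#' @param weighted Use read-abundance weighting (default `FALSE`).
#' @param normalized For the weighted form, divide by the total branch mass so
#'   the distance lies in \[0, 1\] (default `TRUE`). Ignored when
#'   `weighted = FALSE`.
#' @return `unifrac()`: a tibble with columns `sample_a`, `sample_b`,
#'   `distance`, `similarity`.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' a <- c(A = 1, B = 1, C = 0, D = 0)
#' b <- c(A = 1, B = 0, C = 1, D = 0)
#' unweighted_unifrac(a, b, tree)  # 3 / 5
#' @export
unifrac <- function(tbl, tree, weighted = FALSE, normalized = TRUE) {
  m <- otu_matrix(tbl)
  bm <- branch_mass(tree, m)
  ids <- rownames(m)
  pairs <- utils::combn(seq_along(ids), 2)
  d <- vapply(seq_len(ncol(pairs)), function(k) {
    pair_unifrac(bm, pairs[1, k], pairs[2, k], weighted, normalized)
  }, numeric(1))
  tibble(
    sample_a = ids[pairs[1, ]],
    sample_b = ids[pairs[2, ]],
    distance = d,
    similarity = 1 - d
  )
}

#' @rdname unifrac
#' @param a,b Named non-negative count vectors (names are tree tip labels);
#'   for the unweighted form a character vector of present OTU ids is also
#'   accepted.
#' @export
unweighted_unifrac <- function(a, b, tree) {
  m <- pair_matrix(a, b, tree)
  if (all(m[1, ] == 0) && all(m[2, ] == 0)) abort("both samples are empty.")
  pair_unifrac(branch_mass(tree, m), 1, 2, weighted = FALSE)
}

#' @rdname unifrac
#' @export
weighted_unifrac <- function(a, b, tree, normalized = TRUE) {
  m <- pair_matrix(a, b, tree)
  if (any(rowSums(m) == 0)) abort("weighted UniFrac needs positive read totals in both samples.")
  pair_unifrac(branch_mass(tree, m), 1, 2, weighted = TRUE, normalized = normalized)
}

# Descendant read counts per branch: edges x samples matrix, plus lengths.
branch_mass <- function(tree, counts) {
  check_tree(tree)
  missing <- setdiff(colnames(counts), tree$tip.label)
  if (length(missing)) {
    abort(paste0("OTUs not in tree: ", paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..."))
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  node_mass <- matrix(0, nrow = n_node, ncol = nrow(counts))
  node_mass[match(colnames(counts), tree$tip.label), ] <- t(counts)
  post <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    parent <- post$edge[e, 1]
    child <- post$edge[e, 2]
    node_mass[parent, ] <- node_mass[parent, ] + node_mass[child, ]
  }
  list(
    length = post$edge.length,
    mass = node_mass[post$edge[, 2], , drop = FALSE],
    totals = rowSums(counts)
  )
}

pair_unifrac <- function(bm, i, j, weighted, normalized = TRUE) {
  if (weighted) {
    pa <- bm$mass[, i] / bm$totals[i]
    pb <- bm$mass[, j] / bm$totals[j]
    num <- sum(bm$length * abs(pa - pb))
    if (!normalized) return(num)
    den <- sum(bm$length * (pa + pb))
    return(num / den)
  }
  ina <- bm$mass[, i] > 0
  inb <- bm$mass[, j] > 0
  shared_or_unique <- ina | inb
  if (!any(shared_or_unique)) abort("both samples are empty.")
  sum(bm$length[xor(ina, inb)]) / sum(bm$length[shared_or_unique])
}

pair_matrix <- function(a, b, tree) {
  to_counts <- function(x) {
    if (is.character(x)) x <- setNames(rep(1, length(x)), x)
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      abort("count vectors must be named by OTU id.")
    }
    x
  }
  a <- to_counts(a)
  b <- to_counts(b)
  ids <- union(names(a), names(b))
  m <- rbind(
    a = as.integer(round(a[match(ids, names(a))])) ,
    b = as.integer(round(b[match(ids, names(b))]))
  )
  m[is.na(m)] <- 0L
  colnames(m) <- ids
  m
}

#' Presence/absence overlap between OTU sets
#'
#' `shared_otu_fraction()` is the asymmetric coverage of a reference set by a
#' query: the fraction of the reference's OTUs also found in the query
#' (reference = bulk sediment, query = a grain, in the typical use).
#' `jaccard_index()` is the symmetric intersection-over-union.
#'
#' @param reference,query,a,b Character vectors of OTU ids (or anything
#'   coercible; duplicates ignored).
#' @return A proportion in \[0, 1\].
#' @export
shared_otu_fraction <- function(reference, query) {
  reference <- unique(as.character(reference))
  if (length(reference) == 0L) abort("`reference` must be nonempty.")
  length(intersect(reference, unique(as.character(query)))) / length(reference)
}

#' @rdname shared_otu_fraction
#' @export
jaccard_index <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- union(a, b)
  if (length(u) == 0L) abort("both sets are empty.")
  length(intersect(a, b)) / length(u)
}

#' Square distance matrix from tidy pairwise distances
#'
#' @param pairs A tibble as returned by [unifrac()].
#' @return A symmetric base matrix with zero diagonal.
#' @export
distance_matrix <- function(pairs) {
  ids <- unique(c(pairs$sample_a, pairs$sample_b))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(pairs))) {
    m[pairs$sample_a[k], pairs$sample_b[k]] <- pairs$distance[k]
    m[pairs$sample_b[k], pairs$sample_a[k]] <- pairs$distance[k]
  }
  m
}
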