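#' Chao1 richness estimator
#'
#' Nonparametric estimate of true OTU richness from the frequencies of
#' singletons and doubletons. The default is the bias-corrected form
#' \deqn{S_{chao1} = S_{obs} + \frac{f_1 (f_1 - 1)}{2 (f_2 + 1)}}
#' where \eqn{f_1} and \eqn{f_2} are the numbers of OTUs observed exactly
#' once and twice. The classical form \eqn{S_{obs} + f_1^2 / (2 f_2)} is
#' available with `bias_corrected = FALSE` (undefined when \eqn{f_2 = 0}, in
#' which case the bias-corrected value is returned with a warning).
#'
#' @param counts Non-negative integer vector of per-OTU counts for one sample.
#' @param bias_corrected Use the bias-corrected estimator (default `TRUE`).
#' @return A single number, always `>=` the observed richness.
#' @examples
#' chao1(c(1, 1, 2, 5))  # 4 + 2*1/(2*2) = 4.5
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  if (f2 == 0) {
    warn("classical Chao1 undefined with no doubletons; using bias-corrected form.")
    return(s_obs + f1 * (f1 - 1) / 2)
  }
  s_obs + f1^2 / (2 * f2)
}

#' Inverse Simpson diversity index
#'
#' Reciprocal of the probability that two reads drawn with replacement belong
#' to the same OTU: \eqn{1 / \sum_i p_i^2} with \eqn{p_i} the relative
#' abundances. Ranges from 1 (one OTU) to the number of OTUs (perfect
#' evenness). The finite-sample (unbiased, without-replacement) variant
#' \eqn{1 / \sum_i \frac{n_i (n_i - 1)}{N (N - 1)}} is available via
#' `finite_sample = TRUE`.
#'
#' @inheritParams chao1
#' @param finite_sample Use the without-replacement estimator (default
#'   `FALSE`, matching the plug-in form used by vegan's `invsimpson`).
#' @return A single number `>= 1`.
#' @examples
#' inverse_simpson(c(3, 1))  # 1 / (0.5625 + 0.0625) = 1.6
#' @export
inverse_simpson <- function(counts, finite_sample = FALSE) {
  counts <- check_counts(counts)
  n <- sum(counts)
  if (finite_sample) {
    if (n < 2) abort("finite-sample inverse Simpson needs at least 2 reads.")
    return(1 / sum(counts * (counts - 1) / (n * (n - 1))))
  }
  p <- counts / n
  1 / sum(p^2)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting a sample's observed
#' OTUs to the root of the phylogeny (root-inclusive, the picante
#' convention). Adding an OTU can never decrease PD, and a sample containing
#' every leaf has PD equal to the tree's total branch length.
#'
#' @param present Character vector of observed OTU ids (tree leaf labels).
#' @param tree A rooted [ape::phylo][ape::read.tree] tree with branch lengths
#'   whose tip labels include every observed OTU.
#' @return Summed branch length (same units as the tree).
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
#' faith_pd(c("A", "C"), tree)  # 1 + 0.5 + 3 = 4.5
#' @export
faith_pd <- function(present, tree) {
  check_tree(tree)
  present <- unique(as.character(present))
  if (length(present) == 0L) abort("`present` must name at least one OTU.")
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    abort(paste0("OTUs not in tree: ", paste(missing, collapse = ", ")))
  }
  n_tip <- length(tree$tip.label)
  # flag, for every node, whether any observed leaf descends from it
  has_desc <- logical(n_tip + tree$Nnode)
  has_desc[match(present, tree$tip.label)] <- TRUE
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  edge_order <- match(paste(edges[, 1], edges[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in seq_len(nrow(edges))) {
    if (has_desc[edges[e, 2]]) has_desc[edges[e, 1]] <- TRUE
  }
  sum(tree$edge.length[edge_order][has_desc[edges[, 2]]])
}

#' Per-sample alpha diversity table
#'
#' Computes observed OTUs, Chao1, inverse Simpson and (when a tree is given)
#' Faith's PD for every sample of an OTU table. Samples should normally be
#' rarefied to equal depth first (see [subsample_counts()]) so the metrics
#' are comparable.
#'
#' @param tbl An OTU tibble (see [as_otu_tbl()]).
#' @param tree Optional rooted phylogeny covering the table's OTUs; if
#'   `NULL`, `faith_pd` is omitted.
#' @return A tibble with one row per sample: `sample_id`, `observed_otus`,
#'   `chao1`, `inv_simpson` and optionally `faith_pd`.
#' @export
alpha_diversity <- function(tbl, tree = NULL) {
  m <- otu_matrix(tbl)
  out <- tibble(
    sample_id = rownames(m),
    observed_otus = as.integer(rowSums(m > 0)),
    chao1 = apply(m, 1, chao1),
    inv_simpson = apply(m, 1, inverse_simpson)
  )
  if (!is.null(tree)) {
    out$faith_pd <- vapply(seq_len(nrow(m)), function(i) {
      faith_pd(colnames(m)[m[i, ] > 0], tree)
    }, numeric(1))
  }
  out
}

check_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0L) {
    abort("`counts` must be a non-empty numeric vector.")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("`counts` must be non-negative integers.")
  }
  if (sum(counts) == 0) abort("`counts` must contain at least one positive count.")
  counts
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape `phylo` object.")
  if (is.null(tree$edge.length)) abort("`tree` must have branch lengths.")
  if (any(tree$edge.length < 0)) abort("`tree` has negative branch lengths.")
  invisible(tree)
}
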