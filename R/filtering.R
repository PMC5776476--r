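#' Remove rare OTUs by dataset-wide total count
#'
#' Drops OTUs whose summed read count across all samples in the table falls
#' below `min_total`. With the default `min_total = 3` this removes absolute
#' singletons and doubletons — OTUs backed by only one or two sequences in the
#' whole dataset — the standard pre-filter applied to grain and bulk libraries
#' analysed together before any diversity analysis. Counts of retained OTUs
#' are never altered and sample and OTU order are preserved.
#'
#' @param tbl An OTU tibble (see [as_otu_tbl()]).
#' @param min_total Minimum summed count across samples for an OTU to be
#'   retained (default 3).
#' @param per_sample If `TRUE`, apply the threshold within each sample
#'   instead: counts below `min_total` are zeroed per sample, and OTUs left
#'   with zero total are dropped. Default `FALSE` (dataset-wide totals).
#' @return The filtered OTU tibble.
#' @examples
#' tbl <- as_otu_tbl(matrix(c(1L, 0L, 1L, 1L, 2L, 1L), 2, 3,
#'   dimnames = list(c("g1", "g2"), c("a", "b", "c"))))
#' remove_rare_otus(tbl)          # keeps only c (total 3)
#' @export
remove_rare_otus <- function(tbl, min_total = 3, per_sample = FALSE) {
  if (!is_count(min_total, min = 1)) abort("`min_total` must be an integer >= 1.")
  m <- otu_matrix(tbl)
  if (per_sample) {
    m[m < min_total] <- 0L
    keep <- colSums(m) > 0
  } else {
    keep <- colSums(m) >= min_total
  }
  as_otu_tbl(m[, keep, drop = FALSE])
}

#' Rarefy an OTU table to equal depth
#'
#' Subsamples each sample's reads without replacement down to `depth`, so all
#' samples are compared at identical sequencing effort. The default depth is
#' the lowest per-sample depth in the table. Each OTU's subsampled count is
#' hypergeometric given the sample's composition; the draw is delegated to
#' [rrarefy_quiet()] under a locally seeded RNG, so results are reproducible
#' and the caller's RNG stream is untouched.
#'
#' @param tbl An OTU tibble.
#' @param depth Target reads per sample; defaults to the minimum sample depth.
#' @param seed Integer seed for the subsampling draw (optional).
#' @param keep_zero_otus Keep OTU columns whose post-subsampling total is zero
#'   (default `FALSE`: they are dropped).
#' @return The rarefied OTU tibble; every row sums to `depth`. The seed used
#'   is recorded in attribute `"subsample_seed"`.
#' @export
subsample_counts <- function(tbl, depth = NULL, seed = NULL, keep_zero_otus = FALSE) {
  m <- otu_matrix(tbl)
  depths <- rowSums(m)
  if (is.null(depth)) depth <- min(depths)
  if (!is_count(depth, min = 1)) abort("`depth` must be a positive integer.")
  short <- which(depths < depth)
  if (length(short)) {
    abort(paste0("depth ", depth, " exceeds the depth of sample `",
                 rownames(m)[short[1]], "` (", depths[short[1]], ")."))
  }
  sub <- with_seed(seed, rrarefy_quiet(m, depth))
  storage.mode(sub) <- "integer"
  if (!keep_zero_otus) sub <- sub[, colSums(sub) > 0, drop = FALSE]
  out <- as_otu_tbl(sub)
  attr(out, "subsample_seed") <- seed
  out
}

#' Zero out OTUs below a within-sample relative-abundance threshold
#'
#' For each sample, counts of OTUs whose within-sample relative abundance is
#' not strictly greater than `min_permille` per mill are set to zero; OTUs
#' zeroed in every sample are dropped. Thresholds of 0.1 and 1 per mill are
#' the conventional cut-offs for excluding the "rare biosphere". Apply after
#' rarefaction so the threshold means the same number of reads in every
#' sample.
#'
#' @param tbl An OTU tibble.
#' @param min_permille Threshold in parts per thousand; an OTU is kept in a
#'   sample only if `count / depth > min_permille / 1000` (strict).
#' @return The thresholded OTU tibble.
#' @export
abundance_threshold <- function(tbl, min_permille) {
  if (!is.numeric(min_permille) || length(min_permille) != 1L || min_permille < 0) {
    abort("`min_permille` must be a single non-negative number.")
  }
  m <- otu_matrix(tbl)
  depths <- rowSums(m)
  rel <- m / ifelse(depths > 0, depths, 1)
  m[rel <= min_permille / 1000] <- 0L
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) == 0L) {
    return(as_tibble(tibble(sample_id = rownames(otu_matrix(tbl)))))
  }
  as_otu_tbl(m)
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Sums OTU columns that share the same taxon at `rank`, yielding one column
#' per taxon (for example one per family). OTUs missing from the taxonomy map
#' are pooled into `"unclassified"` with a warning; OTUs classified only to a
#' shallower rank are pooled into `"unclassified_<deepest known taxon>"`.
#' Per-sample totals are preserved exactly.
#'
#' @param tbl An OTU tibble.
#' @param tax A taxonomy tibble (`otu_id`, semicolon `lineage`), as from
#'   [read_taxonomy()].
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"` (default `"family"`).
#' @return An OTU-tibble-shaped table whose columns are taxa at `rank`.
#' @export
aggregate_by_rank <- function(tbl, tax, rank = "family") {
  rank <- match.arg(rank, taxonomy_ranks)
  m <- otu_matrix(tbl)
  labels <- rank_labels(colnames(m), tax, rank)
  groups <- split(seq_len(ncol(m)), labels)
  agg <- vapply(groups, function(j) rowSums(m[, j, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(m), names(groups)))
  storage.mode(agg) <- "integer"
  as_otu_tbl(agg)
}

# Map OTU ids to their taxon label at `rank`, bucketing unknowns.
rank_labels <- function(otu_ids, tax, rank) {
  ranks <- split_lineage(tax)
  idx <- match(otu_ids, ranks$otu_id)
  if (anyNA(idx)) {
    warn(paste0(sum(is.na(idx)), " OTU(s) absent from the taxonomy map; ",
                "assigned to \"unclassified\"."))
  }
  rank_i <- match(rank, taxonomy_ranks)
  out <- character(length(otu_ids))
  for (k in seq_along(otu_ids)) {
    i <- idx[k]
    if (is.na(i)) {
      out[k] <- "unclassified"
      next
    }
    val <- ranks[[rank]][i]
    if (!is.na(val)) {
      out[k] <- val
    } else {
      known <- unlist(ranks[i, taxonomy_ranks[seq_len(rank_i)]])
      known <- known[!is.na(known)]
      out[k] <- if (length(known)) paste0("unclassified_", tail(known, 1)) else "unclassified"
    }
  }
  out
}
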