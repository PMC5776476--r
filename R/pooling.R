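#' Grain-pooling richness coverage curve
#'
#' Orders the grain samples by their individual observed OTU richness,
#' consecutively pools them, and asks what fraction of the bulk-sediment OTU
#' richness each pool captures — always comparing identical numbers of
#' sequences. Each grain is first rarefied to a common depth `n` (once, so a
#' pool of `k` grains holds exactly `k * n` reads); the pooled bulk reference
#' (`bulk_pooled`, the concatenated bulk replicates) is then rarefied to
#' `k * n` reads, and coverage at pool size `k` is
#' `|OTUs(pool_k) ∩ OTUs(bulk at k*n)| / |OTUs(bulk at k*n)|`,
#' averaged over `n_replicates` independent bulk subsamples. If `k * n`
#' exceeds the pooled bulk depth the comparison is truncated to the bulk
#' depth with a warning and the depth actually compared is recorded.
#'
#' @param tbl An OTU tibble holding both grain and bulk samples (unrarefied).
#' @param grain_ids,bulk_ids Disjoint sample id sets: the single-grain
#'   libraries and the bulk-sediment replicate libraries.
#' @param order Pool the grains in `"decreasing"` (most diverse first) or
#'   `"increasing"` order of individual richness, or `"custom"` to keep
#'   `grain_ids` as given. Ties broken by sample id.
#' @param depth Common per-grain depth; defaults to the minimum grain depth.
#' @param n_replicates Bulk subsampling replicates per pool size (default 10).
#' @param seed Integer seed controlling the grain rarefaction and all bulk
#'   subsamples.
#' @return A `coverage_curve` tibble with columns `k`, `coverage` (mean over
#'   replicates), `sd_coverage`, `depth_compared`, plus attributes `order`,
#'   `depth`, `seed`, `n_replicates`.
#' @export
coverage_curve <- function(tbl, grain_ids, bulk_ids,
                           order = c("decreasing", "increasing", "custom"),
                           depth = NULL, n_replicates = 10, seed = NULL) {
  order <- match.arg(order)
  m <- otu_matrix(tbl)
  missing <- setdiff(c(grain_ids, bulk_ids), rownames(m))
  if (length(missing)) {
    abort(paste0("samples not in table: ", paste(missing, collapse = ", ")))
  }
  if (length(intersect(grain_ids, bulk_ids))) {
    abort("`grain_ids` and `bulk_ids` must be disjoint.")
  }
  if (length(bulk_ids) == 0L || length(grain_ids) == 0L) {
    abort("need at least one grain and one bulk sample.")
  }
  if (!is_count(n_replicates, min = 1)) abort("`n_replicates` must be a positive integer.")

  grains <- m[grain_ids, , drop = FALSE]
  if (is.null(depth)) depth <- min(rowSums(grains))
  if (any(rowSums(grains) < depth)) {
    abort("`depth` exceeds the depth of at least one grain sample.")
  }
  bulk_pooled <- colSums(m[bulk_ids, , drop = FALSE])
  bulk_total <- sum(bulk_pooled)

  with_seed(seed, {
    sub <- rrarefy_quiet(grains, depth)
    richness <- rowSums(sub > 0)
    ord <- switch(order,
      decreasing = order(-richness, rownames(sub)),
      increasing = order(richness, rownames(sub)),
      custom = seq_len(nrow(sub))
    )
    sub <- sub[ord, , drop = FALSE]
    rows <- purrr::map(seq_len(nrow(sub)), function(k) {
      pool_otus <- colnames(sub)[colSums(sub[seq_len(k), , drop = FALSE]) > 0]
      want <- k * depth
      if (want > bulk_total) {
        warn(sprintf("pool depth %d exceeds pooled bulk depth %d; comparing at %d reads.",
                     want, bulk_total, bulk_total))
        want <- bulk_total
      }
      cov <- vapply(seq_len(n_replicates), function(r) {
        bsub <- rrarefy_quiet(matrix(bulk_pooled, nrow = 1,
                                      dimnames = list("bulk", names(bulk_pooled))), want)
        bulk_otus <- colnames(bsub)[bsub[1, ] > 0]
        length(intersect(pool_otus, bulk_otus)) / length(bulk_otus)
      }, numeric(1))
      tibble(k = k, coverage = mean(cov),
             sd_coverage = if (n_replicates > 1) sd(cov) else NA_real_,
             depth_compared = as.integer(want))
    })
    out <- dplyr::bind_rows(rows)
    structure(out,
              class = c("coverage_curve", class(out)),
              order = order, depth = depth, seed = seed,
              n_replicates = n_replicates,
              grain_order = rownames(sub))
  })
}

#' Smallest pool size reaching a coverage target
#'
#' @param curve A `coverage_curve` from [coverage_curve()].
#' @param target Coverage fraction in \[0, 1\]; a target of 0 is reached by
#'   the first pool.
#' @return The smallest `k` whose mean coverage is at least `target`, or
#'   `NA_integer_` if the curve never reaches it.
#' @export
grains_to_reach <- function(curve, target) {
  if (!is.numeric(target) || length(target) != 1L || is.na(target) ||
      target < 0 || target > 1) {
    abort("`target` must be a proportion in [0, 1].")
  }
  if (nrow(curve) == 0L) abort("`curve` is empty.")
  hit <- which(curve$coverage >= target)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(curve$k[min(hit)])
}

#' @exportS3Method ggplot2::autoplot
autoplot.coverage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$coverage)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = "number of pooled grains",
      y = "fraction of bulk OTU richness covered",
      title = paste0("Grain pooling (", attr(object, "order"), " richness order)")
    ) +
    ggplot2::theme_minimal()
}
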