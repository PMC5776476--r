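#' Identify the core community across grain samples
#'
#' The core community is the set of OTUs detected (count `>= presence_min`)
#' in at least `min_prevalence` of the grain samples — with the default
#' prevalence of 1, in every grain. The table should be rarefied to equal
#' depth first so presence means the same sampling effort everywhere; a
#' warning is issued otherwise.
#'
#' @param tbl An OTU tibble (see [as_otu_tbl()]), ideally rarefied.
#' @param grain_ids Sample ids over which prevalence is computed (the grain
#'   samples); defaults to all samples. Bulk samples should be excluded here
#'   but may remain in `tbl` for comparative reporting.
#' @param min_prevalence Minimum fraction of grain samples an OTU must occur
#'   in (default 1: all of them).
#' @param presence_min Minimum count for an OTU to be called present in a
#'   sample (default 1).
#' @return A `core_report` object: a list with `core_otu_ids`,
#'   `core_otu_count`, `core_fraction_of_otus` (share of all OTUs observed
#'   across the grain subset), and `per_sample_core_read_share`, a tibble of
#'   each grain sample's fraction of reads carried by core OTUs. Use
#'   [tidy()] / [glance()] to get tibbles.
#' @export
find_core <- function(tbl, grain_ids = NULL, min_prevalence = 1, presence_min = 1) {
  m <- otu_matrix(tbl)
  if (is.null(grain_ids)) grain_ids <- rownames(m)
  if (length(grain_ids) == 0L) abort("`grain_ids` must be nonempty.")
  missing <- setdiff(grain_ids, rownames(m))
  if (length(missing)) {
    abort(paste0("samples not in table: ", paste(missing, collapse = ", ")))
  }
  if (!is_proportion(min_prevalence) || min_prevalence <= 0) {
    abort("`min_prevalence` must be in (0, 1].")
  }
  g <- m[grain_ids, , drop = FALSE]
  depths <- rowSums(g)
  if (length(unique(depths)) > 1L) {
    warn("grain samples have unequal depths; rarefy with subsample_counts() first.")
  }
  observed <- colSums(g >= presence_min) > 0
  prevalence <- colMeans(g >= presence_min)
  core <- colnames(g)[prevalence >= min_prevalence & observed]
  share <- rowSums(g[, core, drop = FALSE]) / depths
  structure(
    list(
      core_otu_ids = core,
      core_otu_count = length(core),
      core_fraction_of_otus = length(core) / sum(observed),
      grain_ids = grain_ids,
      min_prevalence = min_prevalence,
      presence_min = presence_min,
      per_sample_core_read_share = tibble(
        sample_id = grain_ids,
        core_read_share = unname(share)
      )
    ),
    class = "core_report"
  )
}

#' @export
print.core_report <- function(x, ...) {
  cat("Core community report\n")
  cat("  grain samples:       ", length(x$grain_ids), "\n")
  cat("  core OTUs:           ", x$core_otu_count,
      sprintf(" (%.1f%% of observed OTUs)", 100 * x$core_fraction_of_otus), "\n")
  rng <- range(x$per_sample_core_read_share$core_read_share)
  cat(sprintf("  core read share:      %.2f-%.2f (mean %.2f)\n",
              rng[1], rng[2], mean(x$per_sample_core_read_share$core_read_share)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.core_report <- function(x, ...) x$per_sample_core_read_share

#' @exportS3Method generics::glance
glance.core_report <- function(x, ...) {
  tibble(
    n_grains = length(x$grain_ids),
    core_otu_count = x$core_otu_count,
    core_fraction_of_otus = x$core_fraction_of_otus,
    mean_core_read_share = mean(x$per_sample_core_read_share$core_read_share),
    min_core_read_share = min(x$per_sample_core_read_share$core_read_share),
    max_core_read_share = max(x$per_sample_core_read_share$core_read_share)
  )
}

#' Family-level breakdown of core-community contributions
#'
#' Expresses, for every grain sample, the share of total reads carried by
#' each family of the core community. Families contributing on average less
#' than `min_mean_share` of a sample's reads are merged into
#' `"other core community"`; all reads from non-core OTUs appear as
#' `"non-core"`, so each sample's shares sum to one.
#'
#' @param report A `core_report` from [find_core()].
#' @param tbl The OTU tibble the report was computed from.
#' @param tax A taxonomy tibble (`otu_id`, `lineage`).
#' @param min_mean_share Mean-share threshold below which a core family is
#'   pooled (default 0.005, i.e. 0.5%).
#' @return A tibble with columns `sample_id`, `family`, `share`.
#' @export
core_family_breakdown <- function(report, tbl, tax, min_mean_share = 0.005) {
  if (!inherits(report, "core_report")) abort("`report` must come from find_core().")
  m <- otu_matrix(tbl)[report$grain_ids, , drop = FALSE]
  depths <- rowSums(m)
  core <- intersect(colnames(m), report$core_otu_ids)
  fam <- rank_labels(core, tax, "family")
  core_m <- m[, core, drop = FALSE]
  by_fam <- vapply(split(seq_along(core), fam),
                   function(j) rowSums(core_m[, j, drop = FALSE]),
                   numeric(nrow(m)))
  if (nrow(m) == 1L) {
    by_fam <- matrix(by_fam, nrow = 1,
                     dimnames = list(rownames(m), names(split(seq_along(core), fam))))
  }
  shares <- by_fam / depths
  pooled <- colMeans(shares) < min_mean_share
  out <- tibble(
    sample_id = rep(rownames(m), times = ncol(shares)),
    family = rep(colnames(shares), each = nrow(m)),
    share = as.vector(shares),
    pooled = rep(pooled, each = nrow(m))
  )
  out <- dplyr::mutate(out, family = ifelse(.data$pooled, "other core community", .data$family))
  out <- dplyr::summarise(dplyr::group_by(out, .data$sample_id, .data$family),
                          share = sum(.data$share), .groups = "drop")
  noncore <- tibble(
    sample_id = rownames(m),
    family = "non-core",
    share = unname(1 - rowSums(by_fam) / depths)
  )
  dplyr::arrange(dplyr::bind_rows(out, noncore), .data$sample_id,
                 dplyr::desc(.data$share))
}
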