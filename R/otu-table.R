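#' OTU count tables as wide tibbles
#'
#' Throughout the package an OTU table is a plain tibble whose first column,
#' `sample_id`, holds unique sample identifiers and whose remaining columns
#' hold non-negative integer read counts, one column per OTU. Rows are
#' samples, so a sample's sequencing depth is its row sum (see
#' [sample_depths()]). `as_otu_tbl()` converts a samples-by-OTUs count matrix
#' (or data frame) into this form and validates it; `otu_matrix()` goes the
#' other way for numeric work.
#'
#' @param x A samples-by-OTUs matrix or data frame of counts. For a matrix,
#'   rownames become `sample_id` and colnames the OTU ids; for a data frame a
#'   `sample_id` column is used if present.
#' @return `as_otu_tbl()` returns a validated OTU tibble; `otu_matrix()` an
#'   integer matrix with sample ids as rownames.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("otu1", "otu2")))
#' tbl <- as_otu_tbl(m)
#' otu_matrix(tbl)
#' @export
as_otu_tbl <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      rownames(x) <- paste0("sample", seq_len(nrow(x)))
    }
    if (is.null(colnames(x))) {
      abort("count matrix must have OTU ids as colnames.")
    }
    tbl <- tibble(sample_id = rownames(x))
    tbl <- dplyr::bind_cols(tbl, as_tibble(x, .name_repair = "minimal"))
  } else if (is.data.frame(x)) {
    tbl <- as_tibble(x)
    if (!"sample_id" %in% names(tbl)) {
      abort("data frame must contain a `sample_id` column.")
    }
    tbl <- dplyr::relocate(tbl, "sample_id")
  } else {
    abort("`x` must be a matrix or data frame of counts.")
  }
  validate_otu_tbl(tbl)
}

#' @rdname as_otu_tbl
#' @param tbl An OTU tibble.
#' @export
otu_matrix <- function(tbl) {
  tbl <- validate_otu_tbl(tbl)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tbl$sample_id
  m
}

#' @rdname as_otu_tbl
#' @export
otu_ids <- function(tbl) setdiff(names(tbl), "sample_id")

#' Per-sample sequencing depth
#'
#' @param tbl An OTU tibble (see [as_otu_tbl()]).
#' @return A tibble with columns `sample_id` and `depth` (row sum of counts).
#' @export
sample_depths <- function(tbl) {
  m <- otu_matrix(tbl)
  tibble(sample_id = rownames(m), depth = as.integer(rowSums(m)))
}

validate_otu_tbl <- function(tbl) {
  if (!is.data.frame(tbl) || !"sample_id" %in% names(tbl)) {
    abort("an OTU table must be a data frame with a `sample_id` column.")
  }
  if (names(tbl)[1] != "sample_id") {
    tbl <- dplyr::relocate(tbl, "sample_id")
  }
  if (nrow(tbl) < 1L) abort("an OTU table needs at least one sample.")
  if (anyDuplicated(tbl$sample_id)) {
    dup <- unique(tbl$sample_id[duplicated(tbl$sample_id)])
    abort(paste0("duplicate sample ids: ", paste(dup, collapse = ", ")))
  }
  ids <- otu_ids(tbl)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate OTU ids: ", paste(dup, collapse = ", ")))
  }
  for (j in ids) {
    v <- tbl[[j]]
    if (!is.numeric(v)) {
      abort(paste0("counts for OTU `", j, "` are not numeric."))
    }
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(paste0("invalid count at sample `", tbl$sample_id[bad[1]],
                   "`, OTU `", j, "`: counts must be non-negative integers."))
    }
    if (!is.integer(v)) tbl[[j]] <- as.integer(v)
  }
  as_tibble(tbl)
}

#' Read and write OTU tables
#'
#' The canonical on-disk dialect is a tab-separated file with a `sample_id`
#' header column followed by one column per OTU, one row per sample. The
#' mothur "shared" dialect (leading `label`, `Group`, `numOtus` columns,
#' `Group` holding the sample id) is accepted on read. Writing always uses
#' the plain dialect, so `read_otu_table(write_otu_table(tbl, f))` round-trips
#' exactly.
#'
#' @param path File path.
#' @param dialect `"plain"` (canonical) or `"mothur"` (shared file).
#' @return `read_otu_table()` returns a validated OTU tibble;
#'   `write_otu_table()` returns `path` invisibly.
#' @export
read_otu_table <- function(path, dialect = c("plain", "mothur")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (dialect == "mothur") {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(raw))) {
      abort("mothur shared file must have label, Group and numOtus columns.")
    }
    raw <- dplyr::rename(raw, sample_id = "Group")
    raw <- dplyr::select(raw, -dplyr::all_of(c("label", "numOtus")))
  }
  if (!"sample_id" %in% names(raw)) {
    abort("plain OTU table must have a `sample_id` header column.")
  }
  raw <- dplyr::relocate(raw, "sample_id")
  for (j in setdiff(names(raw), "sample_id")) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(paste0("parse error in `", basename(path), "` at sample `",
                   raw$sample_id[bad[1]], "`, OTU `", j, "`: `",
                   raw[[j]][bad[1]], "` is not a non-negative integer count."))
    }
    raw[[j]] <- as.integer(v)
  }
  validate_otu_tbl(raw)
}

#' @rdname read_otu_table
#' @param tbl An OTU tibble.
#' @export
write_otu_table <- function(tbl, path) {
  tbl <- validate_otu_tbl(tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read and write taxonomy maps
#'
#' A taxonomy map is a two-column tab-separated file (`otu_id`, `lineage`)
#' whose lineage is a semicolon-separated ranked string
#' (`domain;phylum;class;order;family;genus`, possibly truncated). In memory
#' it is a tibble with those two columns.
#'
#' @param path File path.
#' @return A tibble with columns `otu_id` and `lineage`.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("otu_id", "lineage") %in% names(tax))) {
    abort("taxonomy file must have columns `otu_id` and `lineage`.")
  }
  tax
}

#' @rdname read_taxonomy
#' @param tax A taxonomy tibble (`otu_id`, `lineage`).
#' @export
write_taxonomy <- function(tax, path) {
  readr::write_tsv(tax[, c("otu_id", "lineage")], path, progress = FALSE)
  invisible(path)
}

taxonomy_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

# Split semicolon lineages into a tibble of rank columns; shorter lineages
# leave deeper ranks NA.
split_lineage <- function(tax) {
  parts <- strsplit(tax$lineage, ";", fixed = TRUE)
  out <- matrix(NA_character_, nrow = length(parts), ncol = length(taxonomy_ranks),
                dimnames = list(NULL, taxonomy_ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[nzchar(p)]
    n <- min(length(p), length(taxonomy_ranks))
    if (n > 0) out[i, seq_len(n)] <- p[seq_len(n)]
  }
  dplyr::bind_cols(tibble(otu_id = tax$otu_id), as_tibble(out))
}
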