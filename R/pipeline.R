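#' Run the full grain-community analysis pipeline
#'
#' Orchestrates the stages end to end — simulate (or load) data, rare-OTU
#' filtering, equal-depth rarefaction, alpha and beta diversity, core
#' community, grain-pooling coverage, colonization geometry, and spatial
#' nearest-neighbour statistics — from a single declarative configuration,
#' writing every stage's output plus a JSON run manifest (inputs, seeds,
#' package version, per-file checksums) into `output_dir`. Re-running with
#' the same configuration reproduces byte-identical outputs.
#'
#' The configuration is a named list (or path to a YAML file) with optional
#' blocks:
#' \describe{
#'   \item{stages}{Character vector of stages to run; default all of
#'     `simulate`, `filter`, `subsample`, `alpha`, `beta`, `core`,
#'     `pooling`, `geometry`, `spatial`.}
#'   \item{seed}{Master integer seed; stage seeds are derived from it unless
#'     given explicitly.}
#'   \item{community}{Arguments for [community_model()], used by the
#'     `simulate` stage; alternatively `otu_table`, `tree`, `taxonomy` file
#'     paths to load instead of simulating.}
#'   \item{spatial}{Arguments for [spatial_model()], or a `points` CSV path.}
#'   \item{filter}{`min_total` for [remove_rare_otus()].}
#'   \item{subsample}{`depth` (optional) for [subsample_counts()].}
#'   \item{core}{`min_prevalence` for [find_core()].}
#'   \item{pooling}{`order`, `n_replicates`, `target` for [coverage_curve()].}
#'   \item{geometry}{Arguments for [geometry_params()].}
#' }
#' Grain and bulk samples are told apart by id prefix (`grain`/`bulk`) unless
#' `grain_ids` / `bulk_ids` are listed in the config.
#'
#' @param config Named list or path to a YAML config file.
#' @param output_dir Directory for stage outputs; overrides
#'   `config$output_dir`.
#' @return The run manifest (a list), invisibly; it is also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  all_stages <- c("simulate", "filter", "subsample", "alpha", "beta", "core",
                  "pooling", "geometry", "spatial")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  output_dir <- output_dir %||% config$output_dir %||% abort("an output directory is required.")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  seed <- config$seed %||% 1L
  stage_seed <- function(offset) as.integer((seed * 101 + offset) %% .Machine$integer.max)

  # ---- fail-fast validation before any compute -------------------------
  table_stages <- intersect(stages, c("filter", "subsample", "alpha", "beta",
                                      "core", "pooling"))
  needs_table <- length(table_stages) > 0
  have_table_source <- "simulate" %in% stages || !is.null(config$community$otu_table)
  if (needs_table && !have_table_source) {
    abort("stages need an OTU table: include the `simulate` stage or set community$otu_table.")
  }
  needs_tree <- any(c("alpha", "beta") %in% stages)
  have_tree <- "simulate" %in% stages || !is.null(config$community$tree)
  if (needs_tree && !have_tree) {
    abort("alpha/beta stages need a tree: include `simulate` or set community$tree.")
  }
  if ("spatial" %in% stages && !is.null(config$spatial$points) &&
      !file.exists(config$spatial$points)) {
    abort(paste0("spatial points file not found: ", config$spatial$points))
  }

  manifest <- list(
    package = "sandgrain",
    version = as.character(utils::packageVersion("sandgrain")),
    seed = seed,
    stages = stages,
    config = config,
    outputs = list()
  )
  written <- character(0)
  out_path <- function(name) file.path(output_dir, name)
  record <- function(stage, paths) {
    written <<- c(written, paths)
    manifest$outputs[[stage]] <<- lapply(unname(paths), function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  }

  # ---- data acquisition -------------------------------------------------
  tbl <- tree <- tax <- NULL
  if ("simulate" %in% stages) {
    cm_args <- config$community %||% list()
    cm_args <- cm_args[setdiff(names(cm_args), c("otu_table", "tree", "taxonomy"))]
    if (is.null(cm_args$seed)) cm_args$seed <- stage_seed(1)
    sim <- simulate_community(do.call(community_model, cm_args))
    tbl <- sim$table
    tree <- sim$tree
    tax <- sim$taxonomy
    record("simulate", write_community(sim, output_dir))
  } else if (needs_table) {
    tbl <- read_otu_table(config$community$otu_table,
                          dialect = config$community$dialect %||% "plain")
    if (!is.null(config$community$tree)) tree <- ape::read.tree(config$community$tree)
    if (!is.null(config$community$taxonomy)) tax <- read_taxonomy(config$community$taxonomy)
  }

  grain_ids <- config$grain_ids %||%
    if (!is.null(tbl)) grep("^grain", tbl$sample_id, value = TRUE)
  bulk_ids <- config$bulk_ids %||%
    if (!is.null(tbl)) grep("^bulk", tbl$sample_id, value = TRUE)

  # ---- table stages -----------------------------------------------------
  if ("filter" %in% stages) {
    tbl <- remove_rare_otus(tbl, min_total = config$filter$min_total %||% 3)
    p <- out_path("otu_table_filtered.tsv")
    write_otu_table(tbl, p)
    record("filter", p)
  }
  sub_tbl <- tbl
  if ("subsample" %in% stages) {
    sub_tbl <- subsample_counts(tbl, depth = config$subsample$depth,
                                seed = stage_seed(2))
    p <- out_path("otu_table_subsampled.tsv")
    write_otu_table(sub_tbl, p)
    record("subsample", p)
  }
  if ("alpha" %in% stages) {
    alpha <- alpha_diversity(sub_tbl, tree = tree)
    p <- out_path("alpha_diversity.tsv")
    readr::write_tsv(alpha, p, progress = FALSE)
    record("alpha", p)
  }
  if ("beta" %in% stages) {
    paths <- character(0)
    for (wtd in c(FALSE, TRUE)) {
      b <- unifrac(sub_tbl, tree, weighted = wtd)
      p <- out_path(sprintf("unifrac_%s.tsv", if (wtd) "weighted" else "unweighted"))
      readr::write_tsv(b, p, progress = FALSE)
      paths <- c(paths, p)
    }
    record("beta", paths)
  }
  if ("core" %in% stages) {
    core <- find_core(sub_tbl, grain_ids = grain_ids,
                      min_prevalence = config$core$min_prevalence %||% 1)
    p1 <- out_path("core_read_share.tsv")
    readr::write_tsv(tidy(core), p1, progress = FALSE)
    p2 <- out_path("core_summary.tsv")
    readr::write_tsv(glance(core), p2, progress = FALSE)
    paths <- c(p1, p2)
    if (!is.null(tax)) {
      fam <- core_family_breakdown(core, sub_tbl, tax)
      p3 <- out_path("core_family_breakdown.tsv")
      readr::write_tsv(fam, p3, progress = FALSE)
      paths <- c(paths, p3)
    }
    record("core", paths)
  }
  if ("pooling" %in% stages) {
    orders <- config$pooling$order %||% c("decreasing", "increasing")
    paths <- character(0)
    for (ord in orders) {
      # pooling works from the unrarefied table and does its own subsampling
      curve <- coverage_curve(tbl, grain_ids, bulk_ids, order = ord,
                              n_replicates = config$pooling$n_replicates %||% 10,
                              seed = stage_seed(3))
      p <- out_path(sprintf("coverage_curve_%s.tsv", ord))
      readr::write_tsv(as_tibble(curve), p, progress = FALSE)
      paths <- c(paths, p)
      target <- config$pooling$target %||% 0.5
      manifest$results$pooling[[ord]] <- list(
        target = target, grains_to_reach = grains_to_reach(curve, target)
      )
    }
    record("pooling", paths)
  }
  if ("geometry" %in% stages) {
    gp <- do.call(geometry_params, config$geometry %||% list())
    rep <- colonization_report(gp)
    p1 <- out_path("geometry_summary.tsv")
    readr::write_tsv(glance(rep, rounded = TRUE), p1, progress = FALSE)
    p2 <- out_path("geometry_per_diameter.tsv")
    readr::write_tsv(tidy(rep, rounded = TRUE), p2, progress = FALSE)
    record("geometry", c(p1, p2))
  }
  if ("spatial" %in% stages) {
    if (!is.null(config$spatial$points)) {
      pat <- read_point_pattern(config$spatial$points)
    } else {
      sm_args <- config$spatial %||% list()
      sm_args <- sm_args[setdiff(names(sm_args), "points")]
      if (is.null(sm_args$seed)) sm_args$seed <- stage_seed(4)
      pat <- simulate_point_pattern(do.call(spatial_model, sm_args))
    }
    p1 <- out_path("point_pattern.csv")
    write_point_pattern(pat, p1)
    p2 <- out_path("nn_summary.tsv")
    readr::write_tsv(nn_summary(pat), p2, progress = FALSE)
    record("spatial", c(p1, p2))
  }

  manifest_path <- out_path("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}
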