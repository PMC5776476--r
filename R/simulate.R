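#' Community model for synthetic grain/bulk OTU data
#'
#' Parameter block for [simulate_community()]. The defaults emulate the
#' structure of grain-attached communities in subtidal surface sand: 17
#' single-grain libraries and 3 bulk-sediment replicates at 4e4-1.4e5 reads
#' each; a core of a few hundred OTUs present on every grain and carrying
#' around 60% of each grain's reads (one-half to two-thirds); thousands of
#' patchily occurring rare OTUs responsible for grain-to-grain differences;
#' and additional bulk-only rare OTUs so single grains recover only part of
#' the bulk richness.
#'
#' @param n_grains Number of single-grain samples (default 17).
#' @param n_bulk Number of bulk-sediment samples (default 3).
#' @param n_core_otus Core OTUs, present on every grain (default 400).
#' @param n_rare_otus Rare OTUs occurring patchily across grains (default 4000).
#' @param n_bulk_only_otus Extra rare OTUs present only in bulk (default 2000).
#' @param core_read_fraction Target share of each grain's reads drawn from
#'   core OTUs (default 0.6).
#' @param rare_occupancy Per-grain inclusion probability of each rare OTU
#'   (default 0.3).
#' @param abundance_shape Lognormal sigma of OTU base abundances; larger means
#'   a steeper rank-abundance curve (default 2).
#' @param depth_range Min and max reads per sample (default c(4e4, 1.4e5)).
#' @param bulk_only_read_fraction Share of bulk reads drawn from bulk-only
#'   OTUs (default 0.1).
#' @param seed Integer seed; identical seeds give identical output (default 1).
#' @return A validated `community_model` list.
#' @export
community_model <- function(n_grains = 17, n_bulk = 3,
                            n_core_otus = 400, n_rare_otus = 4000,
                            n_bulk_only_otus = 2000,
                            core_read_fraction = 0.6, rare_occupancy = 0.3,
                            abundance_shape = 2,
                            depth_range = c(4e4, 1.4e5),
                            bulk_only_read_fraction = 0.1,
                            seed = 1) {
  if (!is_count(n_grains, 1) || !is_count(n_bulk, 0)) {
    abort("`n_grains` must be >= 1 and `n_bulk` >= 0.")
  }
  if (!is_count(n_core_otus, 1)) abort("`n_core_otus` must be an integer >= 1.")
  if (!is_count(n_rare_otus, 0) || !is_count(n_bulk_only_otus, 0)) {
    abort("rare OTU counts must be non-negative integers.")
  }
  if (!is_proportion(core_read_fraction)) abort("`core_read_fraction` must be in [0, 1].")
  if (!is.numeric(rare_occupancy) || rare_occupancy <= 0 || rare_occupancy > 1) {
    abort("`rare_occupancy` must be in (0, 1].")
  }
  if (!is.numeric(abundance_shape) || abundance_shape <= 0) {
    abort("`abundance_shape` must be positive.")
  }
  depth_range <- as.numeric(depth_range)
  if (length(depth_range) != 2L || depth_range[1] < 1 || depth_range[1] > depth_range[2]) {
    abort("`depth_range` must be c(min, max) with 1 <= min <= max.")
  }
  if (depth_range[1] <= n_core_otus) {
    abort("minimum depth must exceed `n_core_otus` (every core OTU gets at least one read).")
  }
  if (!is_proportion(bulk_only_read_fraction)) {
    abort("`bulk_only_read_fraction` must be in [0, 1].")
  }
  structure(
    list(
      n_grains = n_grains, n_bulk = n_bulk,
      n_core_otus = n_core_otus, n_rare_otus = n_rare_otus,
      n_bulk_only_otus = n_bulk_only_otus,
      core_read_fraction = core_read_fraction,
      rare_occupancy = rare_occupancy,
      abundance_shape = abundance_shape,
      depth_range = depth_range,
      bulk_only_read_fraction = bulk_only_read_fraction,
      seed = seed
    ),
    class = "community_model"
  )
}

#' Simulate grain and bulk OTU tables with a phylogeny and taxonomy
#'
#' Draws a synthetic dataset with the statistical structure the downstream
#' analyses assume. Core and rare OTUs get lognormal base abundances
#' (`sigma = abundance_shape`). Each grain sample mixes the core profile
#' (weight `core_read_fraction`) with its own random subset of rare OTUs
#' (each included with probability `rare_occupancy`), then draws a
#' multinomial read vector at a uniform random depth in `depth_range`; one
#' read per core OTU is set aside first, so every core OTU is present in
#' every grain by construction while row sums still equal the drawn depth.
#' Bulk samples are multinomial draws from the average of all grain mixtures
#' (bulk as the union habitat), blended with a bulk-only rare profile. The
#' phylogeny is a random bifurcating topology over all OTUs with exponential
#' branch lengths; the taxonomy assigns OTUs to nested synthetic lineages at
#' family-level granularity.
#'
#' @param model A [community_model()].
#' @return A list of class `grain_community`: `table` (OTU tibble; grain
#'   samples `grain01...`, bulk samples `bulk1...`), `tree` (ape `phylo`
#'   whose tips are exactly the table's OTUs), `taxonomy` (`otu_id`,
#'   `lineage`), and `model`.
#' @export
simulate_community <- function(model = community_model()) {
  if (!inherits(model, "community_model")) abort("`model` must come from community_model().")
  n_otus <- model$n_core_otus + model$n_rare_otus + model$n_bulk_only_otus
  if (model$n_core_otus + model$n_rare_otus == 0) {
    abort("need at least one core or rare OTU.")
  }
  pad <- function(prefix, n) {
    if (n == 0) return(character(0))
    sprintf(paste0(prefix, "%0", nchar(n), "d"), seq_len(n))
  }
  core_ids <- pad("core_otu", model$n_core_otus)
  rare_ids <- pad("rare_otu", model$n_rare_otus)
  bulk_ids <- pad("bulkonly_otu", model$n_bulk_only_otus)
  otu_ids <- c(core_ids, rare_ids, bulk_ids)

  with_seed(model$seed, {
    core_base <- rlnorm(model$n_core_otus, 0, model$abundance_shape)
    rare_base <- rlnorm(model$n_rare_otus, 0, model$abundance_shape)
    bulkonly_base <- rlnorm(model$n_bulk_only_otus, 0, model$abundance_shape)
    p_core <- core_base / sum(core_base)

    draw_depth <- function() {
      as.integer(floor(runif(1, model$depth_range[1], model$depth_range[2] + 1)))
    }

    grain_mix <- matrix(0, nrow = model$n_grains, ncol = n_otus)
    counts <- matrix(0L, nrow = model$n_grains + model$n_bulk, ncol = n_otus,
                     dimnames = list(c(pad("grain", model$n_grains),
                                       pad("bulk", model$n_bulk)), otu_ids))
    f <- model$core_read_fraction
    for (g in seq_len(model$n_grains)) {
      mix <- numeric(n_otus)
      if (model$n_rare_otus > 0) {
        present <- runif(model$n_rare_otus) < model$rare_occupancy
        if (any(present)) {
          p_rare <- rare_base * present
          p_rare <- p_rare / sum(p_rare)
          mix[model$n_core_otus + seq_len(model$n_rare_otus)] <- (1 - f) * p_rare
          mix[seq_len(model$n_core_otus)] <- f * p_core
        } else {
          mix[seq_len(model$n_core_otus)] <- p_core
        }
      } else {
        mix[seq_len(model$n_core_otus)] <- p_core
      }
      grain_mix[g, ] <- mix
      depth <- draw_depth()
      base <- integer(n_otus)
      base[seq_len(model$n_core_otus)] <- 1L
      counts[g, ] <- base +
        as.integer(rmultinom(1, depth - model$n_core_otus, mix))
    }

    if (model$n_bulk > 0) {
      bulk_mix <- colMeans(grain_mix)
      if (model$n_bulk_only_otus > 0 && model$bulk_only_read_fraction > 0) {
        p_bo <- bulkonly_base / sum(bulkonly_base)
        b <- model$bulk_only_read_fraction
        bulk_mix <- (1 - b) * bulk_mix
        bulk_mix[model$n_core_otus + model$n_rare_otus + seq_len(model$n_bulk_only_otus)] <-
          b * p_bo
      }
      for (s in seq_len(model$n_bulk)) {
        counts[model$n_grains + s, ] <- as.integer(rmultinom(1, draw_depth(), bulk_mix))
      }
    }

    tree <- ape::rtree(n_otus, rooted = TRUE, br = function(n) rexp(n, rate = 10))
    tree$tip.label <- otu_ids[as.integer(sub("^t", "", tree$tip.label))]

    taxonomy <- synth_taxonomy(otu_ids)

    structure(
      list(table = as_otu_tbl(counts), tree = tree, taxonomy = taxonomy,
           model = model),
      class = "grain_community"
    )
  })
}

# Nested synthetic lineage per OTU: families are drawn with unequal
# probability so a few families dominate, as in real family-level summaries.
synth_taxonomy <- function(otu_ids) {
  n <- length(otu_ids)
  n_fam <- max(2L, min(400L, ceiling(n / 12)))
  w <- 1 / seq_len(n_fam)  # Zipf-ish family sizes
  fam <- sample.int(n_fam, n, replace = TRUE, prob = w / sum(w))
  ord <- (fam - 1L) %/% 3L + 1L
  cls <- (ord - 1L) %/% 3L + 1L
  phy <- (cls - 1L) %/% 4L + 1L
  tibble(
    otu_id = otu_ids,
    lineage = paste("Bacteria",
                    paste0("Phylum_", phy),
                    paste0("Class_", cls),
                    paste0("Order_", ord),
                    paste0("Family_", fam),
                    paste0("Genus_", seq_len(n)),
                    sep = ";")
  )
}

#' Write a simulated community to disk
#'
#' Writes the OTU table (TSV), tree (newick), taxonomy (TSV) and a JSON
#' sidecar of the generator parameters into `dir`.
#'
#' @param sim A `grain_community` from [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_community <- function(sim, dir) {
  if (!inherits(sim, "grain_community")) abort("`sim` must come from simulate_community().")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table = file.path(dir, "otu_table.tsv"),
    tree = file.path(dir, "tree.nwk"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    params = file.path(dir, "community_params.json")
  )
  write_otu_table(sim$table, paths[["table"]])
  ape::write.tree(sim$tree, paths[["tree"]])
  write_taxonomy(sim$taxonomy, paths[["taxonomy"]])
  jsonlite::write_json(unclass(sim$model), paths[["params"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Spatial model for synthetic cell point patterns
#'
#' Parameter block for [simulate_point_pattern()]. Defaults emulate the
#' observed colonization contrast on grain surfaces: protected depressions
#' densely and clumpily populated (nearest neighbours well under a
#' micrometre), exposed convex surfaces largely bare (nearest neighbours of a
#' few micrometres). Protected patches are modelled as non-overlapping disks
#' covering about `protected_patch_fraction` of the window.
#'
#' @param window Rectangle `c(xmin, xmax, ymin, ymax)` in um
#'   (default a 200 x 200 um field).
#' @param exposed_intensity,protected_intensity Cells per um^2 in each patch
#'   class (defaults 0.012 and 0.4).
#' @param protected_patch_fraction Fraction of the window belonging to
#'   protected patches (default 0.3).
#' @param cluster_scale Gaussian dispersion (um) of daughter cells around
#'   cluster centres; 0 gives a homogeneous Poisson pattern (default 2).
#' @param points_per_cluster Mean cells per cluster for the clustered
#'   construction (default 8).
#' @param touching_radius Cells closer than this (um) are flagged touching
#'   (default 1).
#' @param seed Integer seed (default 1).
#' @return A validated `spatial_model` list.
#' @export
spatial_model <- function(window = c(0, 200, 0, 200),
                          exposed_intensity = 0.012,
                          protected_intensity = 0.4,
                          protected_patch_fraction = 0.3,
                          cluster_scale = 2,
                          points_per_cluster = 8,
                          touching_radius = 1,
                          seed = 1) {
  if (length(window) != 4L || window[2] <= window[1] || window[4] <= window[3]) {
    abort("`window` must be c(xmin, xmax, ymin, ymax) with positive area.")
  }
  if (exposed_intensity < 0 || protected_intensity < 0) {
    abort("intensities must be non-negative.")
  }
  if (!is_proportion(protected_patch_fraction)) {
    abort("`protected_patch_fraction` must be in [0, 1].")
  }
  if (cluster_scale < 0) abort("`cluster_scale` must be non-negative.")
  structure(
    list(window = as.numeric(window),
         exposed_intensity = exposed_intensity,
         protected_intensity = protected_intensity,
         protected_patch_fraction = protected_patch_fraction,
         cluster_scale = cluster_scale,
         points_per_cluster = points_per_cluster,
         touching_radius = touching_radius,
         seed = seed),
    class = "spatial_model"
  )
}

#' Simulate a cell point pattern with exposed and protected patches
#'
#' Places non-overlapping protected disks covering approximately
#' `protected_patch_fraction` of the window, then populates each patch class
#' at its own intensity: a homogeneous Poisson process when
#' `cluster_scale = 0`, otherwise a Thomas-type cluster process (Poisson
#' parents, Poisson(`points_per_cluster`) daughters displaced by an isotropic
#' Gaussian of scale `cluster_scale`, thinned to the patch class's own
#' region). Touching flags are derived from `touching_radius` within patch
#' class.
#'
#' @param model A [spatial_model()].
#' @return A [point_pattern()] tibble with columns `x_um`, `y_um`, `patch`,
#'   `touching`; attributes `window`, `model` and `protected_fraction` (the
#'   realized patch area fraction).
#' @export
simulate_point_pattern <- function(model = spatial_model()) {
  if (!inherits(model, "spatial_model")) abort("`model` must come from spatial_model().")
  w <- model$window
  wx <- w[2] - w[1]
  wy <- w[4] - w[3]
  area <- wx * wy

  with_seed(model$seed, {
    if (model$protected_patch_fraction >= 1) {
      # whole window protected: homogeneous habitat, useful for analytic checks
      prot <- simulate_class_points(model, w, area, area,
                                    function(x, y) rep(TRUE, length(x)),
                                    intensity = model$protected_intensity)
      out <- point_pattern(dplyr::mutate(prot, patch = "protected"), window = w,
                           touching_radius = model$touching_radius)
      attr(out, "model") <- model
      attr(out, "protected_fraction") <- 1
      return(out)
    }
    # protected patches: disks on a jittered grid so they never overlap
    r <- min(wx, wy) / 20
    spacing <- 2.2 * r
    gx <- seq(w[1] + spacing / 2, w[2] - spacing / 2, by = spacing)
    gy <- seq(w[3] + spacing / 2, w[4] - spacing / 2, by = spacing)
    grid <- expand.grid(x = gx, y = gy)
    n_disks <- min(nrow(grid),
                   round(model$protected_patch_fraction * area / (pi * r^2)))
    centres <- grid[sample.int(nrow(grid), n_disks), , drop = FALSE]
    jit <- (spacing - 2 * r) / 2
    if (n_disks > 0 && jit > 0) {
      centres$x <- centres$x + runif(n_disks, -jit, jit)
      centres$y <- centres$y + runif(n_disks, -jit, jit)
    }
    protected_area <- n_disks * pi * r^2
    in_protected <- function(x, y) {
      if (n_disks == 0) return(rep(FALSE, length(x)))
      inside <- rep(FALSE, length(x))
      for (i in seq_len(n_disks)) {
        inside <- inside |
          ((x - centres$x[i])^2 + (y - centres$y[i])^2 <= r^2)
      }
      inside
    }

    prot <- simulate_class_points(model, w, area, protected_area,
                                  function(x, y) in_protected(x, y),
                                  intensity = model$protected_intensity)
    expo <- simulate_class_points(model, w, area, area - protected_area,
                                  function(x, y) !in_protected(x, y),
                                  intensity = model$exposed_intensity)
    df <- dplyr::bind_rows(
      dplyr::mutate(prot, patch = "protected"),
      dplyr::mutate(expo, patch = "exposed")
    )
    out <- point_pattern(df, window = w, touching_radius = model$touching_radius)
    attr(out, "model") <- model
    attr(out, "protected_fraction") <- protected_area / area
    out
  })
}

# Points of one patch class: homogeneous Poisson (cluster_scale = 0) or a
# Thomas-type cluster process, both thinned to the class's own region by
# rejection from uniform window proposals.
simulate_class_points <- function(model, w, area, class_area, keep_fun, intensity) {
  if (intensity == 0 || class_area == 0) {
    return(tibble(x_um = numeric(0), y_um = numeric(0)))
  }
  accept <- function(n) {
    got_x <- numeric(0)
    got_y <- numeric(0)
    while (length(got_x) < n) {
      m <- max(100L, ceiling((n - length(got_x)) * area / class_area * 1.5))
      px <- runif(m, w[1], w[2])
      py <- runif(m, w[3], w[4])
      keep <- keep_fun(px, py)
      got_x <- c(got_x, px[keep])
      got_y <- c(got_y, py[keep])
    }
    tibble(x_um = got_x[seq_len(n)], y_um = got_y[seq_len(n)])
  }
  if (model$cluster_scale == 0) {
    return(accept(rpois(1, intensity * class_area)))
  }
  mu <- model$points_per_cluster
  parents <- accept(rpois(1, intensity * class_area / mu))
  if (nrow(parents) == 0) return(parents)
  kids <- purrr::map(seq_len(nrow(parents)), function(i) {
    nk <- rpois(1, mu)
    if (nk == 0) return(NULL)
    kx <- parents$x_um[i] + rnorm(nk, 0, model$cluster_scale)
    ky <- parents$y_um[i] + rnorm(nk, 0, model$cluster_scale)
    ok <- kx >= w[1] & kx <= w[2] & ky >= w[3] & ky <= w[4]
    ok <- ok & keep_fun(kx, ky)
    tibble(x_um = kx[ok], y_um = ky[ok])
  })
  dplyr::bind_rows(kids)
}
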