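#' Cell point patterns on grain surfaces
#'
#' A point pattern is a tibble of cell coordinates on a maximum-intensity
#' projection of a grain surface: columns `x_um`, `y_um`, a two-level
#' `patch` factor (`"exposed"` or `"protected"` surface), and a logical
#' `touching` column flagging cells the detector could not separate from a
#' neighbour. `point_pattern()` validates a data frame into this form,
#' deriving `touching` from `touching_radius` (any cell with a same-pattern
#' neighbour closer than the radius) when the column is absent.
#'
#' @param df Data frame with `x_um`, `y_um`, optional `patch` and `touching`.
#' @param window Rectangle `c(xmin, xmax, ymin, ymax)` in um; defaults to the
#'   bounding box of the points.
#' @param touching_radius Distance (um) below which two cells are flagged as
#'   touching when no `touching` column is supplied; roughly one cell
#'   diameter. Default 1.
#' @return A `point_pattern` tibble with a `window` attribute.
#' @export
point_pattern <- function(df, window = NULL, touching_radius = 1) {
  if (!all(c("x_um", "y_um") %in% names(df))) {
    abort("`df` must have columns `x_um` and `y_um`.")
  }
  out <- as_tibble(df)
  if (!"patch" %in% names(out)) out$patch <- "protected"
  bad <- setdiff(unique(out$patch), c("exposed", "protected"))
  if (length(bad)) {
    abort(paste0("`patch` must be \"exposed\" or \"protected\"; found: ",
                 paste(bad, collapse = ", ")))
  }
  if (is.null(window)) {
    if (nrow(out) == 0L) abort("`window` is required for an empty pattern.")
    window <- c(min(out$x_um), max(out$x_um), min(out$y_um), max(out$y_um))
  }
  if (length(window) != 4L || window[2] < window[1] || window[4] < window[3]) {
    abort("`window` must be c(xmin, xmax, ymin, ymax) with xmax >= xmin, ymax >= ymin.")
  }
  inside <- out$x_um >= window[1] & out$x_um <= window[2] &
    out$y_um >= window[3] & out$y_um <= window[4]
  if (!all(inside)) abort("all points must lie inside `window`.")
  if (!"touching" %in% names(out)) {
    out$touching <- FALSE
    for (cl in unique(out$patch)) {
      i <- which(out$patch == cl)
      if (length(i) >= 2) {
        d <- nn_dist(out$x_um[i], out$y_um[i])
        out$touching[i] <- d < touching_radius
      }
    }
  }
  structure(out, class = c("point_pattern", class(out)), window = window)
}

#' Nearest-neighbour cell-cell distances by patch class
#'
#' For every retained cell, the Euclidean distance to its nearest retained
#' neighbour within the same patch class (exposed and protected surfaces are
#' summarised separately, since their colonization densities differ roughly
#' tenfold). Touching cells — pairs the detector could not separate — are
#' excluded by default, which biases the distances upward exactly as the
#' imaging analysis does. No edge correction is applied.
#'
#' @param pattern A [point_pattern()] tibble (any data frame with the same
#'   columns is accepted).
#' @param exclude_touching Drop cells flagged `touching` before measuring
#'   (default `TRUE`).
#' @param by_patch Summarise within patch class (default `TRUE`); if `FALSE`
#'   all cells form one class `"all"`.
#' @return `nn_distances()`: a tibble of retained cells with their `nn_um`
#'   distance. `nn_summary()`: one row per patch class with `n_cells`,
#'   `mean_nn_um`, `sd_nn_um`, `min_um`, `max_um` (statistics `NA` when a
#'   class retains fewer than 2 cells).
#' @export
nn_distances <- function(pattern, exclude_touching = TRUE, by_patch = TRUE) {
  df <- as_tibble(pattern)
  if (!"touching" %in% names(df)) df$touching <- FALSE
  if (!"patch" %in% names(df) || !by_patch) df$patch <- "all"
  if (exclude_touching) df <- df[!df$touching, , drop = FALSE]
  parts <- split(df, df$patch)
  dplyr::bind_rows(lapply(parts, function(p) {
    if (nrow(p) < 2) {
      p$nn_um <- rep(NA_real_, nrow(p))
    } else {
      p$nn_um <- nn_dist(p$x_um, p$y_um)
    }
    p
  }))
}

#' @rdname nn_distances
#' @export
nn_summary <- function(pattern, exclude_touching = TRUE, by_patch = TRUE) {
  d <- nn_distances(pattern, exclude_touching = exclude_touching, by_patch = by_patch)
  dplyr::summarise(
    dplyr::group_by(d, .data$patch),
    n_cells = dplyr::n(),
    mean_nn_um = if (dplyr::n() >= 2) mean(.data$nn_um) else NA_real_,
    sd_nn_um = if (dplyr::n() >= 2) sd(.data$nn_um) else NA_real_,
    min_um = if (dplyr::n() >= 2) min(.data$nn_um) else NA_real_,
    max_um = if (dplyr::n() >= 2) max(.data$nn_um) else NA_real_,
    .groups = "drop"
  )
}

# Grid-binned nearest-neighbour distances: O(n) expected for roughly uniform
# patterns. Falls back to widening ring searches so it is exact for any
# configuration.
nn_dist <- function(x, y) {
  n <- length(x)
  if (n == 2L) {
    d <- sqrt((x[1] - x[2])^2 + (y[1] - y[2])^2)
    return(c(d, d))
  }
  span <- max(max(x) - min(x), max(y) - min(y), .Machine$double.eps)
  cell <- span / max(1, floor(sqrt(n)))
  ix <- floor((x - min(x)) / cell)
  iy <- floor((y - min(y)) / cell)
  key <- paste(ix, iy)
  bins <- split(seq_len(n), key)
  nx <- max(ix)
  ny <- max(iy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    ring <- 0L
    repeat {
      cand <- integer(0)
      for (dx in max(0, ix[i] - ring):min(nx, ix[i] + ring)) {
        for (dy in max(0, iy[i] - ring):min(ny, iy[i] + ring)) {
          if (ring > 0 && abs(dx - ix[i]) < ring && abs(dy - iy[i]) < ring) next
          b <- bins[[paste(dx, dy)]]
          if (!is.null(b)) cand <- c(cand, b)
        }
      }
      cand <- setdiff(cand, i)
      if (length(cand)) {
        best <- min(best, sqrt((x[cand] - x[i])^2 + (y[cand] - y[i])^2))
      }
      # a neighbour in ring r is guaranteed nearer than any in ring r+2
      if (is.finite(best) && best <= ring * cell) break
      if (ring > nx + ny) break
      ring <- ring + 1L
    }
    out[i] <- best
  }
  out
}

#' Theoretical spacings versus observed nearest-neighbour means
#'
#' Sets two theoretical scales for a colonization density `rho` beside the
#' observed per-class nearest-neighbour means: the square-lattice spacing
#' `sqrt(1 / rho)` (the spacing cells would have if spread evenly) and the
#' expected nearest-neighbour distance of a homogeneous Poisson process at
#' the same intensity, `1 / (2 sqrt(rho))`.
#'
#' @param density Colonization density in cells um^-2.
#' @param summaries Optional [nn_summary()] tibble of observed patterns.
#' @return A tibble with `lattice_spacing_um` and `poisson_mean_nn_um`,
#'   cross-joined with the observed summaries when given.
#' @examples
#' theoretical_vs_observed(0.09)  # 3.33 um lattice, 1.67 um Poisson
#' @export
theoretical_vs_observed <- function(density, summaries = NULL) {
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    abort("`density` must be a single positive number.")
  }
  theo <- tibble(
    lattice_spacing_um = sqrt(1 / density),
    poisson_mean_nn_um = 1 / (2 * sqrt(density))
  )
  if (is.null(summaries)) return(theo)
  dplyr::bind_cols(
    summaries[, intersect(c("patch", "n_cells", "mean_nn_um"), names(summaries))],
    theo[rep(1, nrow(summaries)), ]
  )
}

#' Read and write cell-coordinate tables
#'
#' CSV with columns `x_um`, `y_um`, `patch`, optional `touching` and
#' `grain_id`.
#'
#' @param path File path.
#' @param ... Passed to [point_pattern()] (e.g. `window`, `touching_radius`).
#' @export
read_point_pattern <- function(path, ...) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  point_pattern(df, ...)
}

#' @rdname read_point_pattern
#' @param pattern A point-pattern tibble.
#' @export
write_point_pattern <- function(pattern, path) {
  readr::write_csv(as_tibble(pattern), path, progress = FALSE)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.point_pattern <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                       colour = .data$patch)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "patch") +
    ggplot2::theme_minimal()
}
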