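#' Grain colonization geometry parameters
#'
#' Bundles the measured inputs of the colonization-geometry model: total cell
#' counts per cm^3 of sediment, grain surface area per cm^3 (from micro-CT),
#' the footprint of an average cell, the grain diameter (or range), and the
#' sediment porosity used by the packing route. Defaults are the measured
#' values for subtidal North Sea surface sand: 1.1e9 cells cm^-3, 1.2e10
#' um^2 cm^-3, a 0.43 um^2 cell footprint and 202-635 um grains. The default
#' porosity of 0.423 is a fitted value (back-solved so the packing route
#' reproduces the reported cells-per-grain range over 202-635 um grains at
#' two significant figures); it is not a measured input and should be
#' replaced when a measured porosity is available.
#'
#' @param cells_per_cm3 Total cell count per cm^3 sediment.
#' @param surface_area_um2_per_cm3 Grain surface area (um^2) per cm^3 sediment.
#' @param cell_footprint_um2 Area covered by an average attached cell (um^2).
#' @param grain_diameter_um Grain diameter(s) in um; a vector gives a range.
#' @param porosity Sediment porosity in (0, 1); only the packing route uses it.
#' @return A `geometry_params` list.
#' @export
geometry_params <- function(cells_per_cm3 = 1.1e9,
                            surface_area_um2_per_cm3 = 1.2e10,
                            cell_footprint_um2 = 0.43,
                            grain_diameter_um = c(202, 635),
                            porosity = 0.423) {
  stopifnot(
    is.numeric(cells_per_cm3), length(cells_per_cm3) == 1L, cells_per_cm3 > 0,
    is.numeric(surface_area_um2_per_cm3), length(surface_area_um2_per_cm3) == 1L,
    surface_area_um2_per_cm3 > 0,
    is.numeric(cell_footprint_um2), length(cell_footprint_um2) == 1L,
    cell_footprint_um2 > 0,
    is.numeric(grain_diameter_um), length(grain_diameter_um) >= 1L,
    all(grain_diameter_um > 0)
  )
  if (!is.numeric(porosity) || length(porosity) != 1L ||
      porosity <= 0 || porosity >= 1) {
    abort("`porosity` must lie strictly between 0 and 1.")
  }
  structure(
    list(
      cells_per_cm3 = cells_per_cm3,
      surface_area_um2_per_cm3 = surface_area_um2_per_cm3,
      cell_footprint_um2 = cell_footprint_um2,
      grain_diameter_um = grain_diameter_um,
      porosity = porosity
    ),
    class = "geometry_params"
  )
}

#' Colonization density on grain surfaces
#'
#' Cells per um^2 of grain surface: total cells per cm^3 of sediment divided
#' by grain surface area per cm^3.
#'
#' @param cells_per_cm3 Cells per cm^3 sediment.
#' @param surface_area_um2_per_cm3 Grain surface area (um^2) per cm^3.
#' @return Density in cells um^-2 (unrounded; see [colonization_report()] for
#'   the conventional two-decimal reporting).
#' @examples
#' colonization_density(1.1e9, 1.2e10)  # ~0.09 cells / um^2
#' @export
colonization_density <- function(cells_per_cm3, surface_area_um2_per_cm3) {
  if (surface_area_um2_per_cm3 <= 0) abort("surface area must be positive.")
  cells_per_cm3 / surface_area_um2_per_cm3
}

#' Area per cell, lattice spacing and colonized surface fraction
#'
#' From a colonization density `rho`: each cell claims `1 / rho` um^2; on a
#' square-lattice convention the theoretical distance between two cells is
#' `sqrt(1 / rho)`; and a cell footprint `a` covers the fraction `a * rho` of
#' the surface.
#'
#' @param density Colonization density in cells um^-2 (must be > 0).
#' @param footprint Cell footprint in um^2.
#' @return A one-row tibble: `area_per_cell_um2`, `spacing_um`,
#'   `colonized_fraction`.
#' @examples
#' spacing_and_fraction(0.09, 0.43)
#' @export
spacing_and_fraction <- function(density, footprint) {
  if (!is.numeric(density) || density <= 0) abort("`density` must be positive.")
  tibble(
    area_per_cell_um2 = 1 / density,
    spacing_um = sqrt(1 / density),
    colonized_fraction = footprint * density
  )
}

#' Cells per grain: surface-area route
#'
#' Models a grain as a sphere of the given diameter and multiplies its
#' surface area `pi * d^2` by the colonization density.
#'
#' @param diameter_um Grain diameter(s) in um.
#' @param density Colonization density in cells um^-2.
#' @return Cells per grain (unrounded), vectorized over `diameter_um`.
#' @examples
#' cells_per_grain_surface(c(202, 635), 0.09)  # ~1.2e4 and ~1.1e5
#' @export
cells_per_grain_surface <- function(diameter_um, density) {
  if (any(diameter_um <= 0)) abort("`diameter_um` must be positive.")
  pi * diameter_um^2 * density
}

#' Sand grains per cm^3 of sediment
#'
#' Packing model: the solid fraction `1 - porosity` of a cm^3 divided by the
#' volume of one spherical grain, `pi * d^3 / 6` (d converted from um to cm).
#'
#' @param diameter_um Grain diameter(s) in um.
#' @param porosity Sediment porosity in (0, 1).
#' @return Grains per cm^3, vectorized over `diameter_um`.
#' @export
grains_per_cm3 <- function(diameter_um, porosity) {
  if (!is.numeric(porosity) || length(porosity) != 1L ||
      porosity <= 0 || porosity >= 1) {
    abort("`porosity` must lie strictly between 0 and 1.")
  }
  if (any(diameter_um <= 0)) abort("`diameter_um` must be positive.")
  d_cm <- diameter_um * 1e-4
  (1 - porosity) / (pi * d_cm^3 / 6)
}

#' Cells per grain: packing route
#'
#' Divides total cells per cm^3 by the number of grains per cm^3 from
#' [grains_per_cm3()].
#'
#' @param cells_per_cm3 Cells per cm^3 sediment.
#' @inheritParams grains_per_cm3
#' @return Cells per grain (unrounded), vectorized over `diameter_um`.
#' @export
cells_per_grain_packing <- function(cells_per_cm3, diameter_um, porosity) {
  cells_per_cm3 / grains_per_cm3(diameter_um, porosity)
}

#' Full colonization-geometry report
#'
#' Evaluates the whole geometric model for a parameter set: colonization
#' density, area per cell, lattice spacing, colonized surface fraction, and
#' cells per grain by both the surface-area and the packing route for each
#' grain diameter. Raw (unrounded) values are kept in the object; `tidy()`
#' returns the per-diameter table and `glance()` the scalar quantities, each
#' with optional conventional rounding (density to two decimals, area and
#' spacing to one decimal, colonized fraction to a whole percent, cells per
#' grain to two significant figures) applied at the reporting layer only.
#'
#' The cell count and surface area are each known to two significant figures,
#' so the density is only meaningful to two decimals; by convention the
#' report rounds the density to `density_digits` decimals before propagating
#' it into the derived quantities (set `density_digits = NULL` to propagate
#' the raw ratio instead). Both the raw and the propagated density are kept.
#'
#' @param params A [geometry_params()] object.
#' @param density_digits Decimals the density is rounded to before being
#'   propagated downstream (default 2; `NULL` disables).
#' @return A `geometry_report` list.
#' @examples
#' rep <- colonization_report(geometry_params())
#' glance(rep)
#' tidy(rep, rounded = TRUE)
#' @export
colonization_report <- function(params = geometry_params(), density_digits = 2) {
  if (!inherits(params, "geometry_params")) abort("`params` must come from geometry_params().")
  rho_raw <- colonization_density(params$cells_per_cm3, params$surface_area_um2_per_cm3)
  rho <- if (is.null(density_digits)) rho_raw else round(rho_raw, density_digits)
  sf <- spacing_and_fraction(rho, params$cell_footprint_um2)
  d <- params$grain_diameter_um
  structure(
    list(
      params = params,
      density_cells_per_um2_raw = rho_raw,
      density_cells_per_um2 = rho,
      area_per_cell_um2 = sf$area_per_cell_um2,
      spacing_um = sf$spacing_um,
      colonized_fraction = sf$colonized_fraction,
      per_diameter = tibble(
        diameter_um = d,
        cells_surface_route = cells_per_grain_surface(d, rho),
        grains_per_cm3 = grains_per_cm3(d, params$porosity),
        cells_packing_route = cells_per_grain_packing(params$cells_per_cm3, d,
                                                      params$porosity)
      )
    ),
    class = "geometry_report"
  )
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("Grain colonization geometry\n")
  cat(sprintf("  density:            %.2f cells/um^2\n", x$density_cells_per_um2))
  cat(sprintf("  area per cell:      %.1f um^2\n", x$area_per_cell_um2))
  cat(sprintf("  lattice spacing:    %.1f um\n", x$spacing_um))
  cat(sprintf("  colonized fraction: %.0f%%\n", 100 * x$colonized_fraction))
  d <- x$per_diameter
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  d = %4.0f um: %s cells (surface route), %s cells (packing route)\n",
                d$diameter_um[i],
                format(round_signif(d$cells_surface_route[i]), big.mark = ","),
                format(round_signif(d$cells_packing_route[i]), big.mark = ",")))
  }
  invisible(x)
}

#' @rdname colonization_report
#' @param x A `geometry_report`.
#' @param rounded Apply the conventional reporting precision (default `FALSE`).
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.geometry_report <- function(x, rounded = FALSE, ...) {
  out <- x$per_diameter
  if (rounded) {
    out$cells_surface_route <- round_signif(out$cells_surface_route, 2)
    out$cells_packing_route <- round_signif(out$cells_packing_route, 2)
    out$grains_per_cm3 <- round_signif(out$grains_per_cm3, 2)
  }
  out
}

#' @rdname colonization_report
#' @exportS3Method generics::glance
glance.geometry_report <- function(x, rounded = FALSE, ...) {
  out <- tibble(
    density_cells_per_um2 = x$density_cells_per_um2,
    area_per_cell_um2 = x$area_per_cell_um2,
    spacing_um = x$spacing_um,
    colonized_fraction = x$colonized_fraction,
    colonized_percent = 100 * x$colonized_fraction
  )
  if (rounded) {
    out$density_cells_per_um2 <- round(out$density_cells_per_um2, 2)
    out$area_per_cell_um2 <- round(out$area_per_cell_um2, 1)
    out$spacing_um <- round(out$spacing_um, 1)
    out$colonized_percent <- round(out$colonized_percent)
    out$colonized_fraction <- out$colonized_percent / 100
  }
  out
}
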