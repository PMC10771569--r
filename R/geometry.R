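#' Well-plate hydrogel geometries
#'
#' Builds the axial cross-section of a cylindrical hydrogel cast in a
#' standard well plate, discretized on a regular Cartesian grid of cell
#' centers. Coordinates are 2D (x, y) in cm with the well axis at the
#' origin; a grid cell belongs to the domain (and to a region) iff its
#' center does.
#'
#' Nominal cross-section areas are 190 mm2 (24-well), 380 mm2 (12-well)
#' and 950 mm2 (6-well); the disc diameter is derived from the area. The
#' co-culture configuration (24-well only) is a two-region annular
#' phantom: an inner tumor-cell core of diameter 1.0 cm surrounded by an
#' endothelial ring of outer diameter 1.56 cm, with default constant
#' conductivities of 1.26 and 1.46 S/m respectively.
#'
#' @param plate_format One of 24, 12, 6.
#' @param coculture Logical; build the two-region core/ring phantom
#'   (supported for the 24-well format only).
#' @param grid_spacing Grid spacing in cm (cell edge length). Must be
#'   positive and at most a tenth of the outer diameter. Default 0.01 cm.
#' @param conductivity Optional. A single \code{\link{conductivity_model}}
#'   for monoculture discs, or a named list with entries \code{core} and
#'   \code{ring} for co-cultures. Monoculture default is the
#'   field-dependent liver model (0.4 to 1.6 S/m).
#' @param height Modeled electrode height in cm (used for currents and
#'   resistances). Default 0.3 cm.
#' @return A \code{hydrogel_geometry}: grid coordinates \code{x}, \code{y}
#'   (cm), logical \code{inside} matrix, integer \code{region} matrix
#'   (1 = bulk or core, 2 = ring), \code{region_sigma} (list of
#'   conductivity models indexed by region), and scalar metadata.
#' @examples
#' g <- make_well_geometry(24)
#' sum(g$inside) * g$cell_area_mm2  # ~190 mm2
#' @export
make_well_geometry <- function(plate_format = c(24, 12, 6), coculture = FALSE,
                               grid_spacing = 0.01, conductivity = NULL,
                               height = 0.3) {
  plate_format <- match.arg(as.character(plate_format[1]), c("24", "12", "6"))
  nominal_area_mm2 <- c(`24` = 190, `12` = 380, `6` = 950)[[plate_format]]
  if (coculture && plate_format != "24")
    stop("co-culture phantoms are supported for the 24-well format only")
  if (coculture) {
    outer_d <- 1.56            # endothelial ring outer diameter, cm
    inner_d <- 1.0             # tumor-cell core diameter, cm
  } else {
    outer_d <- 2 * sqrt(nominal_area_mm2 / pi) / 10  # cm from mm2
    inner_d <- NA_real_
  }
  if (!is.finite(grid_spacing) || grid_spacing <= 0 ||
      grid_spacing > outer_d / 10)
    stop("grid_spacing must be > 0 and at most 1/10 of the outer diameter")

  grid <- square_grid(outer_d / 2, grid_spacing)
  r2 <- outer(grid$x^2, grid$y^2, `+`)
  inside <- r2 <= (outer_d / 2)^2
  region <- matrix(NA_integer_, nrow(inside), ncol(inside))
  region[inside] <- 1L
  if (coculture) {
    region[inside & r2 > (inner_d / 2)^2] <- 2L
    if (is.null(conductivity))
      conductivity <- list(core = conductivity_model(1.26),
                           ring = conductivity_model(1.46))
    region_sigma <- list(conductivity$core, conductivity$ring)
    region_names <- c("core", "ring")
  } else {
    if (is.null(conductivity))
      conductivity <- conductivity_model(0.4, 1.6, "field_dependent")
    if (inherits(conductivity, "conductivity_model"))
      conductivity <- list(conductivity)
    region_sigma <- conductivity[1]
    region_names <- "bulk"
  }
  structure(
    list(shape = if (coculture) "annulus" else "disc",
         plate_format = as.integer(plate_format),
         nominal_area_mm2 = nominal_area_mm2,
         outer_diameter = outer_d, inner_diameter = inner_d,
         height = height, grid_spacing = grid_spacing,
         x = grid$x, y = grid$y, inside = inside, region = region,
         region_names = region_names, region_sigma = region_sigma,
         cell_area_mm2 = (grid_spacing * 10)^2),
    class = "hydrogel_geometry")
}

# Symmetric cell-center grid covering [-R, R]: even count, centers at
# +/-(k - 1/2) h, so the lattice is invariant under x -> -x and 90-degree
# rotation. Extends one cell beyond R so boundary cells are never clipped.
square_grid <- function(R, h) {
  n <- 2L * (ceiling(R / h) + 1L)
  x <- (seq_len(n) - (n + 1) / 2) * h
  list(x = x, y = x, n = n)
}

#' @export
print.hydrogel_geometry <- function(x, ...) {
  cat(sprintf("<hydrogel_geometry> %s, %d-well (nominal %g mm2)\n",
              x$shape, x$plate_format, x$nominal_area_mm2))
  cat(sprintf("  outer diameter %.3f cm%s, grid %g cm (%d x %d, %d cells inside)\n",
              x$outer_diameter,
              if (is.finite(x$inner_diameter))
                sprintf(", core diameter %.3f cm", x$inner_diameter) else "",
              x$grid_spacing, length(x$x), length(x$y), sum(x$inside)))
  invisible(x)
}

#' Discretized cross-section area
#'
#' Cell-counting area of the domain or of one region, in mm2.
#'
#' @param geometry A \code{hydrogel_geometry}.
#' @param region Optional region index (1 = bulk/core, 2 = ring).
#' @return Area in mm2.
#' @export
domain_area <- function(geometry, region = NULL) {
  stopifnot(inherits(geometry, "hydrogel_geometry"))
  n <- if (is.null(region)) sum(geometry$inside)
       else sum(geometry$region == region, na.rm = TRUE)
  n * geometry$cell_area_mm2
}

#' Needle-electrode layouts
#'
#' Places blunt-tip needle electrodes (modeled as cylinders of radius
#' \code{electrode_radius}) in a symmetric layout centered on the well
#' axis: a collinear pair, an equilateral triangle, or an axis-aligned
#' square of side \code{spacing}. Square corners are labelled
#' counterclockwise (E1 bottom-left), so edge-sharing pairs are
#' E1-E2, E2-E3, E3-E4 and E1-E4.
#'
#' @param geometry A \code{\link{make_well_geometry}} result.
#' @param layout \code{"pair"}, \code{"triangle"} or \code{"square"}.
#' @param spacing Electrode interspace in cm (pair distance, triangle
#'   side, square side). Defaults: 0.8 (pair), 0.9 (triangle), 1.4
#'   (square).
#' @param electrode_radius Needle radius in cm; default 0.0455 cm
#'   (G19 needle, 0.91 mm outer diameter).
#' @param modeled_height Electrode height in cm used for current
#'   integration; defaults to the geometry height (0.3 cm).
#' @return An \code{electrode_config} with a positions matrix (cm),
#'   labels E1..En, radius and height.
#' @export
place_electrodes <- function(geometry, layout = c("pair", "triangle", "square"),
                             spacing = NULL, electrode_radius = 0.0455,
                             modeled_height = NULL) {
  stopifnot(inherits(geometry, "hydrogel_geometry"))
  layout <- match.arg(layout)
  if (is.null(spacing))
    spacing <- c(pair = 0.8, triangle = 0.9, square = 1.4)[[layout]]
  if (!is.finite(spacing) || spacing <= 2 * electrode_radius)
    stop("spacing must exceed the electrode diameter")
  s <- spacing
  pos <- switch(layout,
    pair = rbind(c(-s / 2, 0), c(s / 2, 0)),
    # equilateral triangle, centroid at the origin, one vertex on +y
    triangle = {
      rc <- s / sqrt(3)
      ang <- pi / 2 + 2 * pi * (0:2) / 3
      cbind(rc * cos(ang), rc * sin(ang))
    },
    # counterclockwise from bottom-left so edges are consecutive labels
    square = rbind(c(-s / 2, -s / 2), c(s / 2, -s / 2),
                   c(s / 2, s / 2), c(-s / 2, s / 2)))
  colnames(pos) <- c("x", "y")
  rownames(pos) <- paste0("E", seq_len(nrow(pos)))
  # one electrode-radius wall clearance: center within R - 2 * radius
  R <- geometry$outer_diameter / 2
  if (any(sqrt(rowSums(pos^2)) > R - 2 * electrode_radius))
    stop(sprintf(
      "electrode placement error: layout '%s' with spacing %g cm does not fit the %.2f cm well with one electrode-radius wall clearance",
      layout, spacing, geometry$outer_diameter))
  d <- as.matrix(stats::dist(pos))
  if (any(d[upper.tri(d)] <= 2 * electrode_radius))
    stop("electrode placement error: electrodes overlap")
  structure(
    list(positions = pos, labels = rownames(pos), layout = layout,
         spacing = spacing, electrode_radius = electrode_radius,
         modeled_height = if (is.null(modeled_height)) geometry$height
                          else modeled_height),
    class = "electrode_config")
}

#' @export
print.electrode_config <- function(x, ...) {
  cat(sprintf("<electrode_config> %s layout, %d needles, spacing %g cm, radius %g cm\n",
              x$layout, nrow(x$positions), x$spacing, x$electrode_radius))
  invisible(x)
}

#' Enumerate electrode pairs
#'
#' All unordered electrode pairs, or only the adjacent (edge-sharing)
#' pairs of a square layout. For four needles in a square this yields the
#' four adjacent pairs (interspace = side) and six pairs in total
#' (including the two opposite, diagonal pairs).
#'
#' @param config An \code{\link{place_electrodes}} result.
#' @param mode \code{"all"} (every pair, n(n-1)/2) or \code{"adjacent"}
#'   (square layouts only).
#' @return A list of length-2 character vectors of electrode labels, in
#'   lexicographic order.
#' @export
enumerate_pairs <- function(config, mode = c("all", "adjacent")) {
  stopifnot(inherits(config, "electrode_config"))
  mode <- match.arg(mode)
  labs <- sort(config$labels)
  if (length(labs) < 2) stop("need at least two electrodes")
  cmb <- utils::combn(labs, 2, simplify = FALSE)
  if (mode == "all") return(cmb)
  if (config$layout != "square")
    stop("mode = 'adjacent' is defined only for the square layout")
  d <- as.matrix(stats::dist(config$positions))
  keep <- vapply(cmb, function(p) {
    isTRUE(all.equal(d[p[1], p[2]], config$spacing, tolerance = 1e-8))
  }, logical(1))
  cmb[keep]
}
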