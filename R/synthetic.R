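# Synthetic stand-ins for the wet-lab inputs: noisy ablation
# measurements, CT-like tumor masks, resistance readouts and live/dead
# z-stacks. Every generator is a pure function of (parameters, seed);
# the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Synthetic noisy ablation measurements
#'
#' Emulates replicate confocal ablation-area measurements: the forward
#' model's ablated measure at a known ground-truth threshold, perturbed
#' by multiplicative zero-mean Gaussian noise with coefficient of
#' variation \code{noise_cv} (replicate scatter grows with ablation
#' size), clipped to the physical range [0, domain measure].
#'
#' @param geometry Either a \code{hydrogel_geometry} (then
#'   \code{electrodes} and \code{plan} are required and the plan is
#'   delivered first) or a precomputed \code{\link{run_plan}} result.
#' @param electrodes,plan Needle layout and activation plan (ignored
#'   when \code{geometry} is already a cumulative field).
#' @param true_threshold Ground-truth IRE threshold, V/cm.
#' @param noise_cv Noise coefficient of variation (>= 0).
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @param sweep Unused by the generator; accepted so callers can share a
#'   precomputed sweep without it being consumed by \code{...}.
#' @param options Solver options.
#' @return A \code{synthetic_measurements} object: \code{areas} (mm2 or
#'   mm3), the ground truth, noise level, seed and provenance.
#' @export
synth_ablation_measurements <- function(geometry, electrodes = NULL,
                                        plan = NULL, true_threshold,
                                        noise_cv = 0.05, n = 9, seed = 1,
                                        sweep = NULL, options = list()) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  stopifnot(n >= 1)
  cum <- if (inherits(geometry, "cumulative_field")) geometry
         else run_plan(geometry, electrodes, plan, options)
  cell <- cell_measure(cum$geometry)
  vals <- cum$Emag[cum$geometry$inside]
  true_area <- sum(vals >= true_threshold) * cell$measure
  domain <- length(vals) * cell$measure
  eps <- with_seed(seed, stats::rnorm(n, mean = 0, sd = noise_cv))
  areas <- pmin(pmax(true_area * (1 + eps), 0), domain)
  structure(
    list(areas = areas, true_threshold = true_threshold,
         true_area = true_area, noise_cv = noise_cv, seed = seed,
         unit = cell$unit,
         provenance = list(
           n_activations = length(cum$plan$activations),
           shape = cum$geometry$shape,
           grid_spacing = cum$geometry$grid_spacing)),
    class = "synthetic_measurements")
}

#' @export
print.synthetic_measurements <- function(x, ...) {
  cat(sprintf(
    "<synthetic_measurements> n = %d, truth %.4g %s at %g V/cm, CV %g, seed %d\n",
    length(x$areas), x$true_area, x$unit, x$true_threshold, x$noise_cv,
    x$seed))
  invisible(x)
}

#' Synthetic bumpy tumor mask
#'
#' A star-convex voxelized tumor standing in for a CT segmentation: the
#' surface radius is \code{base_radius} modulated by a seeded low-order
#' angular perturbation of relative amplitude \code{bumpiness},
#' \deqn{r(\theta, \phi) = R (1 + b \, p(\theta, \phi)), \quad |p| \le 1,}
#' with p a normalized sum of \code{n_lobes} sectoral and zonal
#' harmonics. \code{bumpiness = 0} gives a sphere. A base radius of
#' 5.2 mm gives the ~0.6 cm3 volume of the small tumor mold; 11.5 and
#' 9.3 mm (lobed) approximate the medium and large molds.
#'
#' @param base_radius Mean tumor radius, mm (> voxel_size).
#' @param bumpiness Relative perturbation amplitude in [0, 0.5).
#' @param n_lobes Highest angular order of the perturbation (>= 1).
#' @param voxel_size Isotropic voxel edge, mm.
#' @param seed Integer seed for the perturbation coefficients.
#' @return A \code{\link{tumor_model}}.
#' @export
synth_tumor <- function(base_radius = 5.2, bumpiness = 0.15, n_lobes = 3,
                        voxel_size = 0.5, seed = 1) {
  if (!is.finite(base_radius) || base_radius <= voxel_size)
    stop("base_radius must exceed voxel_size")
  if (bumpiness < 0 || bumpiness >= 0.5)
    stop("bumpiness must lie in [0, 0.5)")
  if (n_lobes < 1) stop("n_lobes must be >= 1")
  co <- with_seed(seed, list(a = stats::runif(n_lobes, -1, 1),
                             psi = stats::runif(n_lobes, 0, 2 * pi),
                             c = stats::runif(n_lobes, -1, 1)))
  norm <- sum(abs(co$a)) + sum(abs(co$c))
  rmax <- base_radius * (1 + bumpiness)
  half <- ceiling(rmax / voxel_size) + 1L
  ax <- (seq(-half, half)) * voxel_size
  n <- length(ax)
  X <- array(ax, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  theta <- acos(ifelse(r > 0, Z / pmax(r, .Machine$double.eps), 1))
  phi <- atan2(Y, X)
  p <- array(0, dim(r))
  for (l in seq_len(n_lobes))
    p <- p + co$a[l] * cos(l * phi + co$psi[l]) * sin(theta)^l +
      co$c[l] * cos(l * theta)
  if (norm > 0) p <- p / norm
  surf <- base_radius * (1 + bumpiness * p)
  mask <- r <= surf
  tumor_model(mask, voxel_size)
}

#' Synthetic inter-electrode resistance readout
#'
#' Forward-models the resistance a pulse generator would report between
#' one electrode pair in a hydrogel of known constant conductivity, with
#' optional multiplicative Gaussian noise.
#'
#' @param geometry,electrodes Domain and needle layout.
#' @param pair Active (anode, cathode) labels.
#' @param true_sigma Ground-truth constant conductivity, S/m (> 0).
#' @param noise_cv Noise coefficient of variation (>= 0).
#' @param seed Integer seed.
#' @param amplitude Probe potential for the forward solve, V.
#' @return Resistance in ohms.
#' @export
synth_resistance <- function(geometry, electrodes, pair, true_sigma,
                             noise_cv = 0, seed = 1, amplitude = 100) {
  if (!is.finite(true_sigma) || true_sigma <= 0)
    stop("true_sigma must be > 0 (S/m)")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  geo <- set_constant_sigma(geometry, true_sigma)
  sol <- solve_field(geo, electrodes, pair, amplitude)
  R <- compute_resistance(sol)
  eps <- if (noise_cv > 0) with_seed(seed, stats::rnorm(1, 0, noise_cv)) else 0
  R * (1 + eps)
}

#' Render a binary live/dead z-stack from a cumulative field
#'
#' Emulates the confocal z-stack a viability scan would produce: each
#' slice is the binary mask of pixels whose cumulative field is at or
#' above the IRE threshold, rasterized at \code{pixel_size} by
#' nearest-neighbor sampling of the field grid. A 2D well field is
#' replicated across slices (the default 5 slices span the 2 mm scanned
#' thickness); a 3D field is sliced at evenly spaced z levels.
#'
#' @param cum A \code{\link{run_plan}} result.
#' @param threshold IRE threshold, V/cm.
#' @param n_slices Number of z slices (>= 1).
#' @param pixel_size Pixel edge, mm (> 0).
#' @return Integer 0/1 array (nx, ny, n_slices) with attributes
#'   \code{pixel_size_mm} and \code{slice_thickness_mm}.
#' @export
render_ablation_stack <- function(cum, threshold, n_slices = 5,
                                  pixel_size = 0.05) {
  stopifnot(inherits(cum, "cumulative_field"), n_slices >= 1)
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0 (mm)")
  g <- cum$geometry
  nd <- dim(cum$Emag)
  px_cm <- pixel_size / 10
  xs <- seq(min(g$x), max(g$x), by = px_cm)
  ys <- seq(min(g$y), max(g$y), by = px_cm)
  ix <- nearest_index(xs, g$x)
  iy <- nearest_index(ys, g$y)
  is3d <- length(nd) == 3
  zlev <- if (is3d) unique(round(seq(1, nd[3], length.out = n_slices)))
          else rep(1L, n_slices)
  slices <- lapply(seq_len(n_slices), function(k) {
    E <- if (is3d) cum$Emag[, , zlev[min(k, length(zlev))]] else cum$Emag
    m <- E[ix, iy, drop = FALSE] >= threshold
    m[is.na(m)] <- FALSE
    m
  })
  total_z <- if (is3d) dim(cum$Emag)[3] * g$voxel_size_mm[3] else 2
  structure(array(as.integer(unlist(slices)),
                  c(length(xs), length(ys), n_slices)),
            pixel_size_mm = pixel_size,
            slice_thickness_mm = total_z / n_slices)
}

nearest_index <- function(q, grid) {
  pmin(pmax(findInterval(q, grid - diff(grid[1:2]) / 2), 1L), length(grid))
}

#' Measure a binary z-stack
#'
#' The synthetic counterpart of an image-analysis area measurement:
#' per-slice ablated area as pixel count times pixel area, and unviable
#' volume as the sum of slice areas times the slice thickness.
#'
#' @param stack Binary (0/1 or logical) 3D array, slices along the third
#'   axis; attributes set by \code{\link{render_ablation_stack}} are used
#'   as defaults.
#' @param pixel_size Pixel edge, mm.
#' @param slice_thickness Slice thickness, mm.
#' @return List with \code{area_per_slice} (mm2) and \code{volume}
#'   (mm3).
#' @export
measure_stack <- function(stack,
                          pixel_size = attr(stack, "pixel_size_mm"),
                          slice_thickness = attr(stack, "slice_thickness_mm")) {
  if (is.null(dim(stack)) || length(dim(stack)) != 3)
    stop("stack must be a 3D array")
  if (!all(unique(as.vector(stack)) %in% c(0, 1, TRUE, FALSE)))
    stop("format error: stack is not binary")
  if (is.null(pixel_size) || is.null(slice_thickness))
    stop("pixel_size and slice_thickness are required")
  areas <- apply(stack, 3, function(s) sum(s > 0)) * pixel_size^2
  list(area_per_slice = areas, volume = sum(areas) * slice_thickness)
}
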