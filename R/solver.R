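#' Quasi-static field solver
#'
#' Solves the conduction problem div(sigma grad phi) = 0 on the regular
#' grid of a \code{\link{make_well_geometry}} or \code{\link{tumor_domain}}
#' domain, with Dirichlet conditions on the active electrode pair (anode
#' at \code{amplitude} volts, cathode grounded) and zero normal flux on
#' the insulating outer wall. Each electric pulse is treated as an
#' electrostatic conduction problem: pulse durations (100 us) are long
#' against the dielectric relaxation time of the hydrogel, so
#' displacement currents are neglected.
#'
#' Discretization is a finite-volume 5-point (2D) / 7-point (3D) stencil
#' with harmonic-mean face conductivities; the linear system is symmetric
#' positive definite and solved by a sparse Cholesky factorization.
#' Field-dependent conductivity is resolved by Picard (fixed-point)
#' iteration with under-relaxation: solve at the current sigma field,
#' re-evaluate sigma(|E|), repeat until the relative max-norm change of
#' |E| falls below \code{tol}.
#'
#' Electrodes not in \code{active_pair} are removed from the conductive
#' domain (treated as insulating holes) for the duration of the
#' activation. The cathode label \code{"wall"} grounds the outer wall
#' instead of a needle (Dirichlet 0 on wall cells), which turns a single
#' centered needle into the coaxial configuration with a known closed
#' form.
#'
#' @param geometry A \code{hydrogel_geometry} (2D well or 3D voxel
#'   domain).
#' @param electrodes An \code{\link{place_electrodes}} /
#'   \code{\link{electrode_config}} result.
#' @param active_pair Length-2 character: (anode label, cathode label);
#'   cathode may be \code{"wall"}.
#' @param amplitude Applied potential, V (>= 0).
#' @param options List: \code{tol} (Picard relative tolerance on |E|,
#'   default 1e-3), \code{max_iter} (default 50), \code{relax}
#'   (under-relaxation factor, default 0.5).
#' @return A \code{field_solution}: arrays \code{phi} (V), \code{Emag}
#'   (V/cm), \code{sigma} (S/m), the active-cell mask, total electrode
#'   \code{current} (A, per modeled height), \code{converged},
#'   \code{iterations}, \code{residual}.
#' @examples
#' g <- make_well_geometry(24, grid_spacing = 0.02,
#'                         conductivity = conductivity_model(0.027))
#' e <- place_electrodes(g, "pair", 0.8)
#' s <- solve_field(g, e, c("E1", "E2"), 1100)
#' max(s$Emag, na.rm = TRUE)
#' @export
solve_field <- function(geometry, electrodes, active_pair, amplitude,
                        options = list()) {
  stopifnot(inherits(geometry, "hydrogel_geometry"),
            inherits(electrodes, "electrode_config"))
  opt <- utils::modifyList(list(tol = 1e-3, max_iter = 50L, relax = 0.5),
                           options)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be >= 0 (V)")
  active_pair <- as.character(active_pair)
  if (length(active_pair) != 2)
    stop("active_pair must name (anode, cathode)")
  anode <- active_pair[1]
  cathode <- active_pair[2]
  known <- c(electrodes$labels, "wall")
  if (!all(c(anode, cathode) %in% known) || !(anode %in% electrodes$labels))
    stop("unknown electrode label in active_pair: ",
         paste(setdiff(c(anode, cathode), known), collapse = ", "))

  elec_cells <- electrode_cell_masks(geometry, electrodes)
  inactive <- setdiff(electrodes$labels, c(anode, cathode))
  active <- geometry$inside
  for (lab in inactive) active <- active & !elec_cells[[lab]]

  dir_mask <- array(FALSE, dim(active))
  dir_val <- array(0, dim(active))
  an_cells <- elec_cells[[anode]] & active
  if (!any(an_cells)) stop("anode '", anode, "' has no grid cells inside the domain")
  dir_mask[an_cells] <- TRUE
  dir_val[an_cells] <- amplitude
  if (cathode == "wall") {
    wall <- boundary_cells(active) & !an_cells
    dir_mask[wall] <- TRUE
  } else {
    ca_cells <- elec_cells[[cathode]] & active
    if (!any(ca_cells)) stop("cathode '", cathode, "' has no grid cells inside the domain")
    dir_mask[ca_cells] <- TRUE
  }

  h <- geometry$grid_spacing
  models <- geometry$region_sigma
  region <- geometry$region
  constant_only <- all(vapply(models, function(m) m$form == "constant",
                              logical(1)))
  sigma <- array(NA_real_, dim(active))
  for (r in seq_along(models))
    sigma[!is.na(region) & region == r] <- models[[r]]$sigma0

  phi <- array(0, dim(active))
  Emag <- array(0, dim(active))
  iter <- 0L
  residual <- 0
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    phi <- solve_linear_potential(active, dir_mask, dir_val, sigma)
    Emag_new <- gradient_magnitude(phi, active, h)
    if (constant_only || amplitude == 0) {
      Emag <- Emag_new
      converged <- TRUE
      break
    }
    scale <- max(Emag_new[active], 0)
    residual <- if (scale > 0)
      max(abs(Emag_new[active] - Emag[active])) / scale else 0
    Emag <- Emag_new
    if (residual < opt$tol) { converged <- TRUE; break }
    if (iter >= opt$max_iter) break
    sig_target <- array(NA_real_, dim(active))
    for (r in seq_along(models)) {
      cells <- !is.na(region) & region == r & active
      sig_target[cells] <- sigma_of_E(models[[r]], pmax(Emag[cells], 0))
    }
    upd <- !is.na(sig_target)
    sigma[upd] <- sigma[upd] + opt$relax * (sig_target[upd] - sigma[upd])
  }
  if (!converged)
    stop(sprintf(
      "field solve did not converge in %d Picard iterations (residual %.3g > tol %.3g)",
      iter, residual, opt$tol))

  sol <- structure(
    list(geometry = geometry, electrodes = electrodes,
         pair = c(anode = anode, cathode = cathode), amplitude = amplitude,
         phi = phi, Emag = Emag, sigma = sigma,
         active = active, dirichlet = dir_mask, anode_cells = an_cells,
         converged = converged, iterations = iter, residual = residual),
    class = "field_solution")
  sol$current <- electrode_current(sol)
  sol
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(
    "<field_solution> %s->%s at %g V: max |E| %.0f V/cm, current %.3g A, %d iteration(s)\n",
    x$pair["anode"], x$pair["cathode"], x$amplitude,
    max(x$Emag[x$active]), x$current, x$iterations))
  invisible(x)
}

# cells of each electrode: centers within electrode_radius of the needle
# axis (all z layers in 3D); falls back to the nearest cell center when
# the radius is below the grid resolution
electrode_cell_masks <- function(geometry, electrodes) {
  nd <- dim(geometry$inside)
  out <- list()
  inside2d <- apply_inside_2d(geometry)
  for (i in seq_len(nrow(electrodes$positions))) {
    p <- electrodes$positions[i, ]
    d2 <- outer((geometry$x - p[1])^2, (geometry$y - p[2])^2, `+`)
    m2 <- d2 <= electrodes$electrode_radius^2 & inside2d
    if (!any(m2)) {
      # needle thinner than the grid: snap to the nearest in-domain cell
      d2[!inside2d] <- Inf
      m2 <- d2 == min(d2)
    }
    mask <- if (length(nd) == 3) {
      array(rep(m2, nd[3]), nd)
    } else m2
    out[[electrodes$labels[i]]] <- mask
  }
  out
}

# 2D projection of the inside mask (any z)
apply_inside_2d <- function(geometry) {
  nd <- dim(geometry$inside)
  if (length(nd) == 2) geometry$inside
  else apply(geometry$inside, c(1, 2), any)
}

# active cells with at least one face neighbor outside the active set or
# outside the array
boundary_cells <- function(active) {
  nd <- dim(active)
  out <- array(FALSE, nd)
  for (k in seq_along(nd)) {
    for (s in c(-1L, 1L)) {
      nb <- neighbor_values(active, k, s, fill = FALSE)
      out <- out | (active & !nb)
    }
  }
  out
}

# values of the neighbor at offset s along axis k; `fill` outside bounds
neighbor_values <- function(arr, k, s, fill = NA) {
  nd <- dim(arr)
  idx <- lapply(nd, seq_len)
  src <- idx
  src[[k]] <- idx[[k]] + s
  keep <- src[[k]] >= 1 & src[[k]] <= nd[k]
  out <- array(fill, nd)
  dst <- idx; dst[[k]] <- idx[[k]][keep]; src[[k]] <- src[[k]][keep]
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(arr), src)))))
  out
}

# assemble and solve the SPD finite-volume system for the potential;
# grid-spacing factors cancel (2D) or are a common factor (3D), so face
# weights are plain harmonic-mean conductivities
solve_linear_potential <- function(active, dir_mask, dir_val, sigma) {
  nd <- dim(active)
  N <- prod(nd)
  unknown <- active & !dir_mask
  nu <- sum(unknown)
  phi <- array(0, nd)
  phi[dir_mask] <- dir_val[dir_mask]
  if (nu == 0) return(phi)
  umap <- rep(NA_integer_, N)
  umap[which(unknown)] <- seq_len(nu)

  av <- as.vector(active)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  b <- numeric(nu)
  diag_acc <- numeric(nu)
  stride <- cumprod(c(1, nd[-length(nd)]))
  for (k in seq_along(nd)) {
    has_next <- as.vector(slice.index(active, k)) < nd[k]
    i1 <- which(av & has_next)
    i2 <- i1 + stride[k]
    keep <- av[i2]
    i1 <- i1[keep]; i2 <- i2[keep]
    w <- 2 * sigma[i1] * sigma[i2] / (sigma[i1] + sigma[i2])
    u1 <- umap[i1]; u2 <- umap[i2]
    bb <- !is.na(u1) & !is.na(u2)       # unknown-unknown faces
    if (any(bb)) {
      ti <- c(ti, u1[bb], u2[bb])
      tj <- c(tj, u2[bb], u1[bb])
      tx <- c(tx, -w[bb], -w[bb])
    }
    # diagonal and rhs contributions
    for (side in 1:2) {
      uu <- if (side == 1) u1 else u2
      oo <- if (side == 1) i2 else i1
      un <- !is.na(uu)
      add <- un
      if (any(add)) {
        diag_acc <- diag_acc + as.vector(
          tabulate_weighted(uu[add], w[add], nu))
        dirn <- un & is.na(umap[oo])    # neighbor is Dirichlet
        if (any(dirn))
          b <- b + as.vector(tabulate_weighted(
            uu[dirn], w[dirn] * dir_val[oo][dirn], nu))
      }
    }
  }
  # isolated cells (no conductive face): pin to ground
  zd <- diag_acc <= 0
  diag_acc[zd] <- 1
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(nu)), j = c(tj, seq_len(nu)),
                            x = c(tx, diag_acc), dims = c(nu, nu))
  # supernodal Cholesky with fill-reducing ordering; the system is SPD
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE,
                         super = TRUE)
  sol <- Matrix::solve(ch, b, system = "A")
  phi[which(unknown)] <- as.numeric(sol)
  phi
}

tabulate_weighted <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, group = bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# |grad phi| in V/cm: central differences where both face neighbors are
# active, one-sided at boundaries, 0 for isolated cells; NA outside
gradient_magnitude <- function(phi, active, h) {
  nd <- dim(phi)
  g2 <- array(0, nd)
  for (k in seq_along(nd)) {
    pp <- neighbor_values(phi, k, 1L, fill = NA)
    pm <- neighbor_values(phi, k, -1L, fill = NA)
    ap <- neighbor_values(active, k, 1L, fill = FALSE)
    am <- neighbor_values(active, k, -1L, fill = FALSE)
    gk <- array(0, nd)
    both <- ap & am
    gk[both] <- (pp[both] - pm[both]) / (2 * h)
    fwd <- ap & !am
    gk[fwd] <- (pp[fwd] - phi[fwd]) / h
    bwd <- am & !ap
    gk[bwd] <- (phi[bwd] - pm[bwd]) / h
    g2 <- g2 + gk^2
  }
  out <- sqrt(g2)
  out[!active] <- NA_real_
  out
}

#' Total current leaving the energized electrode
#'
#' Integrates the normal current density over a closed contour of grid
#' faces around the anode: the faces separating the anode cell set
#' (optionally dilated by \code{dilate} layers of cells) from the rest of
#' the conductive domain. In 2D the current is per modeled electrode
#' height (converted to A using the configured height).
#'
#' @param solution A \code{\link{solve_field}} result.
#' @param dilate Number of cell layers by which to grow the contour
#'   outward from the electrode (default 1). Different contours agree to
#'   discretization accuracy by charge conservation.
#' @return Current in amperes.
#' @export
electrode_current <- function(solution, dilate = 1L) {
  stopifnot(inherits(solution, "field_solution"))
  S <- solution$anode_cells
  for (i in seq_len(dilate)) S <- dilate_mask(S, solution$active)
  nd <- dim(S)
  h_m <- solution$geometry$grid_spacing / 100          # cm -> m
  face_per_len <- if (length(nd) == 2)
    solution$electrodes$modeled_height / 100 else h_m  # face area / h_m
  I <- 0
  for (k in seq_along(nd)) {
    for (s in c(-1L, 1L)) {
      nbS <- neighbor_values(S, k, s, fill = FALSE)
      nbA <- neighbor_values(solution$active, k, s, fill = FALSE)
      fc <- S & !nbS & nbA                 # faces from S to active non-S
      if (!any(fc)) next
      phN <- neighbor_values(solution$phi, k, s, fill = 0)
      sgN <- neighbor_values(solution$sigma, k, s, fill = 0)
      w <- 2 * solution$sigma[fc] * sgN[fc] /
        (solution$sigma[fc] + sgN[fc])
      I <- I + sum(w * (solution$phi[fc] - phN[fc])) * face_per_len
    }
  }
  I
}

dilate_mask <- function(S, active) {
  nd <- dim(S)
  out <- S
  for (k in seq_along(nd))
    for (s in c(-1L, 1L))
      out <- out | neighbor_values(S, k, s, fill = FALSE)
  out & active
}

#' Resistance between the active electrode pair
#'
#' @param solution A converged \code{\link{solve_field}} result.
#' @param amplitude Applied potential, V; defaults to the solve's.
#' @return Resistance in ohms, \code{amplitude / current}.
#' @export
compute_resistance <- function(solution, amplitude = solution$amplitude) {
  stopifnot(inherits(solution, "field_solution"))
  if (!isTRUE(solution$converged)) stop("solution did not converge")
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("amplitude must be > 0 (V)")
  if (abs(solution$current) <= .Machine$double.eps)
    stop("degenerate solution: zero electrode current")
  amplitude / solution$current
}

#' Calibrate a constant conductivity from a measured resistance
#'
#' Recovers the hydrogel conductivity that reproduces an inter-electrode
#' resistance readout (e.g. from the pulse generator) in the given
#' geometry. For a constant conductivity the resistance scales as
#' R = c / sigma with c purely geometric, so a single reference solve at
#' \code{sigma_ref} gives the closed form
#' sigma = sigma_ref * R(sigma_ref) / measured_R.
#'
#' @param geometry,electrodes Domain and needle layout.
#' @param pair Active (anode, cathode) labels.
#' @param amplitude Applied potential used for the reference solve, V.
#' @param measured_R Measured resistance, ohm (> 0, finite).
#' @param sigma_ref Reference conductivity for the geometric solve, S/m.
#' @return Calibrated conductivity, S/m.
#' @export
calibrate_conductivity <- function(geometry, electrodes, pair, amplitude,
                                   measured_R, sigma_ref = 0.1) {
  if (!is.finite(measured_R) || measured_R <= 0)
    stop("measured_R must be a positive finite resistance (ohm)")
  geo <- set_constant_sigma(geometry, sigma_ref)
  ref <- solve_field(geo, electrodes, pair, amplitude)
  R_ref <- compute_resistance(ref)
  sigma_ref * R_ref / measured_R
}

# replace every region's conductivity model with a constant
set_constant_sigma <- function(geometry, sigma) {
  geometry$region_sigma <- lapply(geometry$region_sigma,
                                  function(m) conductivity_model(sigma))
  geometry
}

#' Manually specify an electrode configuration
#'
#' Lower-level companion to \code{\link{place_electrodes}} for
#' non-standard layouts (e.g. a single centered needle for the coaxial
#' benchmark, or needle trajectories over a tumor).
#'
#' @param positions n x 2 matrix of (x, y) centers in cm.
#' @param electrode_radius Needle radius, cm.
#' @param modeled_height Electrode height for current integration, cm.
#' @param labels Electrode labels; default E1..En.
#' @return An \code{electrode_config}.
#' @export
electrode_config <- function(positions, electrode_radius = 0.0455,
                             modeled_height = 0.3, labels = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 2,
                      dimnames = list(NULL, c("x", "y")))
  if (is.null(labels)) labels <- paste0("E", seq_len(nrow(positions)))
  rownames(positions) <- labels
  structure(
    list(positions = positions, labels = labels, layout = "custom",
         spacing = NA_real_, electrode_radius = electrode_radius,
         modeled_height = modeled_height),
    class = "electrode_config")
}
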