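# Shared fixtures, memoized so expensive field solves run once per
# session. Coarse grids (0.02 cm) are used wherever the property under
# test is grid-agnostic; the discretization tests build their own grids.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# 24-well disc with the calibrated constant conductivity
geom24 <- function(h = 0.02) {
  fixture(sprintf("geom24_%g", h),
          make_well_geometry(24, grid_spacing = h,
                             conductivity = conductivity_model(0.027)))
}

pair24 <- function(h = 0.02) {
  fixture(sprintf("pair24_%g", h), place_electrodes(geom24(h), "pair", 0.8))
}

# single 1100 V activation on the 24-well pair
cum24 <- function(h = 0.02, amplitude = 1100) {
  fixture(sprintf("cum24_%g_%g", h, amplitude),
          run_plan(geom24(h), pair24(h),
                   activation_plan(c("E1", "E2"),
                                   pulse_protocol(amplitude, 100))))
}

sweep24 <- function(h = 0.02) {
  fixture(sprintf("sweep24_%g", h), ablation_sweep(cum24(h)))
}

# coaxial benchmark: centered electrode, grounded wall, constant sigma.
# Returns the solution plus the equal-area effective radii of the
# discrete electrode and wall cell sets used by the closed form.
coaxial <- function(h = 0.01, a = 0.1, V = 100, sigma = 0.1) {
  fixture(sprintf("coax_%g_%g", h, a), {
    g <- make_well_geometry(24, grid_spacing = h,
                            conductivity = conductivity_model(sigma))
    e <- electrode_config(matrix(c(0, 0), 1), electrode_radius = a,
                          modeled_height = 0.3)
    s <- solve_field(g, e, c("E1", "wall"), V)
    idx <- which(g$inside, arr.ind = TRUE)
    list(g = g, e = e, s = s, V = V, sigma = sigma,
         r = sqrt(g$x[idx[, 1]]^2 + g$y[idx[, 2]]^2),
         free = !s$dirichlet[g$inside],
         a_eff = h * sqrt(sum(s$anode_cells) / pi),
         R_eff = h * sqrt(sum(g$inside) / pi))
  })
}

# a cumulative field with a hand-made magnitude map, for measure-level
# checks that need exact control of the field values
fake_cumulative <- function(geometry, Emag) {
  structure(list(geometry = geometry, electrodes = NULL, plan = NULL,
                 Emag = Emag, solutions = list()),
            class = "cumulative_field")
}
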