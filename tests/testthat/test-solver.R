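# Verification of the conduction solver against the coaxial closed form
# phi(r) = V ln(R/r) / ln(R/a) and its resistance ln(R/a) / (2 pi sigma h),
# plus the structural properties of the constant- and field-dependent-
# conductivity problems. The closed form is evaluated with the equal-area
# effective radii of the discrete electrode and wall cell sets, so the
# comparison isolates solver error from boundary-staircase error.

test_that("zero amplitude yields the zero solution", {
  s <- solve_field(geom24(), pair24(), c("E1", "E2"), 0)
  expect_true(all(s$phi[s$active] == 0))
  expect_true(all(s$Emag[s$active] == 0))
  expect_equal(s$current, 0)
})

test_that("coaxial potential, field and resistance match the closed form", {
  cx <- coaxial(h = 0.01)
  free <- cx$free
  phi_exact <- cx$V * log(cx$R_eff / cx$r) / log(cx$R_eff / cx$a_eff)
  err_phi <- abs(cx$s$phi[cx$g$inside][free] - phi_exact[free]) / cx$V
  expect_lt(max(err_phi), 0.03)

  # field away from both staircase boundaries
  interior <- free & cx$r > 1.5 * cx$a_eff & cx$r < 0.85 * cx$R_eff
  E_exact <- cx$V / (cx$r * log(cx$R_eff / cx$a_eff))
  err_E <- abs(cx$s$Emag[cx$g$inside][interior] - E_exact[interior]) /
    E_exact[interior]
  expect_lt(max(err_E), 0.02)

  R_num <- compute_resistance(cx$s)
  R_th <- log(cx$R_eff / cx$a_eff) / (2 * pi * cx$sigma * 0.003)
  expect_equal(R_num, R_th, tolerance = 0.02)
})

test_that("coaxial error decreases under grid refinement", {
  err_at <- function(h) {
    cx <- coaxial(h = h)
    phi_exact <- cx$V * log(cx$R_eff / cx$r) / log(cx$R_eff / cx$a_eff)
    max(abs(cx$s$phi[cx$g$inside][cx$free] - phi_exact[cx$free])) / cx$V
  }
  expect_lt(err_at(0.01), err_at(0.02))
})

test_that("current is conserved across enclosing contours", {
  s <- cum24()$solutions[[1]]
  I0 <- electrode_current(s, dilate = 0)
  I2 <- electrode_current(s, dilate = 2)
  expect_equal(I0, I2, tolerance = 0.01)
})

test_that("the constant-sigma problem is linear in the amplitude", {
  s1 <- cum24(amplitude = 1100)$solutions[[1]]
  s2 <- solve_field(geom24(), pair24(), c("E1", "E2"), 2200)
  expect_equal(s2$phi, 2 * s1$phi, tolerance = 1e-10)
  expect_equal(max(s2$Emag[s2$active]), 2 * max(s1$Emag[s1$active]),
               tolerance = 1e-10)
  # superposing +V and -V boundary data: swap anode and cathode
  s3 <- solve_field(geom24(), pair24(), c("E2", "E1"), 1100)
  resid <- s1$phi + s3$phi - 1100
  expect_lt(max(abs(resid[s1$active])), 1e-8)
})

test_that("the potential obeys the maximum principle", {
  s <- cum24()$solutions[[1]]
  expect_gte(min(s$phi[s$active]), 0)
  expect_lte(max(s$phi[s$active]), s$amplitude)
})

test_that("a symmetric pair yields a mirror-symmetric field", {
  s <- cum24()$solutions[[1]]
  E <- s$Emag
  E[is.na(E)] <- 0
  expect_lt(max(abs(E - E[, rev(seq_len(ncol(E)))])) / max(E), 1e-10)
})

test_that("Picard iteration converges with sigma inside its bounds", {
  g <- make_well_geometry(24, grid_spacing = 0.02)  # field-dependent default
  e <- place_electrodes(g, "pair", 0.8)
  s <- solve_field(g, e, c("E1", "E2"), 1100)
  expect_true(s$converged)
  expect_lt(s$residual, 1e-3)
  expect_lte(s$iterations, 50)
  expect_gt(s$iterations, 1)
  expect_true(all(s$sigma[s$active] >= 0.4 - 1e-12 &
                  s$sigma[s$active] <= 1.6 + 1e-12))
  # the nonlinear problem is no longer amplitude-linear
  s2 <- solve_field(g, e, c("E1", "E2"), 2200)
  expect_gt(max(abs(s2$phi[s2$active] - 2 * s$phi[s$active])), 1)
})

test_that("invalid solve requests are rejected with context", {
  expect_error(solve_field(geom24(), pair24(), c("E1", "E9"), 100),
               "E9")
  expect_error(solve_field(geom24(), pair24(), c("E1", "E2"), -5),
               "amplitude")
  expect_error(compute_resistance(cum24()$solutions[[1]], 0), "amplitude")
})

test_that("conductivity calibration inverts the resistance readout", {
  g <- geom24(); e <- pair24()
  R_true <- synth_resistance(g, e, c("E1", "E2"), true_sigma = 0.027)
  sig <- calibrate_conductivity(g, e, c("E1", "E2"), 100, R_true)
  expect_equal(sig, 0.027, tolerance = 0.005)
  # R ~ 1/sigma: doubling the measured resistance halves the estimate
  sig_half <- calibrate_conductivity(g, e, c("E1", "E2"), 100, 2 * R_true)
  expect_equal(sig_half, sig / 2, tolerance = 1e-10)
  expect_error(calibrate_conductivity(g, e, c("E1", "E2"), 100, Inf),
               "measured_R")
})

test_that("calibration recovers draws from the small-hydrogel range", {
  g <- geom24(); e <- pair24()
  sigmas <- c(0.022, 0.027, 0.032)   # printed Hep-G2 small-hydrogel range
  rec <- vapply(seq_along(sigmas), function(i) {
    R <- synth_resistance(g, e, c("E1", "E2"), sigmas[i], seed = i)
    calibrate_conductivity(g, e, c("E1", "E2"), 100, R)
  }, numeric(1))
  expect_equal(rec, sigmas, tolerance = 0.005)
  expect_true(all(rec >= 0.022 - 1e-6 & rec <= 0.032 + 1e-6))
})
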