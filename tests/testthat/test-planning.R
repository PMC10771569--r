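test_that("treatment time is pulse count over frequency, summed", {
  expect_equal(treatment_time(
    activation_plan(c("E1", "E2"), pulse_protocol(2300, 8))), 8)
  p100 <- pulse_protocol(1100, 100)
  expect_equal(treatment_time(activation_plan(
    list(c("E1", "E2"), c("E1", "E3"), c("E2", "E3")), p100)), 300)
  empty <- structure(list(activations = list()), class = "activation_plan")
  expect_warning(t0 <- treatment_time(empty), "empty")
  expect_equal(t0, 0)
})

test_that("pulse protocols enforce their physical constraints", {
  expect_error(pulse_protocol(0, 8), "positive")
  expect_error(pulse_protocol(1100, -1), "positive")
  # a 100 us pulse cannot be delivered at more than 10 kHz
  expect_error(pulse_protocol(1100, 8, pulse_width = 100,
                              frequency = 20000), "period")
  p <- pulse_protocol(1100, 100)
  expect_equal(p$pulse_width, 100)
  expect_equal(p$frequency, 1)
})

test_that("cumulative field is the pointwise max over activations", {
  cum <- cum24()
  single <- cum$solutions[[1]]
  # one activation: cumulative equals that activation's field
  expect_equal(cum$Emag[geom24()$inside], single$Emag[geom24()$inside])
  # repeating the activation changes nothing (idempotence of max)
  twice <- run_plan(geom24(), pair24(), activation_plan(
    list(c("E1", "E2"), c("E1", "E2")), pulse_protocol(1100, 100)))
  expect_equal(twice$Emag, cum$Emag)
  # cumulative dominates every single-activation field pointwise
  g6 <- make_well_geometry(6, grid_spacing = 0.04,
                           conductivity = conductivity_model(0.027))
  e6 <- place_electrodes(g6, "square", 1.4)
  cum6 <- run_plan(g6, e6, activation_plan(
    enumerate_pairs(e6, "adjacent"), pulse_protocol(1100, 100)))
  for (s in cum6$solutions) {
    E <- s$Emag
    E[is.na(E)] <- 0
    expect_true(all(cum6$Emag[g6$inside] >= E[g6$inside] - 1e-12))
  }
})

test_that("all-pairs square delivery is invariant under 90-degree rotation", {
  g6 <- make_well_geometry(6, grid_spacing = 0.04,
                           conductivity = conductivity_model(0.027))
  e6 <- place_electrodes(g6, "square", 1.4)
  cum6 <- run_plan(g6, e6, activation_plan(
    enumerate_pairs(e6, "all"), pulse_protocol(2300, 8)))
  E <- cum6$Emag
  E[is.na(E)] <- 0
  Erot <- t(E)[, rev(seq_len(nrow(E)))]
  expect_lt(max(abs(E - Erot)) / max(E), 0.01)
})

test_that("ablation sweep is monotone with exact boundary behavior", {
  sw <- sweep24()
  expect_true(all(diff(sw$ablated) <= 0))
  expect_true(all(sw$ablated >= 0 &
                  sw$ablated <= attr(sw, "domain_measure")))
  cum <- cum24()
  E <- cum$Emag[geom24()$inside]
  low <- ablation_sweep(cum, E_min = min(E) - 2, E_max = max(E) + 10,
                        step = 5)
  # threshold at/below the field minimum ablates the whole domain
  expect_equal(low$ablated[1], attr(low, "domain_measure"))
  # threshold above the maximum ablates nothing
  expect_equal(low$ablated[nrow(low)], 0)
  expect_error(ablation_sweep(cum, 500, 300, 1), "E_min")
})

test_that("coaxial iso-field area matches the closed-form annulus", {
  cx <- coaxial(h = 0.01)
  cum <- fake_cumulative(cx$g, cx$s$Emag)
  sw <- ablation_sweep(cum, 120, 800, 1)
  for (E_th in c(150, 200, 250)) {
    r_th <- cx$V / (E_th * log(cx$R_eff / cx$a_eff))   # iso-field radius, cm
    area_th <- (pi * min(r_th, cx$R_eff)^2 - pi * cx$a_eff^2) * 100  # mm2
    expect_equal(sw$ablated[sw$threshold == E_th], area_th,
                 tolerance = 0.03)
  }
})

test_that("ablated area grows along the voltage ladder 600 < 1100 < 2300 V", {
  cov <- vapply(c(600, 1100, 2300), function(V)
    coverage_fraction(cum24(amplitude = V), 544), numeric(1))
  expect_true(all(diff(cov) > 0))
})

test_that("ablated area is stable under grid refinement", {
  area_at <- function(h) {
    sw <- sweep24(h)
    sw$ablated[sw$threshold == 544]
  }
  expect_equal(area_at(0.01), area_at(0.005), tolerance = 0.02)
})

test_that("adding an activation never shrinks the ablated measure", {
  g6 <- make_well_geometry(6, grid_spacing = 0.04,
                           conductivity = conductivity_model(0.027))
  e6 <- place_electrodes(g6, "square", 1.4)
  adj <- enumerate_pairs(e6, "adjacent")
  p <- pulse_protocol(1100, 100)
  sw1 <- ablation_sweep(run_plan(g6, e6, activation_plan(adj[1], p)),
                        200, 2500, 20)
  sw4 <- ablation_sweep(run_plan(g6, e6, activation_plan(adj, p)),
                        200, 2500, 20)
  expect_true(all(sw4$ablated >= sw1$ablated))
})

test_that("coverage fraction is a proper fraction of the region", {
  cum <- cum24()
  E <- cum$Emag[geom24()$inside]
  expect_equal(coverage_fraction(cum, min(E)), 1.0)
  expect_gte(min(coverage_fraction(cum, 544)), 0)
  # zero field everywhere: nothing is covered
  zero <- run_plan(geom24(), pair24(),
                   activation_plan(c("E1", "E2"), pulse_protocol(1e-9, 1)))
  expect_equal(coverage_fraction(zero, 100), 0)
  # constructed field covering exactly half the cells
  g <- geom24()
  Ehalf <- array(0, dim(g$inside))
  idx <- which(g$inside)
  Ehalf[idx[seq_len(floor(length(idx) / 2))]] <- 1000
  Ehalf[!g$inside] <- NA
  expect_equal(coverage_fraction(fake_cumulative(g, Ehalf), 600),
               floor(length(idx) / 2) / length(idx))
})

test_that("the tri-level coverage map partitions the domain", {
  cum <- cum24()
  lab <- classify_field_map(cum)
  n_in <- sum(geom24()$inside)
  counts <- table(factor(lab[geom24()$inside], levels = 0:2))
  expect_equal(sum(counts), n_in)
  expect_true(all(is.na(lab[!geom24()$inside])))
  # uniform field between thresholds: everything exp_only
  g <- geom24()
  uni <- array(600, dim(g$inside)); uni[!g$inside] <- NA
  lab_u <- classify_field_map(fake_cumulative(g, uni))
  expect_true(all(lab_u[g$inside] == 1L))
  # zero field: all untreated
  zero <- array(0, dim(g$inside)); zero[!g$inside] <- NA
  expect_true(all(classify_field_map(fake_cumulative(g, zero))[g$inside] == 0L))
  # equal thresholds collapse the exp_only band
  lab_t <- classify_field_map(cum, 544, 544)
  expect_false(any(lab_t[g$inside] == 1L))
  expect_error(classify_field_map(cum, 800, 544), "exp_threshold")
})
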