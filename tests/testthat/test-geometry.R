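test_that("well discs match their nominal cross-section areas", {
  for (fmt in c(24, 12, 6)) {
    g <- make_well_geometry(fmt, grid_spacing = 0.01)
    expect_equal(domain_area(g), g$nominal_area_mm2,
                 tolerance = 0.02)
  }
  expect_equal(make_well_geometry(24)$nominal_area_mm2, 190)
  expect_equal(make_well_geometry(6)$nominal_area_mm2, 950)
})

test_that("discretized area converges to the nominal area under refinement", {
  err <- vapply(c(0.02, 0.01), function(h) {
    g <- make_well_geometry(24, grid_spacing = h)
    abs(domain_area(g) - g$nominal_area_mm2) / g$nominal_area_mm2
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("co-culture annulus has the printed core/ring proportions", {
  g <- make_well_geometry(24, coculture = TRUE, grid_spacing = 0.005)
  expect_identical(g$shape, "annulus")
  expect_equal(g$inner_diameter, 1.0)
  expect_equal(g$outer_diameter, 1.56)
  # core area over whole disc area = (1.0 / 1.56)^2
  ratio <- domain_area(g, region = 1) / domain_area(g)
  expect_equal(ratio, (1.0 / 1.56)^2, tolerance = 0.01)
  # every in-domain cell carries exactly one region label
  expect_true(all(g$region[g$inside] %in% c(1L, 2L)))
  expect_true(all(is.na(g$region[!g$inside])))
  # default two-region conductivities: HCC core, endothelial ring
  expect_equal(g$region_sigma[[1]]$sigma0, 1.26)
  expect_equal(g$region_sigma[[2]]$sigma0, 1.46)
  expect_error(make_well_geometry(12, coculture = TRUE), "24-well")
})

test_that("grid spacing must resolve the domain", {
  expect_error(make_well_geometry(24, grid_spacing = 0.5), "grid_spacing")
  expect_error(make_well_geometry(24, grid_spacing = -0.01), "grid_spacing")
})

test_that("electrode layouts are symmetric with exact interspacing", {
  g6 <- make_well_geometry(6, grid_spacing = 0.02)
  sq <- place_electrodes(g6, "square", 1.4)
  d <- as.matrix(dist(sq$positions))
  expect_equal(sort(d[upper.tri(d)]),
               c(1.4, 1.4, 1.4, 1.4, 1.4 * sqrt(2), 1.4 * sqrt(2)))
  expect_equal(unname(colMeans(sq$positions)), c(0, 0))

  tr <- place_electrodes(g6, "triangle", 0.9)
  dt <- as.matrix(dist(tr$positions))
  expect_equal(unname(dt[upper.tri(dt)]), rep(0.9, 3))

  pr <- place_electrodes(geom24(), "pair", 0.8)
  expect_equal(unname(dist(pr$positions)[1]), 0.8)
  expect_equal(pr$electrode_radius, 0.0455)
})

test_that("electrodes that do not fit the well are rejected", {
  g24 <- geom24()
  expect_error(place_electrodes(g24, "square", 2.0), "placement")
  expect_error(place_electrodes(g24, "pair", 0.05), "spacing")
})

test_that("pair enumeration matches the 4-needle combinatorics", {
  g6 <- make_well_geometry(6, grid_spacing = 0.02)
  sq <- place_electrodes(g6, "square", 1.4)
  adj <- enumerate_pairs(sq, "adjacent")
  all_p <- enumerate_pairs(sq, "all")
  expect_length(adj, 4)
  expect_length(all_p, 6)
  # adjacent pairs are a subset of all pairs
  key <- function(p) paste(sort(p), collapse = "-")
  expect_true(all(vapply(adj, key, "") %in% vapply(all_p, key, "")))
  # deterministic lexicographic order
  expect_identical(vapply(all_p, key, ""),
                   c("E1-E2", "E1-E3", "E1-E4", "E2-E3", "E2-E4", "E3-E4"))
  pr <- pair24()
  expect_length(enumerate_pairs(pr, "all"), 1)
  expect_error(enumerate_pairs(pr, "adjacent"), "square")
})

test_that("tumor masks load from NIfTI with trimming and validation", {
  r_mm <- 4; vox <- 0.5
  tum <- synth_tumor(r_mm, bumpiness = 0, voxel_size = vox, seed = 1)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_tumor_nifti(tum, path)
  back <- load_tumor_mask(path)
  expect_equal(back$voxel_size, rep(vox, 3))
  expect_equal(sum(back$mask), sum(tum$mask))
  # voxelized sphere volume ~ (4/3) pi r^3
  expect_equal(tumor_volume(back), 4 / 3 * pi * r_mm^3, tolerance = 0.03)
  # trimmed to bounding box + margin
  expect_lte(max(dim(back$mask)), 2 * ceiling(r_mm / vox) + 1 + 4)
})

test_that("degenerate tumor volumes are rejected", {
  zero <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0L, c(4, 4, 4))), zero)
  expect_error(load_tumor_mask(zero, voxel_size = 1), "empty-input")

  grey <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(runif(64), c(4, 4, 4))), grey)
  expect_error(load_tumor_mask(grey, voxel_size = 1), "format error")

  expect_error(tumor_model(array(TRUE, c(2, 2)), 1), "3D")
  expect_error(tumor_model(array(FALSE, c(2, 2, 2)), 1), "empty-input")
  expect_error(tumor_model(array(TRUE, c(2, 2, 2)), -1), "voxel_size")
})

test_that("tumor masks round-trip through multi-page TIFF", {
  tum <- synth_tumor(3, bumpiness = 0.2, voxel_size = 0.5, seed = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(array(as.integer(tum$mask), dim(tum$mask)), path)
  expect_error(load_tumor_mask(path), "voxel_size")
  back <- load_tumor_mask(path, voxel_size = 0.5)
  expect_equal(sum(back$mask), sum(tum$mask))
})
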