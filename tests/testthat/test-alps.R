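# ALPS voxel selection and index.

test_that("noise-free phantom selection lands in the ground-truth regions with alignment 1", {
  g <- default_geometry()
  f <- build_phantom(g, control_profile())
  m <- select_fiber_voxels(f, default_roi(g))
  expect_equal(m$voxels$alignment, rep(1, 3), tolerance = 1e-12)
  for (i in 1:3) {
    r <- g$regions[g$regions$fiber == m$voxels$fiber[i], ]
    expect_true(m$voxels$x[i] >= r$x0 && m$voxels$x[i] <= r$x1)
    expect_true(m$voxels$y[i] >= r$y0 && m$voxels$y[i] <= r$y1)
    expect_true(m$voxels$z[i] >= r$z0 && m$voxels$z[i] <= r$z1)
  }
  expect_false(m$low_alignment)
  # all three fibers share the chosen x
  expect_equal(length(unique(m$voxels$x)), 1L)
})

test_that("ties go to the lowest linear voxel index", {
  # homogeneous regions: every voxel ties at alignment 1, so the first voxel
  # (lowest linear index) of each region at the lowest shared x must win
  g <- tiny_geometry()
  f <- build_phantom(g, esrd_profile())
  m <- select_fiber_voxels(f, default_roi(g))
  r <- g$regions
  expect_equal(m$voxels$x, rep(r$x0[1], 3))
  expect_equal(m$voxels$y, r$y0)
  expect_equal(m$voxels$z, rep(r$z0[1], 3))
})

test_that("an ROI over isotropic background yields a flagged low-alignment measurement", {
  g <- default_geometry()
  f <- build_phantom(g, isotropic_profile(0.8))
  m <- select_fiber_voxels(f, default_roi(g))
  expect_true(m$low_alignment)
  res <- subject_alps(simulate_dwi(f, default_protocol(), snr = Inf), default_roi(g))
  expect_true(res$low_alignment)
  expect_equal(res$index, 1, tolerance = 1e-9)  # isotropy forces the index to 1
})

test_that("selection errors are informative", {
  g <- default_geometry()
  f <- build_phantom(g, control_profile())
  f$valid[] <- FALSE
  expect_error(select_fiber_voxels(f, default_roi(g)), class = "dtialps_computation_error")
  roi_out <- fiber_roi(tibble::tibble(
    fiber = c("projection", "association", "subcortical"),
    x0 = 1L, x1 = 20L, y0 = c(1L, 3L, 5L), y1 = c(2L, 4L, 6L), z0 = 1L, z1 = 2L))
  expect_error(select_fiber_voxels(build_phantom(g, control_profile()), roi_out),
               class = "dtialps_input_error")
})

test_that("compute_alps matches direct arithmetic and the calibrated group means", {
  expect_equal(compute_alps(list(dxx_proj = 1, dxx_assoc = 1, dyy_proj = 1, dzz_assoc = 1)), 1)
  expect_equal(compute_alps(list(dxx_proj = 1.2, dxx_assoc = 1.4, dyy_proj = 0.8, dzz_assoc = 0.9)),
               1.3 / 0.85, tolerance = 1e-12)
  expect_equal(compute_alps(list(dxx_proj = 0.816, dxx_assoc = 0.816, dyy_proj = 0.50, dzz_assoc = 0.50)),
               1.632, tolerance = 1e-12)
  expect_error(compute_alps(list(dxx_proj = 1, dxx_assoc = 1, dyy_proj = -1, dzz_assoc = 0.5)),
               class = "dtialps_computation_error")
})

test_that("the index is invariant to a common rescaling of the four diffusivities", {
  withr::with_seed(41, {
    for (i in 1:20) {
      m <- as.list(setNames(runif(4, 0.1, 2), c("dxx_proj", "dxx_assoc", "dyy_proj", "dzz_assoc")))
      c_ <- runif(1, 1e-3, 1e3)
      scaled <- lapply(m, `*`, c_)
      expect_equal(compute_alps(scaled), compute_alps(m), tolerance = 1e-12)
    }
  })
})

test_that("subject_alps reproduces the analytic index on noise-free phantoms", {
  g <- default_geometry()
  for (prof in list(esrd_profile(), control_profile())) {
    dwi <- simulate_dwi(build_phantom(g, prof), default_protocol(), snr = Inf)
    res <- subject_alps(dwi, default_roi(g))
    expect_equal(res$index, analytic_alps(prof), tolerance = 1e-6)
    expect_false(res$low_alignment)
  }
})

test_that("permuting the y and z axes of phantom and ROI leaves the index unchanged", {
  g <- default_geometry()
  f <- build_phantom(g, esrd_profile())
  base <- compute_alps(select_fiber_voxels(f, default_roi(g)))

  # swap y and z in the tensor field: permute array axes and tensor elements
  # (Dyy <-> Dzz, Dxy <-> Dxz); projection fibers now run along y and
  # association fibers along z, so their roles swap
  Dp <- aperm(f$D, c(1, 3, 2, 4))[, , , c(1, 3, 2, 5, 4, 6)]
  fp <- dtialps:::tensor_field(Dp, s0 = f$s0, valid = aperm(f$valid, c(1, 3, 2)))
  r <- g$regions
  swapped <- tibble::tibble(
    fiber = c("projection", "association", "subcortical")[c(2, 1, 3)],
    x0 = r$x0, x1 = r$x1, y0 = r$z0, y1 = r$z1, z0 = r$y0, z1 = r$y1)
  mp <- select_fiber_voxels(fp, fiber_roi(swapped))
  expect_equal(compute_alps(mp), base, tolerance = 1e-12)
})

test_that("selection finds the true fiber voxels under randomized region placements", {
  withr::with_seed(51, {
    for (i in 1:15) {
      dims <- c(10L, 12L, 5L)
      ys <- sort(sample(1:(dims[2] - 1), 3))
      regions <- tibble::tibble(
        fiber = c("projection", "association", "subcortical"),
        x0 = 2L, x1 = 9L, y0 = ys, y1 = ys, z0 = 2L, z1 = 4L)
      g <- phantom_geometry(dims, regions)
      f <- build_phantom(g, control_profile())
      m <- select_fiber_voxels(f, fiber_roi(regions))
      expect_equal(m$voxels$y, ys)
      expect_equal(m$voxels$alignment, rep(1, 3), tolerance = 1e-12)
    }
  })
})
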