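# Design matrix, log-linear tensor fit, eigendecomposition, axis diffusivities.

test_that("design matrix rows follow the b-matrix expansion", {
  proto <- acquisition_protocol(
    c(0, 1000, 1000, 1000, 1000, 1000, 1000, 1000),
    cbind(0, diag(3),
          matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1), 3) / sqrt(2),
          c(1, 1, 1) / sqrt(3)),
    s0 = 100)
  X <- design_matrix(proto)
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0, 0, 0, 0))                 # b = 0 row
  expect_equal(unname(X[2, ]), c(1, -1000, 0, 0, 0, 0, 0))             # g = x
  expect_equal(unname(X[5, "dxy"]), -1000)                             # g = (1,1,0)/sqrt(2)
  expect_equal(unname(X[5, c("dxx", "dyy")]), c(-500, -500))
})

test_that("under-determined protocols are rejected", {
  # 6 coplanar directions cannot identify Dzz-related elements
  g <- rbind(cos(seq(0, pi, length.out = 7))[-7], sin(seq(0, pi, length.out = 7))[-7], 0)
  expect_error(acquisition_protocol(c(0, rep(1000, 6)), cbind(0, g), s0 = 1),
               class = "dtialps_input_error")
})

test_that("noise-free simulate -> fit round trip is exact for random tensors and protocols", {
  withr::with_seed(21, {
    for (i in 1:20) {
      m <- random_spd_tensor()
      proto <- random_protocol(n_dirs = sample(8:32, 1))
      dwi <- simulate_dwi(one_voxel_field(m), proto, snr = Inf)
      tf <- fit_tensor(dwi)
      expect_true(tf$valid[1, 1, 1])
      fitted <- dtialps:::tensor_matrix(tf$D[1, 1, 1, ])
      expect_lt(max(abs(fitted - m)), 1e-8)
      expect_equal(exp(tf$lnS0[1, 1, 1]), proto$s0, tolerance = 1e-8)
    }
  })
})

test_that("whole-phantom noise-free fit recovers every element to 1e-8 mm^2/s", {
  f <- build_phantom(default_geometry(), esrd_profile())
  dwi <- simulate_dwi(f, default_protocol(), snr = Inf)
  tf <- fit_tensor(dwi)
  expect_lt(max(abs(tf$D - f$D)), 1e-8)
  expect_true(all(tf$valid))
})

test_that("degenerate voxels are handled: constant signal gives a zero tensor, dead voxels are flagged", {
  proto <- random_protocol(n_dirs = 10, s0 = 50)
  sig <- array(50, c(1, 1, 1, proto$n))
  dwi <- structure(list(signal = sig, protocol = proto, voxel_size = c(2, 2, 2),
                        axes = dtialps:::axis_convention(), snr = Inf, seed = NULL,
                        geometry = NULL), class = "alps_dwi")
  tf <- fit_tensor(dwi)
  expect_equal(max(abs(tf$D)), 0)          # zero tensor
  expect_false(tf$valid[1, 1, 1])          # and not positive definite, so flagged

  dead <- dwi
  dead$signal[] <- 0
  tf2 <- expect_no_error(fit_tensor(dead))
  expect_false(tf2$valid[1, 1, 1])
})

test_that("fit error shrinks monotonically as SNR grows", {
  f <- build_phantom(default_geometry(), control_profile())
  proto <- default_protocol()
  err <- vapply(c(10, 20, 40, 80), function(snr) {
    mean(vapply(1:3, function(s) {
      mean(abs(fit_tensor(simulate_dwi(f, proto, snr = snr, seed = 1000 + s))$D - f$D))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("median per-element error at SNR 40 stays below 5e-5 mm^2/s on the default phantom", {
  f <- build_phantom(default_geometry(), control_profile())
  proto <- default_protocol()
  med <- vapply(1:20, function(s) {
    median(abs(fit_tensor(simulate_dwi(f, proto, snr = 40, seed = s))$D - f$D))
  }, numeric(1))
  expect_lt(max(med), 5e-5)
})

test_that("eig_sorted orders eigenvalues, reconstructs the tensor and is rotation invariant", {
  expect_equal(eig_sorted(diag(3))$values, c(1, 1, 1))
  e <- eig_sorted(diag(c(3, 2, 1)))
  expect_equal(e$values, c(3, 2, 1))
  expect_equal(abs(e$vectors[, 1]), c(1, 0, 0))
  withr::with_seed(31, {
    for (i in 1:15) {
      m <- random_spd_tensor()
      e <- eig_sorted(m)
      expect_true(all(diff(e$values) <= 0))
      recon <- e$vectors %*% diag(e$values) %*% t(e$vectors)
      expect_lt(max(abs(recon - m)) / max(abs(m)), 1e-12)
      # rotation leaves eigenvalues unchanged
      q <- qr.Q(qr(matrix(rnorm(9), 3)))
      expect_equal(eig_sorted(q %*% m %*% t(q))$values, e$values, tolerance = 1e-10)
    }
  })
  expect_error(eig_sorted(matrix(c(1, NA, 0, NA, 1, 0, 0, 0, 1), 3)),
               class = "dtialps_input_error")
})

test_that("axis_diffusivities returns the scanner-frame diagonal, not eigenvalues", {
  expect_equal(axis_diffusivities(diag(c(5, 6, 7))), c(dxx = 5, dyy = 6, dzz = 7))
  expect_equal(unname(axis_diffusivities(0.8 * diag(3))), rep(0.8, 3))
  # anisotropic tensor with off-diagonals: diagonal differs from eigenvalues
  m <- matrix(c(2, 0.5, 0, 0.5, 1, 0, 0, 0, 1), 3)
  expect_equal(unname(axis_diffusivities(m)), c(2, 1, 1))
  expect_false(isTRUE(all.equal(sort(axis_diffusivities(m)), sort(eig_sorted(m)$values))))
  # projection-fiber tensor of the control profile
  f <- build_phantom(default_geometry(), control_profile())
  d <- axis_diffusivities(dtialps:::tensor_matrix(f$D[3, 3, 3, ])) * 1e3
  expect_equal(unname(d), c(0.816, 0.50, 1.40))
})
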