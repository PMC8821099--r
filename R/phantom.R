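#' Build a three-fiber tensor-field phantom
#'
#' Fills each fiber region with an axis-aligned diffusion tensor whose
#' principal axis is the fiber direction (projection = z, association = y,
#' subcortical = x) and whose scanner-frame diagonal follows the profile:
#'
#' * projection voxels: `diag(lambda_pv, lambda_rd, lambda_ax)` — the x
#'   diagonal element is the perivascular diffusivity;
#' * association voxels: `diag(lambda_pv, lambda_ax, lambda_rd)`;
#' * subcortical voxels: `diag(lambda_ax, lambda_pv, lambda_rd)`;
#' * background voxels: isotropic `lambda_bg * I`.
#'
#' Profile values are in 10^-3 mm^2/s; the stored field is in mm^2/s.
#'
#' @param geometry An [phantom_geometry()].
#' @param profile An [diffusivity_profile()].
#' @return An `alps_tensor_field` with every voxel valid.
#' @examples
#' f <- build_phantom(default_geometry(), control_profile())
#' # a projection-region voxel, in 10^-3 mm^2/s:
#' f$D[3, 3, 3, 1:3] * 1e3   # (0.816, 0.50, 1.40)
#' @export
build_phantom <- function(geometry, profile) {
  stopifnot(inherits(geometry, "alps_geometry"), inherits(profile, "alps_profile"))
  dims <- geometry$dim
  D <- array(0, c(dims, 6L))
  bg <- profile_lambda_bg(profile) * 1e-3
  D[, , , 1] <- bg
  D[, , , 2] <- bg
  D[, , , 3] <- bg
  diag_for <- function(fiber) {
    p <- profile[profile$fiber == fiber, ]
    switch(fiber,
      projection  = c(p$lambda_pv, p$lambda_rd, p$lambda_ax),
      association = c(p$lambda_pv, p$lambda_ax, p$lambda_rd),
      subcortical = c(p$lambda_ax, p$lambda_pv, p$lambda_rd)
    ) * 1e-3
  }
  for (fiber in geometry$regions$fiber) {
    m <- region_mask(geometry, fiber)
    d <- diag_for(fiber)
    for (k in 1:3) {
      comp <- D[, , , k]
      comp[m] <- d[k]
      D[, , , k] <- comp
    }
  }
  tensor_field(D, s0 = NA_real_, valid = array(TRUE, dims), geometry = geometry)
}
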