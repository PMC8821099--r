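# Tensor storage convention: per-voxel 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
# in mm^2/s, matching the design-matrix column order. The NIfTI writer
# re-orders to lower-triangular (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz); see io.R.

D6_NAMES <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")

tensor_field <- function(D, s0, valid, geometry = NULL, lnS0 = NULL) {
  stopifnot(length(dim(D)) == 4L, dim(D)[4] == 6L)
  structure(
    list(
      D = D, s0 = s0, valid = valid,
      lnS0 = lnS0, geometry = geometry,
      axes = axis_convention(), units = "mm^2/s"
    ),
    class = "alps_tensor_field"
  )
}

#' @export
print.alps_tensor_field <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("<alps_tensor_field> %d x %d x %d voxels, %d valid (units %s)\n",
              d[1], d[2], d[3], sum(x$valid), x$units))
  invisible(x)
}

# 3x3 symmetric matrix from a 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

tensor_vector <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

#' Design matrix of the log-linear tensor model
#'
#' Maps the parameter vector (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) to the
#' log-signal of each measurement: for b-value b and unit gradient g the
#' Stejskal-Tanner model gives `ln S = ln S0 - b g' D g`, so the row for
#' measurement i is
#' `(1, -b gx^2, -b gy^2, -b gz^2, -2 b gx gy, -2 b gx gz, -2 b gy gz)`.
#'
#' @param protocol An [acquisition_protocol()].
#' @return An n x 7 matrix. Errors if the protocol leaves the tensor
#'   under-determined (rank < 7).
#' @export
design_matrix <- function(protocol) {
  b <- protocol$bvals
  g <- protocol$bvecs
  X <- cbind(
    1,
    -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
    -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ], -2 * b * g[2, ] * g[3, ]
  )
  colnames(X) <- c("lnS0", D6_NAMES)
  if (qr(X)$rank < 7L) {
    abort_input("Protocol is under-determined: design matrix rank < 7 (need >= 6 non-collinear b > 0 directions plus b = 0).")
  }
  X
}

#' Fit diffusion tensors by ordinary least squares on log-signals
#'
#' Per voxel, solves the log-linear system `ln S = X beta` for
#' `beta = (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` by ordinary least squares.
#' On noise-free data this inverts the forward model exactly. Signals at or
#' below zero are clamped to `1e-6 * S0` before the log; a voxel is flagged
#' invalid if more than 20% of its measurements needed clamping, if the fit is
#' non-finite, or if the fitted tensor is not positive definite (negative
#' eigenvalues are never clipped — the voxel is excluded from ALPS selection
#' instead, since clipping would bias the diffusivities).
#'
#' A weighted variant (`method = "wls"`, weights proportional to the squared
#' predicted signal, the usual first-order correction for log-transformed
#' Rician-corrupted magnitudes) is available; the default is plain OLS.
#'
#' @param dwi A DWI volume from [simulate_dwi()] or [read_dwi()].
#' @param mask Optional logical array (grid shape) restricting the fit.
#' @param method `"ols"` (default) or `"wls"` (one reweighted pass).
#' @return An `alps_tensor_field`: per-voxel tensor elements (mm^2/s),
#'   estimated ln S0, and a validity mask.
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("ols", "wls")) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "alps_dwi"))
  proto <- dwi$protocol
  X <- design_matrix(proto)
  dims <- dim(dwi$signal)[1:3]
  nvox <- prod(dims)
  if (is.null(mask)) mask <- array(TRUE, dims)
  S <- matrix(aperm(dwi$signal, c(4, 1, 2, 3)), nrow = proto$n)  # n x nvox
  idx <- which(as.vector(mask))

  eps <- 1e-6 * proto$s0
  Sm <- S[, idx, drop = FALSE]
  clamped <- Sm <= 0
  Sm[clamped] <- eps
  beta <- qr.solve(X, log(Sm))  # 7 x nsel
  if (method == "wls") {
    # one IRLS pass: weights = squared predicted signals
    pred <- exp(X %*% beta)
    for (j in seq_along(idx)) {
      w <- pred[, j]^2
      Xw <- X * w
      beta[, j] <- solve(crossprod(X, Xw), crossprod(Xw, log(Sm[, j])))
    }
  }

  D <- array(0, c(dims, 6L))
  Dm <- matrix(D, nrow = nvox)
  Dm[idx, ] <- t(beta[-1, , drop = FALSE])
  D <- array(Dm, c(dims, 6L))

  lnS0 <- array(NA_real_, dims)
  lnS0[idx] <- beta[1, ]

  valid <- array(FALSE, dims)
  finite_fit <- colSums(!is.finite(beta)) == 0
  too_clamped <- colMeans(clamped) > 0.20
  spd <- is_spd6(t(beta[-1, , drop = FALSE]))
  valid[idx] <- finite_fit & !too_clamped & spd
  tensor_field(D, s0 = proto$s0, valid = valid,
               geometry = dwi$geometry, lnS0 = lnS0)
}

# vectorized positive-definiteness of rows of an n x 6 tensor matrix
# (Sylvester's criterion on leading principal minors; equivalent to all
# eigenvalues > 0 for symmetric matrices)
is_spd6 <- function(d6) {
  xx <- d6[, 1]; yy <- d6[, 2]; zz <- d6[, 3]
  xy <- d6[, 4]; xz <- d6[, 5]; yz <- d6[, 6]
  m1 <- xx
  m2 <- xx * yy - xy^2
  m3 <- xx * (yy * zz - yz^2) - xy * (xy * zz - yz * xz) + xz * (xy * yz - yy * xz)
  ok <- m1 > 0 & m2 > 0 & m3 > 0
  ok[!is.finite(ok)] <- FALSE
  ok
}

#' Sorted eigendecomposition of a diffusion tensor
#'
#' @param tensor A 3 x 3 symmetric matrix or a 6-vector
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @return A list with `values` (descending) and `vectors` (orthonormal
#'   columns; `vectors[, 1]` is the fiber orientation).
#' @export
eig_sorted <- function(tensor) {
  m <- if (is.matrix(tensor)) tensor else tensor_matrix(tensor)
  if (any(!is.finite(m))) abort_input("Tensor has non-finite entries.")
  e <- eigen(m, symmetric = TRUE)  # already descending
  list(values = e$values, vectors = e$vectors)
}

#' Scanner-frame axis diffusivities of a tensor
#'
#' Returns the diagonal elements Dxx, Dyy, Dzz — the apparent diffusivities
#' along the scanner x, y and z axes. These (not the eigenvalues) are the
#' quantities entering the ALPS index.
#'
#' @inheritParams eig_sorted
#' @return Named numeric vector `c(dxx, dyy, dzz)`.
#' @export
axis_diffusivities <- function(tensor) {
  d <- if (is.matrix(tensor)) diag(tensor) else tensor[1:3]
  if (any(!is.finite(d))) abort_input("Tensor has non-finite entries.")
  setNames(as.numeric(d), c("dxx", "dyy", "dzz"))
}
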