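#' Simulate a diffusion-weighted volume from a tensor field
#'
#' Applies the Stejskal-Tanner forward model per voxel and measurement,
#' `S = S0 * exp(-b g' D g)`, then corrupts the magnitude with Rician noise:
#' `S_noisy = sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ Normal(0, S0/snr)`
#' independent per voxel and measurement. `snr = Inf` returns the noiseless
#' signal.
#'
#' @param field An `alps_tensor_field` (tensors in mm^2/s).
#' @param protocol An [acquisition_protocol()].
#' @param snr Signal-to-noise ratio referenced to the b = 0 signal; positive,
#'   possibly infinite.
#' @param seed Optional integer; when given, the volume is a deterministic
#'   function of `(field, protocol, snr, seed)` and the caller's RNG state is
#'   left untouched.
#' @return A list of class `alps_dwi`: 4-D `signal` array
#'   (x, y, z, measurement), the `protocol`, `voxel_size`, `axes` label,
#'   `snr`, `seed` and the originating `geometry` (if any).
#' @export
simulate_dwi <- function(field, protocol, snr = Inf, seed = NULL) {
  stopifnot(inherits(field, "alps_tensor_field"), inherits(protocol, "alps_protocol"))
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0) {
    abort_input("`snr` must be a single positive (possibly infinite) number.")
  }
  if (any(!is.finite(field$D))) abort_input("Tensor field has non-finite entries.")

  dims <- dim(field$D)[1:3]
  nvox <- prod(dims)
  # b-matrix without intercept: exponent = -(Xd %*% d6)
  Xd <- -design_matrix(protocol)[, -1, drop = FALSE]          # n x 6, positive coeffs
  Dm <- t(matrix(field$D, nrow = nvox))                       # 6 x nvox
  S <- protocol$s0 * exp(-Xd %*% Dm)                          # n x nvox

  add_noise <- function() {
    sigma <- protocol$s0 / snr
    e1 <- matrix(rnorm(length(S), 0, sigma), nrow(S))
    e2 <- matrix(rnorm(length(S), 0, sigma), nrow(S))
    sqrt((S + e1)^2 + e2^2)
  }
  if (is.finite(snr)) {
    S <- if (is.null(seed)) add_noise() else withr::with_seed(as.integer(seed), add_noise())
  }

  signal <- aperm(array(S, c(protocol$n, dims)), c(2, 3, 4, 1))
  voxel_size <- if (!is.null(field$geometry)) field$geometry$voxel_size else c(2, 2, 2.25)
  structure(
    list(
      signal = signal, protocol = protocol, voxel_size = voxel_size,
      axes = axis_convention(), snr = snr, seed = seed,
      geometry = field$geometry
    ),
    class = "alps_dwi"
  )
}

#' @export
print.alps_dwi <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<alps_dwi> %d x %d x %d voxels x %d measurements, SNR %s\n",
              d[1], d[2], d[3], d[4], format(x$snr)))
  invisible(x)
}
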