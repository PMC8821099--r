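# Shared in-code fixtures: small geometries, random SPD tensors and random
# acquisition protocols for property-style tests.

tiny_geometry <- function() {
  phantom_geometry(
    dim = c(8L, 9L, 4L),
    regions = tibble::tibble(
      fiber = c("projection", "association", "subcortical"),
      x0 = 2L, x1 = 7L,
      y0 = c(2L, 4L, 6L), y1 = c(2L, 4L, 6L),
      z0 = 2L, z1 = 3L
    )
  )
}

# random symmetric positive-definite tensor with brain-like scale (mm^2/s)
random_spd_tensor <- function() {
  A <- matrix(rnorm(9), 3, 3)
  m <- crossprod(A)
  m <- m / max(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  m <- m * 2e-3 + diag(3) * 1e-4
  (m + t(m)) / 2
}

# random protocol: one b0 plus n random unit directions at b = 1000
random_protocol <- function(n_dirs = 12, s0 = 500) {
  repeat {
    g <- matrix(rnorm(3 * n_dirs), 3)
    g <- sweep(g, 2, sqrt(colSums(g^2)), "/")
    p <- try(acquisition_protocol(c(0, rep(1000, n_dirs)), cbind(0, g), s0 = s0),
             silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# single-voxel tensor field from a 3x3 tensor
one_voxel_field <- function(m) {
  D <- array(0, c(1, 1, 1, 6))
  D[1, 1, 1, ] <- c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
  dtialps:::tensor_field(D, s0 = NA_real_, valid = array(TRUE, c(1, 1, 1)))
}

# Rician mean and SD for magnitude nu and noise sigma (closed form via
# the Laguerre half polynomial, independent oracle for the noise law)
rician_moments <- function(nu, sigma) {
  x <- -nu^2 / (2 * sigma^2)
  L <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  m <- sigma * sqrt(pi / 2) * L
  v <- 2 * sigma^2 + nu^2 - m^2
  c(mean = m, sd = sqrt(v))
}
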