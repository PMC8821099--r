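#' Phantom geometry: fiber regions on a voxel grid
#'
#' Defines the voxel grid and the rectangular regions occupied by the three
#' fiber populations. The axis convention is fixed throughout the package and
#' recorded in every volume it writes:
#'
#' * x = left-right, the direction of the medullary veins and hence the
#'   perivascular direction of the ALPS construction;
#' * y = anterior-posterior, the association-fiber direction;
#' * z = inferior-superior, the projection-fiber direction.
#'
#' Regions must be pairwise disjoint, lie inside the grid, and share at least
#' one x index, since the ALPS procedure selects one voxel per fiber on a
#' common x coordinate.
#'
#' @param dim Integer grid shape, `c(nx, ny, nz)`.
#' @param regions A data frame with columns `fiber` (one row each for
#'   `"projection"`, `"association"`, `"subcortical"`) and inclusive voxel
#'   index bounds `x0, x1, y0, y1, z0, z1` (1-based).
#' @param voxel_size Voxel edge lengths in mm, length 3.
#' @return A list of class `alps_geometry` with elements `dim`, `regions`
#'   (tibble), `voxel_size` and `axes` (the axis-convention label).
#' @examples
#' default_geometry()
#' @export
phantom_geometry <- function(dim, regions, voxel_size = c(2, 2, 2.25)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) abort_input("`dim` must be three positive integers.")
  regions <- as_tibble(regions)
  need <- c("fiber", "x0", "x1", "y0", "y1", "z0", "z1")
  if (!all(need %in% names(regions))) {
    abort_input("`regions` must have columns fiber, x0, x1, y0, y1, z0, z1.")
  }
  fibers <- c("projection", "association", "subcortical")
  if (!setequal(regions$fiber, fibers) || nrow(regions) != 3L) {
    abort_input("`regions` must contain exactly the projection, association and subcortical fibers.")
  }
  regions <- regions[match(fibers, regions$fiber), need]
  b <- regions[, -1]
  if (any(b < 1) || any(regions$x1 > dim[1]) || any(regions$y1 > dim[2]) || any(regions$z1 > dim[3]) ||
      any(regions$x0 > regions$x1) || any(regions$y0 > regions$y1) || any(regions$z0 > regions$z1)) {
    abort_input("Region bounds must be ordered and lie inside the grid.")
  }
  # pairwise disjointness via voxel membership masks
  occ <- array(0L, dim)
  for (i in seq_len(3)) {
    occ[regions$x0[i]:regions$x1[i], regions$y0[i]:regions$y1[i], regions$z0[i]:regions$z1[i]] <-
      occ[regions$x0[i]:regions$x1[i], regions$y0[i]:regions$y1[i], regions$z0[i]:regions$z1[i]] + 1L
  }
  if (any(occ > 1L)) abort_input("Fiber regions overlap; they must be disjoint.")
  shared_x <- Reduce(intersect, lapply(seq_len(3), function(i) regions$x0[i]:regions$x1[i]))
  if (length(shared_x) == 0L) {
    abort_input("Fiber regions must share at least one x index (ALPS selects voxels on a common x-axis).")
  }
  structure(
    list(
      dim = dim,
      regions = regions,
      voxel_size = as.numeric(voxel_size),
      axes = axis_convention()
    ),
    class = "alps_geometry"
  )
}

#' @rdname phantom_geometry
#' @details `default_geometry()` is a 12 x 12 x 6 grid with the three fiber
#'   slabs stacked along y (projection at the front, association in the
#'   middle, subcortical at the back), all spanning x = 2..11 so that every
#'   interior x index is shared, surrounded by isotropic background.
#' @export
default_geometry <- function() {
  phantom_geometry(
    dim = c(12L, 12L, 6L),
    regions = tibble(
      fiber = c("projection", "association", "subcortical"),
      x0 = 2L, x1 = 11L,
      y0 = c(2L, 6L, 10L), y1 = c(4L, 8L, 12L),
      z0 = 2L, z1 = 5L
    )
  )
}

axis_convention <- function() {
  c(x = "left-right (perivascular / medullary veins)",
    y = "anterior-posterior (association fibers)",
    z = "inferior-superior (projection fibers)")
}

# logical mask of a single region
region_mask <- function(geometry, fiber) {
  r <- geometry$regions[geometry$regions$fiber == fiber, ]
  m <- array(FALSE, geometry$dim)
  m[r$x0:r$x1, r$y0:r$y1, r$z0:r$z1] <- TRUE
  m
}

#' @export
print.alps_geometry <- function(x, ...) {
  cat(sprintf("<alps_geometry> %d x %d x %d voxels (%.3g x %.3g x %.3g mm)\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  print(x$regions)
  invisible(x)
}
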