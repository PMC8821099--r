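#' Fiber regions of interest for the ALPS procedure
#'
#' The ALPS construction places a rectangular ROI over each of the three fiber
#' populations visible at the level of the lateral-ventricle body. Each ROI
#' carries the axis the fiber is expected to run along (projection = z,
#' association = y, subcortical = x); the selection step scores voxels by how
#' well their principal diffusion direction aligns with that axis.
#'
#' @param regions Data frame with columns `fiber`, `x0, x1, y0, y1, z0, z1`
#'   (inclusive 1-based voxel bounds) covering the projection, association and
#'   subcortical fibers.
#' @param min_alignment Alignment floor: if any selected voxel's
#'   |e1 . axis| falls below it, the measurement is flagged
#'   (`low_alignment = TRUE`). Default 0.5.
#' @return A list of class `alps_roi`.
#' @export
fiber_roi <- function(regions, min_alignment = 0.5) {
  regions <- as_tibble(regions)
  need <- c("fiber", "x0", "x1", "y0", "y1", "z0", "z1")
  if (!all(need %in% names(regions))) {
    abort_input("`regions` must have columns fiber, x0, x1, y0, y1, z0, z1.")
  }
  fibers <- c("projection", "association", "subcortical")
  if (!setequal(regions$fiber, fibers)) {
    abort_input("ROI must cover exactly the projection, association and subcortical fibers.")
  }
  regions <- regions[match(fibers, regions$fiber), need]
  regions$axis <- c("z", "y", "x")
  structure(list(regions = regions, min_alignment = min_alignment), class = "alps_roi")
}

#' @rdname fiber_roi
#' @param geometry An [phantom_geometry()]; the default ROI simply reuses the
#'   phantom's fiber regions (on real data the ROIs are drawn by the analyst).
#' @export
default_roi <- function(geometry = default_geometry(), min_alignment = 0.5) {
  fiber_roi(geometry$regions, min_alignment = min_alignment)
}

axis_unit_vector <- function(axis) {
  switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
         abort_input(sprintf("Unknown axis label '%s'.", axis)))
}

#' Select one voxel per fiber on a shared x index
#'
#' Implements the ALPS voxel-selection rule: within each fiber ROI every valid
#' voxel is scored by the alignment `|e1(v) . axis_f|` between its principal
#' eigenvector and the fiber's expected axis. For each candidate x index
#' present (with at least one valid voxel) in all three ROIs, the per-fiber
#' best voxel at that x is found (maximum alignment, ties broken by lowest
#' linear voxel index); the x index maximizing the summed alignment over the
#' three fibers is chosen, ties again going to the lowest index. The selected
#' voxels' scanner-frame axis diffusivities are returned.
#'
#' @param field An `alps_tensor_field`.
#' @param roi An [fiber_roi()].
#' @return A list of class `alps_measurement`: `voxels` (tibble with one row
#'   per fiber: selected indices, alignment, dxx/dyy/dzz in mm^2/s), the four
#'   formula diffusivities `dxx_proj`, `dxx_assoc`, `dyy_proj`, `dzz_assoc`,
#'   the shared `x` index, and `low_alignment` flag. Subcortical diffusivities
#'   are carried for QC only; they do not enter the index.
#' @export
select_fiber_voxels <- function(field, roi) {
  stopifnot(inherits(field, "alps_tensor_field"), inherits(roi, "alps_roi"))
  dims <- dim(field$D)[1:3]
  Dm <- matrix(field$D, nrow = prod(dims))  # nvox x 6

  b <- roi$regions
  if (any(b$x1 > dims[1]) || any(b$y1 > dims[2]) || any(b$z1 > dims[3]) || any(b[, c("x0", "y0", "z0")] < 1)) {
    abort_input("ROI bounds fall outside the volume.")
  }

  # score every valid ROI voxel of each fiber
  score_fiber <- function(i) {
    axis <- axis_unit_vector(b$axis[i])
    grid <- expand.grid(x = b$x0[i]:b$x1[i], y = b$y0[i]:b$y1[i], z = b$z0[i]:b$z1[i])
    lin <- grid$x + dims[1] * (grid$y - 1L) + dims[1] * dims[2] * (grid$z - 1L)
    keep <- field$valid[cbind(grid$x, grid$y, grid$z)]
    grid <- grid[keep, , drop = FALSE]
    lin <- lin[keep]
    if (nrow(grid) == 0L) return(NULL)
    align <- vapply(seq_along(lin), function(j) {
      e1 <- eig_sorted(Dm[lin[j], ])$vectors[, 1]
      abs(sum(e1 * axis))
    }, numeric(1))
    tibble(fiber = b$fiber[i], x = grid$x, y = grid$y, z = grid$z,
           lin = lin, alignment = align)
  }
  cand <- lapply(seq_len(nrow(b)), score_fiber)
  if (any(vapply(cand, is.null, logical(1)))) {
    abort_computation(sprintf(
      "No valid voxels in the %s ROI.",
      paste(b$fiber[vapply(cand, is.null, logical(1))], collapse = ", ")))
  }
  cand <- dplyr::bind_rows(cand)

  shared_x <- Reduce(intersect, lapply(split(cand$x, cand$fiber), unique))
  if (length(shared_x) == 0L) {
    abort_input("ROIs share no x index with valid voxels; ALPS requires selections on a common x-axis.")
  }

  # per fiber and x: best voxel (max alignment, tie -> lowest linear index)
  best <- cand |>
    dplyr::filter(.data$x %in% shared_x) |>
    dplyr::arrange(dplyr::desc(.data$alignment), .data$lin) |>
    dplyr::distinct(.data$fiber, .data$x, .keep_all = TRUE)
  totals <- best |>
    dplyr::summarise(total = sum(.data$alignment), .by = "x") |>
    dplyr::arrange(dplyr::desc(.data$total), .data$x)
  x_sel <- totals$x[1]

  sel <- best[best$x == x_sel, ]
  sel <- sel[match(c("projection", "association", "subcortical"), sel$fiber), ]
  dd <- Dm[sel$lin, 1:3, drop = FALSE]
  voxels <- tibble(
    fiber = sel$fiber, x = sel$x, y = sel$y, z = sel$z,
    alignment = sel$alignment,
    dxx = dd[, 1], dyy = dd[, 2], dzz = dd[, 3]
  )
  structure(
    list(
      voxels = voxels,
      dxx_proj = voxels$dxx[1], dyy_proj = voxels$dyy[1],
      dxx_assoc = voxels$dxx[2], dzz_assoc = voxels$dzz[2],
      x = x_sel,
      low_alignment = any(voxels$alignment < roi$min_alignment),
      min_alignment = roi$min_alignment
    ),
    class = "alps_measurement"
  )
}

#' @export
print.alps_measurement <- function(x, ...) {
  cat(sprintf("<alps_measurement> shared x = %d%s\n", x$x,
              if (x$low_alignment) " [low alignment]" else ""))
  print(x$voxels)
  invisible(x)
}

#' The ALPS index
#'
#' `ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`: the mean
#' diffusivity along the perivascular (x) direction in the projection and
#' association fibers, over the mean diffusivity perpendicular to both the
#' fibers and the perivascular direction. The index is dimensionless and
#' invariant to a common rescaling of all four diffusivities; values near 1
#' indicate no preferential perivascular diffusion.
#'
#' @param m An `alps_measurement`, or a named list/vector with components
#'   `dxx_proj`, `dxx_assoc`, `dyy_proj`, `dzz_assoc`.
#' @return The ALPS index (a single number).
#' @examples
#' compute_alps(list(dxx_proj = 1.2, dxx_assoc = 1.4, dyy_proj = 0.8, dzz_assoc = 0.9))
#' @export
compute_alps <- function(m) {
  v <- lapply(c("dxx_proj", "dxx_assoc", "dyy_proj", "dzz_assoc"), function(f) {
    x <- m[[f]]
    if (is.null(x) || !is.finite(x)) abort_input(sprintf("Missing or non-finite diffusivity `%s`.", f))
    x
  })
  names(v) <- c("dxx_proj", "dxx_assoc", "dyy_proj", "dzz_assoc")
  den <- (v$dyy_proj + v$dzz_assoc) / 2
  if (den <= 0) {
    where <- if (inherits(m, "alps_measurement")) {
      sprintf(" (projection voxel x=%d,y=%d,z=%d; association voxel x=%d,y=%d,z=%d)",
              m$voxels$x[1], m$voxels$y[1], m$voxels$z[1],
              m$voxels$x[2], m$voxels$y[2], m$voxels$z[2])
    } else ""
    abort_computation(paste0("Nonpositive ALPS denominator", where, "."))
  }
  ((v$dxx_proj + v$dxx_assoc) / 2) / den
}

#' Per-subject ALPS from a DWI volume
#'
#' Composition of the three analysis stages: tensor fit
#' ([fit_tensor()]) -> fiber-voxel selection ([select_fiber_voxels()]) ->
#' index ([compute_alps()]). Deterministic given its inputs.
#'
#' @param dwi A DWI volume.
#' @param roi An [fiber_roi()].
#' @param mask Optional fit mask.
#' @inheritParams fit_tensor
#' @return A list of class `alps_result`: `index`, the `measurement`, and the
#'   `low_alignment` flag.
#' @export
subject_alps <- function(dwi, roi, mask = NULL, method = "ols") {
  field <- with_stage("tensor fit", fit_tensor(dwi, mask = mask, method = method))
  m <- with_stage("voxel selection", select_fiber_voxels(field, roi))
  index <- with_stage("index computation", compute_alps(m))
  structure(
    list(index = index, measurement = m, low_alignment = m$low_alignment),
    class = "alps_result"
  )
}

with_stage <- function(stage, expr) {
  retag <- function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)), class = class(e)[1], parent = e)
  }
  tryCatch(expr,
           dtialps_input_error = retag,
           dtialps_computation_error = retag)
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> ALPS index = %.4f%s\n", x$index,
              if (x$low_alignment) " [low alignment]" else ""))
  invisible(x)
}
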