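# Readers and writers. DWI goes to NIfTI-1 plus FSL-dialect .bval/.bvec
# (space-separated; bvec has 3 rows). A small JSON sidecar records the axis
# convention, S0 and simulation provenance, since NIfTI has no room for them.

#' Write / read a DWI volume
#'
#' `write_dwi()` writes `<prefix>.nii.gz`, `<prefix>.bval`, `<prefix>.bvec`
#' and a `<prefix>.json` sidecar (axis convention, S0, SNR, seed).
#' `read_dwi()` reads the three required files back; gradient directions off
#' unit norm by less than 1% are renormalized, larger deviations are an
#' error. If no sidecar is present, S0 is estimated as the mean b = 0 signal.
#'
#' @param dwi An `alps_dwi` volume.
#' @param prefix Output path prefix.
#' @return `write_dwi()` returns the written file paths invisibly;
#'   `read_dwi()` returns an `alps_dwi`.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "alps_dwi"))
  paths <- paste0(prefix, c(".nii.gz", ".bval", ".bvec", ".json"))
  img <- RNifti::asNifti(dwi$signal,
                         list(pixdim = c(-1, dwi$voxel_size, 1, 0, 0, 0)))
  RNifti::writeNifti(img, paths[1])
  writeLines(paste(format(dwi$protocol$bvals, trim = TRUE), collapse = " "), paths[2])
  writeLines(apply(format(dwi$protocol$bvecs, digits = 8, trim = TRUE), 1, paste, collapse = " "),
             paths[3])
  jsonlite::write_json(
    list(axes = as.list(dwi$axes), s0 = dwi$protocol$s0, snr = dwi$snr,
         seed = dwi$seed, voxel_size_mm = dwi$voxel_size),
    paths[4], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' @rdname write_dwi
#' @param nifti_path,bval_path,bvec_path Input files.
#' @param s0 Optional baseline signal override.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, s0 = NULL) {
  for (p in c(nifti_path, bval_path, bvec_path)) {
    if (!file.exists(p)) abort_input(sprintf("File not found: %s", p))
  }
  img <- tryCatch(RNifti::readNifti(nifti_path),
                  error = function(e) abort_input(sprintf("Unreadable NIfTI %s: %s", nifti_path, conditionMessage(e))))
  signal <- array(as.numeric(img), dim = dim(img))
  if (length(dim(signal)) != 4L) abort_input(sprintf("%s is not a 4-D volume.", nifti_path))
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  if (length(bvals) != dim(signal)[4] || ncol(bvecs) != length(bvals)) {
    abort_input(sprintf(
      "Shape mismatch: %d volumes in %s but %d b-values in %s / %d directions in %s.",
      dim(signal)[4], nifti_path, length(bvals), bval_path, ncol(bvecs), bvec_path))
  }
  if (any(signal < 0)) abort_input(sprintf("%s contains negative signals.", nifti_path))

  sidecar <- sub("\\.nii(\\.gz)?$", ".json", nifti_path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(s0)) s0 <- meta$s0 %||% mean(signal[, , , bvals == 0, drop = FALSE])

  proto <- acquisition_protocol(bvals, bvecs, s0 = s0)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  structure(
    list(signal = signal, protocol = proto,
         voxel_size = as.numeric(pd[1:3]),
         axes = axis_convention(),
         snr = meta$snr %||% NA_real_, seed = meta$seed %||% NULL,
         geometry = NULL),
    class = "alps_dwi"
  )
}

#' Write a tensor field as NIfTI
#'
#' Writes the six tensor elements as a 4-D NIfTI in lower-triangular order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz — the FSL/DTI convention) to
#' `<prefix>_tensor.nii.gz`, and the validity mask to `<prefix>_mask.nii.gz`.
#'
#' @param field An `alps_tensor_field`.
#' @param prefix Output path prefix.
#' @export
write_tensor_field <- function(field, prefix) {
  stopifnot(inherits(field, "alps_tensor_field"))
  # internal order (xx, yy, zz, xy, xz, yz) -> lower-triangular
  lt <- field$D[, , , c(1, 4, 2, 5, 6, 3), drop = FALSE]
  vs <- if (!is.null(field$geometry)) field$geometry$voxel_size else c(2, 2, 2.25)
  paths <- paste0(prefix, c("_tensor.nii.gz", "_mask.nii.gz"))
  hdr4 <- list(pixdim = c(-1, vs, 1, 0, 0, 0))
  RNifti::writeNifti(RNifti::asNifti(lt, hdr4), paths[1])
  RNifti::writeNifti(RNifti::asNifti(field$valid + 0, hdr4), paths[2])
  invisible(paths)
}

#' Write / read a fiber ROI as JSON
#'
#' @param roi An [fiber_roi()].
#' @param path JSON file path.
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "alps_roi"))
  jsonlite::write_json(
    list(min_alignment = roi$min_alignment, regions = roi$regions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("File not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fiber_roi(x$regions, min_alignment = x$min_alignment %||% 0.5)
}

#' Write / read a cohort as CSV
#'
#' One row per subject, columns as produced by [simulate_cohort()] (arm,
#' demographics, the laboratory panel, per-fiber axis diffusivities and the
#' measured ALPS index).
#'
#' @param cohort A cohort tibble.
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(as_tibble(cohort), path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("File not found: %s", path))
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("alps_cohort", class(out))
  out
}
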