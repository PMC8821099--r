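# broom-style tidiers

#' @exportS3Method generics::tidy
tidy.alps_measurement <- function(x, ...) {
  x$voxels
}

#' @exportS3Method generics::tidy
tidy.alps_result <- function(x, ...) {
  tibble(
    alps = x$index,
    dxx_proj = x$measurement$dxx_proj, dxx_assoc = x$measurement$dxx_assoc,
    dyy_proj = x$measurement$dyy_proj, dzz_assoc = x$measurement$dzz_assoc,
    x_index = x$measurement$x, low_alignment = x$low_alignment
  )
}

#' @exportS3Method generics::tidy
tidy.alps_stats_report <- function(x, ...) {
  x$comparison
}

#' @exportS3Method generics::glance
glance.alps_stats_report <- function(x, ...) {
  tibble(
    n_tests = nrow(x$comparison),
    n_significant = sum(x$comparison$significant),
    alpha = x$alpha,
    m_corrected = x$correction$m,
    alpha_adjusted = x$correction$alpha_adjusted
  )
}

#' @exportS3Method generics::tidy
tidy.alps_pipeline_result <- function(x, ...) {
  if (is.null(x$report)) return(tibble())
  x$report$comparison
}

#' @exportS3Method generics::glance
glance.alps_pipeline_result <- function(x, ...) {
  grp <- if (nrow(x$cohort) > 0) split(x$cohort$alps, x$cohort$arm) else list()
  tibble(
    n_subjects = nrow(x$cohort),
    alps_esrd = if ("esrd" %in% names(grp)) mean(grp$esrd) else NA_real_,
    alps_control = if ("control" %in% names(grp)) mean(grp$control) else NA_real_,
    n_correlations = nrow(x$correlations)
  )
}
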