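#' End-to-end pipeline configuration
#'
#' Bundles a cohort configuration with the statistical options of the
#' analysis stage. Configurations can also be read from JSON or YAML files
#' with [read_pipeline_config()].
#'
#' @param cohort An [cohort_config()].
#' @param alpha Two-tailed significance level (default 0.05).
#' @param corrected Variables subject to Bonferroni correction in the group
#'   comparison (default: the nine per-fiber axis diffusivities).
#' @param correlate_arm Arm on which clinical correlations are computed
#'   (default `"esrd"`, the arm with laboratory data).
#' @return A list of class `alps_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), alpha = 0.05,
                            corrected = DIFFUSIVITY_VARS,
                            correlate_arm = "esrd") {
  stopifnot(inherits(cohort, "alps_cohort_config"))
  structure(
    list(cohort = cohort, alpha = alpha, corrected = corrected,
         correlate_arm = correlate_arm),
    class = "alps_pipeline_config"
  )
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Recognized fields (all optional): `n_esrd`, `n_control`, `snr`, `rho`,
#' `seed`, `fidelity`, `sigma_subj`, `lambda_pv_esrd`, `lambda_pv_control`,
#' `alpha`, `correlate_arm`.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return An `alps_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("File not found: %s", path))
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_input("YAML configs need the `yaml` package; use JSON instead.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sigma <- x$sigma_subj %||% 0.04
  prof_esrd <- if (!is.null(x$lambda_pv_esrd)) {
    diffusivity_profile(c(1.40, 1.40, 1.40), c(x$lambda_pv_esrd, x$lambda_pv_esrd, 0.50),
                        c(0.50, 0.50, 0.50), sigma_subj = sigma)
  } else esrd_profile(sigma_subj = sigma)
  prof_ctrl <- if (!is.null(x$lambda_pv_control)) {
    diffusivity_profile(c(1.40, 1.40, 1.40), c(x$lambda_pv_control, x$lambda_pv_control, 0.50),
                        c(0.50, 0.50, 0.50), sigma_subj = sigma)
  } else control_profile(sigma_subj = sigma)
  cc <- cohort_config(
    n_esrd = x$n_esrd %||% 49, n_control = x$n_control %||% 38,
    profile_esrd = prof_esrd, profile_control = prof_ctrl,
    snr = x$snr %||% 40, rho = x$rho %||% 0.370,
    fidelity = x$fidelity %||% "fast",
    seed = x$seed %||% 1L
  )
  pipeline_config(cohort = cc, alpha = x$alpha %||% 0.05,
                  correlate_arm = x$correlate_arm %||% "esrd")
}

log_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Run the full synthetic-cohort analysis
#'
#' Executes simulate -> (fit -> select -> index, per subject) -> statistics,
#' optionally writing all result tables to `out_dir`:
#' `subjects.csv` (per-subject records incl. the four formula diffusivities
#' and the index), `comparison.csv` (group-comparison table),
#' `correlations.csv` (ALPS vs clinical variables in the dialysis arm),
#' `report.txt` (human-readable summary) and `metadata.json` (seeds and
#' parameters, for reproducibility). Output is deterministic for a fixed
#' configuration seed.
#'
#' @param config An [pipeline_config()] (or an [cohort_config()], which is
#'   wrapped with default statistical options).
#' @param out_dir Optional output directory (created if needed).
#' @param quiet Suppress progress messages (default `FALSE` logs stage
#'   timings to stderr).
#' @return A list of class `alps_pipeline_result`: `cohort`, `report` (an
#'   `alps_stats_report` or `NULL` for an empty cohort), `correlations`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (inherits(config, "alps_cohort_config")) config <- pipeline_config(cohort = config)
  stopifnot(inherits(config, "alps_pipeline_config"))
  cc <- config$cohort

  t0 <- Sys.time()
  log_msg(quiet, "simulating cohort (n = %d + %d, fidelity %s, seed %d)...",
          cc$n_esrd, cc$n_control, cc$fidelity, cc$seed)
  cohort <- simulate_cohort(cc)
  t1 <- Sys.time()
  log_msg(quiet, "cohort ready in %.1fs", as.numeric(t1 - t0, units = "secs"))

  if (nrow(cohort) == 0L || length(unique(cohort$arm)) < 2L) {
    warn("Empty or single-arm cohort: no statistics computed.")
    report <- NULL
    correlations <- tibble()
  } else {
    report <- compare_groups(cohort, corrected = config$corrected, alpha = config$alpha)
    esrd <- cohort[cohort$arm == config$correlate_arm, ]
    correlations <- correlate_clinical(esrd, alpha = config$alpha)
  }
  t2 <- Sys.time()
  log_msg(quiet, "statistics done in %.1fs", as.numeric(t2 - t1, units = "secs"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(out_dir, "subjects.csv"))
    if (!is.null(report)) {
      readr::write_csv(report$comparison, file.path(out_dir, "comparison.csv"))
      readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
      writeLines(format_report(report, correlations), file.path(out_dir, "report.txt"))
    }
    jsonlite::write_json(
      list(seed = cc$seed, snr = cc$snr, rho = cc$rho, fidelity = cc$fidelity,
           n_esrd = cc$n_esrd, n_control = cc$n_control, alpha = config$alpha,
           timings_s = list(
             cohort = as.numeric(t1 - t0, units = "secs"),
             stats = as.numeric(t2 - t1, units = "secs"))),
      file.path(out_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
    log_msg(quiet, "results written to %s", out_dir)
  }

  structure(list(cohort = cohort, report = report, correlations = correlations),
            class = "alps_pipeline_result")
}

# plain-text summary mirroring the clinical-table layout
format_report <- function(report, correlations) {
  cmp <- report$comparison
  lines <- c(
    sprintf("Group comparison (%s vs %s)", report$groups[1], report$groups[2]),
    sprintf("alpha = %g two-tailed; Bonferroni m = %d, adjusted threshold %s",
            report$alpha, report$correction$m, report$correction$display),
    "",
    sprintf("%-12s %22s %22s %10s %6s", "variable",
            paste0("mean (SD) ", report$groups[1]),
            paste0("mean (SD) ", report$groups[2]), "p", "sig")
  )
  for (i in seq_len(nrow(cmp))) {
    r <- cmp[i, ]
    fmt_ms <- function(m, s) if (is.na(m)) "-" else sprintf("%.3f (%.3f)", m, s)
    lines <- c(lines, sprintf(
      "%-12s %22s %22s %10.4g %6s", r$variable,
      fmt_ms(r$mean_a, r$sd_a), fmt_ms(r$mean_b, r$sd_b),
      r$p.value, ifelse(r$significant, "*", "")))
  }
  if (nrow(correlations) > 0) {
    lines <- c(lines, "", "ALPS index vs clinical variables (Pearson)",
               sprintf("%-16s %6s %8s %10s", "variable", "n", "r", "p"))
    for (i in seq_len(nrow(correlations))) {
      r <- correlations[i, ]
      lines <- c(lines, sprintf("%-16s %6s %8s %10s", r$variable,
                                ifelse(is.na(r$n), "-", r$n),
                                ifelse(is.na(r$r), "-", sprintf("%.3f", r$r)),
                                ifelse(is.na(r$p.value), "-", sprintf("%.4g", r$p.value))))
    }
  }
  lines
}

#' @export
print.alps_pipeline_result <- function(x, ...) {
  cat(sprintf("<alps_pipeline_result> %d subjects\n", nrow(x$cohort)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
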