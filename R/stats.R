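# Statistical battery: pooled two-sample t, Pearson chi-square (no continuity
# correction), Pearson correlation, Bonferroni. Kernels are computed from the
# textbook formulas; test code cross-checks them against stats::t.test,
# stats::chisq.test and stats::cor.test.

#' Independent two-sample t-test (pooled variance)
#'
#' Student's pooled-variance two-sample t-test with
#' `df = n_a + n_b - 2` and a two-tailed p-value. A Welch (unequal-variance)
#' variant is available via `var_equal = FALSE`.
#'
#' @param a,b Numeric samples, each with at least two finite values.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A one-row tibble: `statistic` (t), `df`, `p.value`, `mean_a`,
#'   `mean_b`.
#' @examples
#' t_test_independent(c(1, 2, 3), c(2, 3, 4))
#' @export
t_test_independent <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2 || any(!is.finite(a)) || any(!is.finite(b))) {
    abort_input("Both samples need >= 2 finite values.")
  }
  na <- length(a); nb <- length(b)
  d <- mean(a) - mean(b)
  if (var_equal) {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    if (sp2 == 0) {
      if (d == 0) {
        return(tibble(statistic = 0, df = na + nb - 2, p.value = 1,
                      mean_a = mean(a), mean_b = mean(b)))
      }
      abort_computation("Zero pooled variance with unequal means: t is undefined.")
    }
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    va <- var(a) / na; vb <- var(b) / nb
    if (va + vb == 0) {
      if (d == 0) {
        return(tibble(statistic = 0, df = na + nb - 2, p.value = 1,
                      mean_a = mean(a), mean_b = mean(b)))
      }
      abort_computation("Zero variance with unequal means: t is undefined.")
    }
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  t <- d / se
  tibble(statistic = t, df = df, p.value = 2 * pt(-abs(t), df),
         mean_a = mean(a), mean_b = mean(b))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction,
#' `X^2 = N (ad - bc)^2 / (r1 r2 c1 c2)`, on 1 degree of freedom.
#'
#' @param tab 2x2 matrix of nonnegative counts with positive marginals.
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @examples
#' # men/women by arm (ESRD, control)
#' chi_square_2x2(matrix(c(28, 21, 21, 17), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort_input("`tab` must be a 2x2 matrix of nonnegative integer counts.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort_input("Chi-square is undefined with a zero marginal.")
  }
  n <- sum(tab)
  num <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  x2 <- num / den
  tibble(statistic = x2, df = 1, p.value = pchisq(x2, 1, lower.tail = FALSE))
}

#' Pearson correlation with two-tailed p-value
#'
#' `r = cov(x, y) / (sd(x) sd(y))`; the p-value comes from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. A
#' perfect correlation (|r| = 1) has p = 0.
#'
#' @param x,y Equal-length numeric samples, n >= 3, neither constant.
#' @return A one-row tibble: `r`, `n`, `statistic` (t), `df`, `p.value`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) abort_input("Need equal-length samples with >= 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort_input("Correlation is undefined for a constant sample.")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sd(x) * sd(y))
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    return(tibble(r = r, n = n, statistic = Inf * sign(r), df = n - 2, p.value = 0))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  tibble(r = r, n = n, statistic = t, df = n - 2, p.value = 2 * pt(-abs(t), n - 2))
}

#' Bonferroni-adjusted significance threshold
#'
#' Returns `alpha / m` at full precision plus the display form truncated to
#' four decimals (the reporting convention for the nine per-axis diffusivity
#' comparisons: 0.05/9 is displayed as 0.0055).
#'
#' @param alpha Family-wise level, in (0, 1).
#' @param m Number of comparisons, >= 1.
#' @return A one-row tibble: `alpha`, `m`, `alpha_adjusted`, `display`.
#' @examples
#' bonferroni_alpha(0.05, 9)
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 9) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort_input("`alpha` must be in (0, 1).")
  if (!is.numeric(m) || m < 1 || m != round(m)) abort_input("`m` must be a positive integer.")
  adj <- alpha / m
  tibble(alpha = alpha, m = as.integer(m), alpha_adjusted = adj,
         display = sprintf("%.4f", trunc(adj * 1e4) / 1e4))
}

#' Group comparison table for a two-arm cohort
#'
#' Runs the study's between-group battery on a cohort data frame: pooled
#' two-sample t-tests for continuous variables, Pearson chi-square for
#' categorical ones, with a Bonferroni-adjusted threshold applied only to the
#' variables named in `corrected` (by default the nine per-fiber axis
#' diffusivities; the ALPS index and demographics are judged at the
#' uncorrected two-tailed `alpha`).
#'
#' @param data A data frame (e.g. an [simulate_cohort()] result) with a
#'   two-level grouping column.
#' @param variables Continuous variables to compare (default: ALPS plus the
#'   nine axis diffusivities and age).
#' @param categorical Categorical variables to compare (default `"sex"`).
#' @param corrected Subset of `variables` subject to Bonferroni correction;
#'   `m` is their number.
#' @param group Name of the grouping column (default `"arm"`).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param var_equal Passed to [t_test_independent()].
#' @return A list of class `alps_stats_report`: `comparison` (tibble with
#'   per-variable statistics, p-values, the threshold applied and the
#'   significance flag) and `correction` (the [bonferroni_alpha()] row).
#' @export
compare_groups <- function(data,
                           variables = c("alps", DIFFUSIVITY_VARS, "age"),
                           categorical = "sex",
                           corrected = DIFFUSIVITY_VARS,
                           group = "arm", alpha = 0.05, var_equal = TRUE) {
  data <- as_tibble(data)
  if (!group %in% names(data)) abort_input(sprintf("Grouping column `%s` not found.", group))
  levels <- sort(unique(data[[group]]))
  if (length(levels) != 2L) abort_input("`compare_groups()` needs exactly two groups.")
  missing <- setdiff(c(variables, categorical), names(data))
  if (length(missing) > 0) {
    abort_input(sprintf("Variable(s) not in the cohort: %s.", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(corrected, variables)
  if (length(extra) > 0) {
    abort_input(sprintf("`corrected` must be a subset of `variables` (offending: %s).",
                        paste(extra, collapse = ", ")))
  }
  corr <- bonferroni_alpha(alpha, max(length(corrected), 1))

  ga <- data[data[[group]] == levels[1], ]
  gb <- data[data[[group]] == levels[2], ]

  cont <- purrr::map_dfr(variables, function(v) {
    tt <- t_test_independent(ga[[v]], gb[[v]], var_equal = var_equal)
    thr <- if (v %in% corrected) corr$alpha_adjusted else alpha
    tibble(
      variable = v, type = "continuous",
      group_a = levels[1], group_b = levels[2],
      mean_a = tt$mean_a, sd_a = sd(ga[[v]]),
      mean_b = tt$mean_b, sd_b = sd(gb[[v]]),
      statistic = tt$statistic, df = tt$df, p.value = tt$p.value,
      corrected = v %in% corrected, threshold = thr,
      significant = tt$p.value < thr
    )
  })
  cat_ <- purrr::map_dfr(categorical, function(v) {
    tab <- table(factor(data[[group]], levels), data[[v]])
    if (!all(dim(tab) == c(2, 2))) {
      abort_input(sprintf("Categorical variable `%s` must have exactly two levels.", v))
    }
    cs <- chi_square_2x2(unclass(tab))
    tibble(
      variable = v, type = "categorical",
      group_a = levels[1], group_b = levels[2],
      mean_a = NA_real_, sd_a = NA_real_, mean_b = NA_real_, sd_b = NA_real_,
      statistic = cs$statistic, df = cs$df, p.value = cs$p.value,
      corrected = FALSE, threshold = alpha,
      significant = cs$p.value < alpha
    )
  })
  structure(
    list(comparison = dplyr::bind_rows(cont, cat_), correction = corr,
         groups = levels, alpha = alpha),
    class = "alps_stats_report"
  )
}

DIFFUSIVITY_VARS <- c("dxx_proj", "dyy_proj", "dzz_proj",
                      "dxx_assoc", "dyy_assoc", "dzz_assoc",
                      "dxx_subc", "dyy_subc", "dzz_subc")

#' Correlations between the ALPS index and clinical variables
#'
#' Pearson correlation of the measured ALPS index against each clinical
#' variable, within one cohort (the study runs this within the dialysis arm).
#' Constant or insufficiently observed variables yield a flagged row rather
#' than an error.
#'
#' @param data Cohort data frame with an `alps` column.
#' @param variables Clinical variables to correlate (default: the study's 17
#'   — age, dialysis duration, 14 laboratory values including PTH, and
#'   hematocrit/hemoglobin/total CO2 are part of that list).
#' @param alpha Two-tailed level used for the `significant` flag.
#' @return A tibble with one row per variable: `variable`, `n`, `r`,
#'   `statistic`, `df`, `p.value`, `significant`, `note`.
#' @export
correlate_clinical <- function(data, variables = CLINICAL_VARS, alpha = 0.05) {
  data <- as_tibble(data)
  if (!"alps" %in% names(data)) abort_input("Cohort has no `alps` column; run the pipeline first.")
  missing <- setdiff(variables, names(data))
  if (length(missing) > 0) {
    abort_input(sprintf("Variable(s) not in the cohort: %s.", paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(variables, function(v) {
    out <- tibble(variable = v, n = NA_integer_, r = NA_real_,
                  statistic = NA_real_, df = NA_real_, p.value = NA_real_,
                  significant = NA, note = NA_character_)
    res <- tryCatch(pearson_r(data$alps, data[[v]]), error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$note <- res
    } else {
      out$n <- as.integer(res$n); out$r <- res$r
      out$statistic <- res$statistic; out$df <- res$df
      out$p.value <- res$p.value
      out$significant <- res$p.value < alpha
    }
    out
  })
}

CLINICAL_VARS <- c("age", "dialysis_months",
                   "hemoglobin", "hematocrit", "protein", "albumin",
                   "ast", "alt", "bun", "creatinine", "sodium", "potassium",
                   "chloride", "calcium", "phosphate", "pth", "total_co2")

#' @export
print.alps_stats_report <- function(x, ...) {
  cat(sprintf("<alps_stats_report> %s vs %s; alpha = %g, Bonferroni m = %d (adjusted %s)\n",
              x$groups[1], x$groups[2], x$alpha, x$correction$m, x$correction$display))
  print(x$comparison)
  invisible(x)
}
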