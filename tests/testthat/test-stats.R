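# Statistical kernels and the group/correlation batteries. Base R's t.test,
# chisq.test and cor.test serve as independent reference implementations.

test_that("pooled t-test matches hand values and the reference implementation", {
  r <- t_test_independent(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p.value, 0.2878641, tolerance = 1e-6)

  same <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # antisymmetry
  fwd <- t_test_independent(c(1, 5, 2), c(4, 4, 7, 1))
  rev <- t_test_independent(c(4, 4, 7, 1), c(1, 5, 2))
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p.value, rev$p.value)

  expect_error(t_test_independent(c(1, 1, 1), c(2, 2, 2)),
               class = "dtialps_computation_error")
  expect_equal(t_test_independent(c(1, 1), c(1, 1))$p.value, 1)

  withr::with_seed(61, {
    for (i in 1:400) {
      a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 2))
      mine <- t_test_independent(a, b)
      ref <- t.test(a, b, var.equal = TRUE)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-6)
      expect_equal(mine$p.value, ref$p.value, tolerance = 1e-6)
      welch <- t_test_independent(a, b, var_equal = FALSE)
      refw <- t.test(a, b)
      expect_equal(welch$statistic, unname(refw$statistic), tolerance = 1e-6)
      expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-6)
    }
  })
})

test_that("chi-square on 2x2 tables matches the closed form and the study's sex comparison", {
  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  # men/women by arm: 28/21 in the dialysis arm, 21/17 among controls
  sex <- matrix(c(28, 21, 21, 17), 2, byrow = TRUE)
  r <- chi_square_2x2(sex)
  expect_equal(r$statistic, 0.03074, tolerance = 1e-3)
  expect_equal(r$p.value, 0.861, tolerance = 1e-3)
  ref <- chisq.test(sex, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p.value, ref$p.value, tolerance = 1e-10)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               class = "dtialps_input_error")
  withr::with_seed(62, {
    for (i in 1:200) {
      tab <- matrix(rpois(4, 20) + 1, 2)
      mine <- chi_square_2x2(tab)
      ref <- chisq.test(tab, correct = FALSE)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-6)
      expect_equal(mine$p.value, ref$p.value, tolerance = 1e-6)
    }
  })
})

test_that("Pearson correlation matches hand values and the reference implementation", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  r <- pearson_r(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$r, 0.8, tolerance = 1e-12)
  expect_equal(r$p.value, 0.1040880, tolerance = 1e-6)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), class = "dtialps_input_error")

  withr::with_seed(63, {
    for (i in 1:400) {
      n <- sample(3:40, 1)
      a <- rnorm(n); b <- rnorm(n) + runif(1, -1, 1) * a
      mine <- pearson_r(a, b)
      ref <- cor.test(a, b)
      expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-6)
      expect_equal(mine$p.value, ref$p.value, tolerance = 1e-6)
    }
  })
})

test_that("Bonferroni threshold is alpha/m with the four-decimal display convention", {
  expect_equal(bonferroni_alpha(0.05, 1)$alpha_adjusted, 0.05)
  nine <- bonferroni_alpha(0.05, 9)
  expect_equal(nine$alpha_adjusted, 0.05 / 9)
  expect_equal(nine$display, "0.0055")
  expect_lt(bonferroni_alpha(0.05, 10)$alpha_adjusted, nine$alpha_adjusted)
  expect_error(bonferroni_alpha(0.05, 0), class = "dtialps_input_error")
})

test_that("compare_groups runs the full battery with correction only where intended", {
  co <- simulate_cohort(cohort_config(n_esrd = 30, n_control = 30, seed = 77, fidelity = "full",
                                      snr = 40))
  rep_ <- compare_groups(co)
  tab <- tidy(rep_)
  expect_true(all(tab$p.value >= 0 & tab$p.value <= 1))
  expect_equal(rep_$correction$m, 9L)
  expect_equal(tab$threshold[tab$variable == "alps"], 0.05)
  expect_equal(tab$threshold[tab$variable == "dxx_proj"], 0.05 / 9)
  expect_equal(tab$type[tab$variable == "sex"], "categorical")
  expect_error(compare_groups(co, variables = c("alps", "nonexistent")),
               class = "dtialps_input_error", regexp = "nonexistent")

  # identical groups relabeled: every continuous row has t = 0 (or p = 1)
  half <- co[co$arm == "esrd", ]
  dup <- dplyr::bind_rows(half, dplyr::mutate(half, arm = "mirror"))
  same <- compare_groups(dup, variables = c("alps", "age"), categorical = "sex",
                         corrected = NULL)
  expect_true(all(same$comparison$statistic[same$comparison$type == "continuous"] == 0))
  expect_true(all(same$comparison$p.value == 1))
})

test_that("the calibrated arms separate on ALPS in almost every cohort", {
  hits <- vapply(1:100, function(s) {
    co <- simulate_cohort(cohort_config(seed = 4000 + s))
    tab <- compare_groups(co)$comparison
    tab$significant[tab$variable == "alps"]
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("correlate_clinical recovers null and perfect correlations and flags constants", {
  # under rho = 0, |r| with PTH stays below 0.3 for nearly all n = 49 cohorts
  rs <- vapply(1:100, function(s) {
    co <- simulate_cohort(cohort_config(n_control = 0, rho = 0, seed = 5000 + s))
    correlate_clinical(co, variables = "pth")$r
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.3), 0.95)

  co <- simulate_cohort(cohort_config(n_control = 0, seed = 6001))
  self <- correlate_clinical(dplyr::mutate(co, alps_copy = alps), variables = "alps_copy")
  expect_equal(self$r, 1)

  flagged <- correlate_clinical(dplyr::mutate(co, flat = 1), variables = c("pth", "flat"))
  expect_true(is.na(flagged$r[flagged$variable == "flat"]))
  expect_false(is.na(flagged$note[flagged$variable == "flat"]))
  expect_false(is.na(flagged$r[flagged$variable == "pth"]))
})
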