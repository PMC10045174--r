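test_that("Mann-Whitney exact branch matches the enumeration oracle", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, 0.1)  # 2 of the 20 labelings are as extreme
  expect_equal(res$p_value, mw_enumeration_oracle(c(1, 2, 3), c(4, 5, 6)))
  # identical samples: no evidence of a difference
  x <- c(2, 5, 9)
  expect_gte(mann_whitney_u(x, x)$p_value, 0.99)
  # randomized battery against the oracle, all n <= 8, no ties
  set.seed(101)
  for (i in 1:100) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    vals <- sample(1000, n1 + n2)  # distinct -> tie-free
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    got <- mann_whitney_u(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, mw_enumeration_oracle(x, y), tolerance = 1e-12,
                 label = sprintf("MW case %d", i))
    # U from rank sums equals U from its defining pair count
    expect_equal(got$statistic, mw_u_pairs(x, y))
  }
})

test_that("Mann-Whitney falls back to a tie-corrected normal approximation", {
  x <- c(1, 1, 2, 2, 3); y <- c(2, 3, 3, 4, 4)
  res <- mann_whitney_u(x, y)
  expect_identical(res$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Wilcoxon signed-rank exact branch matches the sign enumeration", {
  res <- wilcoxon_signed_rank(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, 2 / 16)  # all-positive signs, 2^4 patterns
  # paired no-change data collapse to p = 1 with a warning
  expect_warning(res0 <- wilcoxon_signed_rank(c(1, 2), c(1, 2)),
                 "all paired differences are zero")
  expect_equal(res0$p_value, 1)
  expect_true(res0$all_zero)
  # randomized battery against the oracle, <= 12 nonzero pairs, with ties
  set.seed(202)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    before <- sample(50, n, replace = TRUE)
    after <- before + sample(c(-4:-1, 1:4), n, replace = TRUE)
    got <- wilcoxon_signed_rank(before, after)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, wsr_enumeration_oracle(before, after),
                 tolerance = 1e-12, label = sprintf("WSR case %d", i))
  }
})

test_that("large-sample Wilcoxon agrees with the reference implementation", {
  set.seed(7)
  before <- rnorm(30, 10, 2)
  after <- before - rnorm(30, 0.8, 1)
  res <- wilcoxon_signed_rank(before, after)
  expect_identical(res$method, "normal")
  ref <- stats::wilcox.test(after, before, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("synthetic group-difference regimes reach the reported significance", {
  # ILD vs control invasiveness at the study's sample sizes
  cohort <- generate_cohort(cohort_spec(seed = 55))
  base <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(cohort$measurements, arm == "untreated"),
                    patient_id),
    zoi = median(zoi_percent), .groups = "drop")
  base <- dplyr::inner_join(base,
                            dplyr::select(cohort$patients, "patient_id",
                                          "group"),
                            by = "patient_id")
  mw <- mann_whitney_u(base$zoi[base$group == "ILD"],
                       base$zoi[base$group == "control"])
  expect_lt(mw$p_value, 1e-4)
  # untreated vs nintedanib paired medians at n = 23
  med <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(cohort$measurements,
                                  arm %in% c("untreated", "nintedanib"),
                                  group == "ILD"),
                    patient_id, arm),
    zoi = median(zoi_percent), .groups = "drop")
  wide <- tidyr::pivot_wider(med, names_from = "arm", values_from = "zoi")
  wt <- wilcoxon_signed_rank(wide$untreated, wide$nintedanib)
  expect_lt(wt$p_value, 1e-4)
})

test_that("linear regression reports slope, r, r^2 and the slope t-test p", {
  fit <- suppressWarnings(linear_regression(1:10, 2 * (1:10) + 1))
  expect_equal(fit$r, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  fit <- linear_regression(x, y)
  # hand computation: cov = 1, sd_x = sd_y = sqrt(5/3) -> r = 0.6
  expect_equal(fit$r, 0.6)
  expect_equal(fit$r_squared, fit$r^2, tolerance = 1e-12)
  ref <- summary(lm(y ~ x))
  expect_equal(fit$p_value, ref$coefficients[2, 4])
  expect_error(linear_regression(rep(2, 5), 1:5), "degenerate predictor")
  expect_error(linear_regression(1:2, 1:2), "at least 3")
})

test_that("delta-delta-Ct expression follows the two-power rule", {
  expect_equal(ddct_expression(20, 15, 22, 17), 1)   # ddCt = 0
  expect_equal(ddct_expression(24, 18, 25, 20), 0.5) # ddCt = 6 - 5 = 1
  expect_equal(ddct_expression(18, 18, 21, 18), 8)   # ddCt = -3
  expect_error(ddct_expression(NA, 18, 25, 20), "finite")
})

test_that("group summaries use the n-1 SD and a t-based CI", {
  s <- summarize_group(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2.5))
  half <- qt(0.975, 4) * sqrt(2.5) / sqrt(5)
  expect_equal(c(s$ci_low, s$ci_high), c(3 - half, 3 + half))
  expect_equal(summarize_group(c(1, 1, 1))$sd, 0)
  expect_error(summarize_group(3), "at least 2")
})

test_that("progressor labels follow the 5-point, 12-month rule", {
  pts <- tibble::tibble(
    patient_id = c("A", "B", "C", "D", "E"),
    fvc_baseline = c(60, 60, 60, 60, 60),
    fvc_followup = c(54, 55, 56, NA, 50),
    followup_months = c(10, 10, 10, NA, 14))
  lab <- classify_progressors(pts)
  expect_identical(lab$progression,
                   c("progressor",     # decline 6
                     "progressor",     # decline exactly 5: boundary in
                     "non-progressor", # decline 4
                     "undetermined",   # no follow-up
                     "non-progressor")) # outside the 12-month window
  expect_equal(lab$delta_fvc, c(-6, -5, -4, NA, -10))
  # monotonicity: deeper decline can never undo progression
  worse <- pts
  worse$fvc_followup <- pts$fvc_followup - 3
  lab2 <- classify_progressors(worse)
  progressed <- lab$progression == "progressor"
  expect_true(all(lab2$progression[progressed] == "progressor"))
  # relative rule: 5% of a 60-point baseline is a 3-point drop
  rel <- classify_progressors(pts, rule = "relative")
  expect_identical(rel$progression[3], "progressor")
})
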