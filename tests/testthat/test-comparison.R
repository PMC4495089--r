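test_that("quantitative descriptives handle single values and missing data", {
  df <- tibble::tibble(
    practice_group = c("CM", "CM", "CM", "Ho", "Mx", "Mx"),
    cost = c(10, 20, NA, 7, NA, NA)
  )
  d <- describe_quantitative(df, "cost")
  cm <- d[d$group == "CM", ]
  expect_equal(cm$n, 3)
  expect_equal(cm$n_described, 2)
  expect_equal(cm$mean, 15)
  expect_equal(cm$n_missing, 1)
  ho <- d[d$group == "Ho", ]                       # single observation
  expect_equal(ho$mean, ho$median)
  expect_true(is.na(ho$sd))
  mx <- d[d$group == "Mx", ]                       # all missing
  expect_equal(mx$n_missing, mx$n)
  expect_true(is.na(mx$mean))
})

test_that("qualitative percentages use the non-missing denominator and sum to 100", {
  df <- tibble::tibble(
    practice_group = c(rep("CM", 175 + 1389), rep("Ho", 5)),
    sick = c(rep("yes", 175), rep("no", 1389), "yes", "no", "no", NA, NA)
  )
  d <- describe_qualitative(df, "sick")
  cm_yes <- d[d$group == "CM" & d$level == "yes", ]
  expect_equal(round(cm_yes$pct, 1), 11.2)         # 175 / 1564
  ho <- d[d$group == "Ho", ]
  expect_equal(unique(ho$n_missing), 2)
  expect_equal(sum(ho$pct), 100)
  expect_equal(sum(d[d$group == "CM", ]$pct), 100)
})

test_that("chi-squared matches hand arithmetic and published contingency results", {
  # textbook 2x2: 10/90 vs 20/80
  res <- chi_squared_test(matrix(c(10, 90, 20, 80), nrow = 2))
  expect_equal(res$statistic, 3.9216, tolerance = 1e-4)
  expect_equal(res$df, 1)

  # perfectly proportional table: statistic 0, p 1
  res <- chi_squared_test(matrix(c(10, 20, 30, 60), nrow = 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$overall_p, 1)

  # published sick-leave 2x3 table reproduces p = 0.0051 at 2 significant figures
  tab <- matrix(c(175, 1389, 336, 2783, 112, 1297), nrow = 2,
                dimnames = list(c("yes", "no"), c("CM", "Mx", "Ho")))
  res <- chi_squared_test(tab, ref = "CM")
  expect_equal(signif(res$overall_p, 2), 0.0051)
  expect_named(res$pairwise_p, c("Mx_vs_CM", "Ho_vs_CM"))
  expect_lt(res$pairwise_p[["Ho_vs_CM"]], 0.05)
})

test_that("chi-squared equals a brute-force expected-count computation", {
  brute_chisq <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- sum((m - e)^2 / e)
    list(stat = stat,
         p = stats::pchisq(stat, (nrow(m) - 1) * (ncol(m) - 1),
                           lower.tail = FALSE))
  }
  set.seed(31)
  for (i in 1:50) {
    r <- sample(2:3, 1); c <- sample(2:3, 1)
    m <- matrix(sample(0:20, r * c, replace = TRUE), nrow = r)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    res <- chi_squared_test(m)
    oracle <- brute_chisq(m)
    expect_equal(res$statistic, oracle$stat, tolerance = 1e-10)
    expect_equal(res$overall_p, oracle$p, tolerance = 1e-10)
  }
})

test_that("degenerate contingency tables raise a named error", {
  m <- matrix(c(0, 10, 0, 20), nrow = 2)   # first row all zero
  expect_error(chi_squared_test(m), "row 1", class = "gpcost_validation_error")
  m2 <- matrix(c(0, 0, 5, 10), nrow = 2)   # first column all zero
  expect_error(chi_squared_test(m2), "column 1", class = "gpcost_validation_error")
  expect_error(chi_squared_test(matrix(1:3, nrow = 1)),
               class = "gpcost_validation_error")
})

test_that("ANOVA reproduces hand computations and degenerates correctly", {
  # {1,2,3} vs {4,5,6}: between SS 13.5 on 1 df, within SS 4 on 4 df
  res <- anova_costs(c(1, 2, 3, 4, 5, 6), rep(c("CM", "Ho"), each = 3))
  expect_equal(res$statistic, 13.5, tolerance = 1e-10)
  expect_equal(res$overall_p, 0.02131164, tolerance = 1e-6)

  # three identical groups: F = 0, p = 1
  res <- anova_costs(rep(c(1, 2, 3), 3), rep(c("CM", "Mx", "Ho"), each = 3))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$overall_p, 1)

  expect_error(anova_costs(c(1, 2, 3), c("CM", "CM", "Ho")),
               "Ho", class = "gpcost_validation_error")
  expect_error(anova_costs(c(1, 2), c("CM", "CM")),
               class = "gpcost_validation_error")
})

test_that("pairwise two-group ANOVA p equals the pooled t-test p (F = t^2)", {
  set.seed(17)
  for (i in 1:25) {
    x <- rnorm(sample(5:30, 1), mean = 10, sd = 3)
    y <- rnorm(sample(5:30, 1), mean = 10 + runif(1, -2, 2), sd = 3)
    res <- anova_costs(c(x, y), c(rep("CM", length(x)), rep("Ho", length(y))))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(res$pairwise_p[["Ho_vs_CM"]], tt$p.value, tolerance = 1e-10)
    expect_equal(res$overall_p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("the F-test keeps its nominal size on null gaussian groups", {
  set.seed(99)
  reps <- 400
  rejections <- vapply(seq_len(reps), function(i) {
    v <- rnorm(90)
    g <- rep(c("CM", "Mx", "Ho"), each = 30)
    anova_costs(v, g)$overall_p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("headline percent differences match the published ratios", {
  expect_equal(headline_ratio(68.93, 86.63), 20.4)
  expect_equal(round(headline_ratio(68.93, 86.63), 0), 20)
  expect_equal(headline_ratio(25.62, 48.68), 47.4)
  expect_equal(headline_ratio(13, 13), 0)
  expect_error(headline_ratio(5, 0), class = "gpcost_validation_error")
})

test_that("compare_groups assembles the three report tables with tests", {
  cfg <- cohort_config(group_sizes = c(CM = 250, Mx = 250, Ho = 250), seed = 8)
  co <- suppressMessages(generate_cohort(cfg))
  b <- cost_visits(co$visits, co$drug_lines)
  cmp <- compare_groups(co$visits, co$drug_lines, b, ref = "CM")

  expect_s3_class(cmp, "gpcost_comparison")
  expect_setequal(unique(cmp$nonmedicinal$variable),
                  c("sick_leave", "radiology", "ct_scan", "mri", "lab_test",
                    "nursing", "physiotherapy", "specialist_referral"))
  expect_equal(nrow(cmp$costs), 9 * 3)
  expect_true(all(cmp$tests$overall_p >= 0 & cmp$tests$overall_p <= 1))
  expect_true(all(c("Mx_vs_CM", "Ho_vs_CM") %in% names(cmp$tests)))

  # consultation cost rows exclude NUA visits
  n_costed <- sum(b$consultation_costed & b$practice_group == "Ho")
  ho_cons <- cmp$costs[cmp$costs$variable == "consultation_total" &
                         cmp$costs$group == "Ho", ]
  expect_equal(ho_cons$n, n_costed)
  # prescription rows keep them
  ho_rx <- cmp$costs[cmp$costs$variable == "prescription_total" &
                       cmp$costs$group == "Ho", ]
  expect_equal(ho_rx$n, sum(b$practice_group == "Ho"))
})
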