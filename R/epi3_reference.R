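# Published summary tables of the EPI3 economic study of French general
# practice (2008 tariffs). The patient-level data were never deposited, so
# these printed group-level numbers are the only external anchors available:
# they serve as inputs for recomputation checks (percentages from counts,
# chi-squared tests on printed contingency tables, headline cost ratios),
# never as values the engine is fitted to.

#' Published group sizes of the EPI3 economic-study population
#'
#' @return Named integer vector: patients per practice group (CM/Mx/Ho).
#' @export
epi3_group_sizes <- function() {
  c(CM = 1691L, Mx = 3187L, Ho = 1501L)
}

#' Published non-medicinal prescription counts
#'
#' Yes/no counts per practice group for the eight non-medicinal
#' prescription flags, with the published percentage and overall
#' chi-squared p-value. Yes + no can fall short of the group size:
#' percentages were computed on the non-missing sample.
#'
#' @return A tibble with columns \code{variable, group, n_yes, n_no,
#'   published_pct, published_p}.
#' @export
epi3_nonmedicinal_counts <- function() {
  rows <- list(
    c("sick_leave",          175, 1389, 336, 2783, 112, 1297, 11.2, 10.8, 7.9, 0.0051),
    c("radiology",           104, 1463, 183, 2937,  79, 1328,  6.6,  5.9, 5.6, 0.4503),
    c("ct_scan",              16, 1538,  28, 3093,   7, 1392,  1.0,  0.9, 0.5, 0.2552),
    c("mri",                  16, 1535,  28, 3087,   8, 1390,  1.0,  0.9, 0.6, 0.3765),
    c("lab_test",            247, 1322, 390, 2736, 195, 1209, 15.7, 12.5, 13.9, 0.0084),
    c("nursing",              14, 1539,  29, 3086,   7, 1393,  0.9,  0.9, 0.5, 0.3090),
    c("physiotherapy",        97, 1461, 180, 2939, 106, 1294,  6.2,  5.8, 7.6, 0.0698),
    c("specialist_referral", 191, 1354, 311, 2792, 133, 1261, 12.4, 10.0, 9.5, 0.0201)
  )
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      variable = r[1],
      group = c("CM", "Mx", "Ho"),
      n_yes = as.integer(r[c(2, 4, 6)]),
      n_no = as.integer(r[c(3, 5, 7)]),
      published_pct = as.numeric(r[8:10]),
      published_p = as.numeric(r[11])
    )
  }))
}

#' Published prescription-size moments
#'
#' Mean [SD] number of drug lines per prescription, overall and by
#' reimbursement tier (non-reimbursable, 35%, 65%), per practice group.
#'
#' @return A tibble with columns \code{variable, group, mean, sd}.
#' @export
epi3_prescription_moments <- function() {
  grid <- list(
    drugs_per_rx   = c(3.1, 2.1, 2.8, 1.9, 3.5, 2.2),
    lines_tier_0    = c(0.2, 0.4, 0.2, 0.5, 0.3, 0.6),
    lines_tier_0.35 = c(0.7, 0.9, 0.8, 1.1, 2.0, 1.9),
    lines_tier_0.65 = c(2.2, 1.9, 1.9, 1.6, 1.1, 1.5)
  )
  dplyr::bind_rows(lapply(names(grid), function(v) {
    x <- grid[[v]]
    tibble::tibble(
      variable = v, group = c("CM", "Mx", "Ho"),
      mean = x[c(1, 3, 5)], sd = x[c(2, 4, 6)]
    )
  }))
}

#' Published three-payer cost summary
#'
#' Mean [SD] cost in EUR per practice group for the nine cells of the
#' cost grid: Social-Security / remaining / health-expenditure
#' perspective, each split into consultation, prescription and total.
#'
#' @return A tibble with columns \code{variable, group, mean, sd}.
#' @export
epi3_cost_summary <- function() {
  grid <- list(
    total_ss               = c(65.25, 97.38, 60.51, 165.85, 42.00, 70.30),
    consultation_ss        = c(16.49, 2.97, 16.21, 2.82, 15.81, 2.55),
    prescription_ss        = c(48.68, 96.32, 43.87, 162.74, 25.62, 68.23),
    total_remaining        = c(21.35, 29.24, 21.08, 28.12, 26.89, 27.79),
    consultation_remaining = c(6.19, 3.88, 6.27, 3.60, 11.20, 5.75),
    prescription_remaining = c(15.24, 28.15, 15.28, 27.74, 15.87, 27.25),
    health_expenditure     = c(86.63, 106.97, 81.60, 170.04, 68.93, 81.53),
    consultation_total     = c(22.68, 2.53, 22.49, 2.17, 27.08, 5.00),
    prescription_total     = c(63.72, 106.28, 59.03, 167.29, 41.67, 79.74)
  )
  dplyr::bind_rows(lapply(names(grid), function(v) {
    x <- grid[[v]]
    tibble::tibble(
      variable = v, group = c("CM", "Mx", "Ho"),
      mean = x[c(1, 3, 5)], sd = x[c(2, 4, 6)]
    )
  }))
}
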