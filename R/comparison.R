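# Statistical reporting stage: per-group descriptives, chi-squared tests on
# categorical flags (Pearson, no continuity correction — the r x c default
# of the big commercial stats packages), and one-way ANOVA on costs with an
# overall p-value plus pairwise contrasts of each group against the
# conventional-medicine (CM) reference. No multiple-testing correction is
# applied: raw per-variable p-values are reported.

#' Per-group descriptive summary of a quantitative variable
#'
#' Group size, described n, mean, SD, median, quartiles, range and the
#' number of missing values. Percent-style variables belong in
#' [describe_qualitative()].
#'
#' @param data A data frame containing \code{var} and the grouping column.
#' @param var Name of the quantitative column (string).
#' @param by Name of the grouping column.
#' @return A tibble with one row per group. Empty groups and all-missing
#'   variables yield \code{NA} descriptors, not an error.
#' @export
describe_quantitative <- function(data, var, by = "practice_group") {
  check_columns(data, c(var, by), "describe_quantitative input")
  groups <- sort(unique(as.character(data[[by]])))
  rows <- lapply(groups, function(g) {
    x <- data[[var]][data[[by]] == g]
    ok <- x[!is.na(x)]
    m <- length(ok)
    q <- if (m > 0) stats::quantile(ok, c(0.25, 0.5, 0.75), names = FALSE) else rep(NA_real_, 3)
    tibble::tibble(
      group = g, variable = var, n = length(x), n_described = m,
      mean = if (m > 0) mean(ok) else NA_real_,
      sd = if (m > 1) stats::sd(ok) else NA_real_,
      median = q[2], q1 = q[1], q3 = q[3],
      min = if (m > 0) min(ok) else NA_real_,
      max = if (m > 0) max(ok) else NA_real_,
      n_missing = length(x) - m
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-group frequency summary of a qualitative variable
#'
#' Counts and percentages per level, with percentages computed on the
#' non-missing sample of each group.
#'
#' @inheritParams describe_quantitative
#' @return A tibble with one row per group x level, columns \code{group,
#'   variable, level, count, pct, n_missing}.
#' @export
describe_qualitative <- function(data, var, by = "practice_group") {
  check_columns(data, c(var, by), "describe_qualitative input")
  groups <- sort(unique(as.character(data[[by]])))
  levels_all <- sort(unique(as.character(data[[var]][!is.na(data[[var]])])))
  rows <- lapply(groups, function(g) {
    x <- as.character(data[[var]][data[[by]] == g])
    n_missing <- sum(is.na(x))
    ok <- x[!is.na(x)]
    counts <- table(factor(ok, levels = levels_all))
    tibble::tibble(
      group = g, variable = var, level = levels_all,
      count = as.integer(counts),
      pct = if (length(ok) > 0) 100 * as.integer(counts) / length(ok) else NA_real_,
      n_missing = n_missing
    )
  })
  dplyr::bind_rows(rows)
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared without continuity correction,
#' df = (r - 1)(c - 1). When \code{ref} names a column, each other column
#' is additionally tested against the reference in a two-column subtable.
#'
#' @param contingency An r x c matrix of counts (r, c >= 2), columns
#'   typically the practice groups.
#' @param ref Optional reference column name for pairwise contrasts.
#' @param variable Optional variable label carried into the result.
#' @return A list of class \code{comparison_result}: \code{variable},
#'   \code{test = "chi_squared"}, \code{statistic}, \code{df},
#'   \code{overall_p} and \code{pairwise_p} (named numeric, possibly
#'   empty).
#' @examples
#' sick_leave <- matrix(c(175, 1389, 336, 2783, 112, 1297), nrow = 2,
#'                      dimnames = list(c("yes", "no"), c("CM", "Mx", "Ho")))
#' chi_squared_test(sick_leave, ref = "CM")$overall_p  # ~0.0051
#' @export
chi_squared_test <- function(contingency, ref = NULL, variable = NA_character_) {
  m <- as.matrix(contingency)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort_validation("contingency table must be at least 2 x 2")
  }
  if (any(is.na(m)) || any(m < 0)) {
    abort_validation("contingency counts must be non-negative and non-missing")
  }
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    dim_lbl <- if (any(rs == 0)) {
      sprintf("row %s", paste(which(rs == 0), collapse = ", "))
    } else {
      sprintf("column %s", paste(which(cs == 0), collapse = ", "))
    }
    abort_validation(sprintf("degenerate contingency table: %s has zero total", dim_lbl))
  }
  fit <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  pairwise <- numeric(0)
  if (!is.null(ref)) {
    if (is.null(colnames(m)) || !ref %in% colnames(m)) {
      abort_validation(sprintf("reference column '%s' not found in the table", ref))
    }
    others <- setdiff(colnames(m), ref)
    pairwise <- vapply(others, function(g) {
      suppressWarnings(stats::chisq.test(m[, c(ref, g)], correct = FALSE))$p.value
    }, numeric(1))
    names(pairwise) <- paste0(others, "_vs_", ref)
  }
  structure(
    list(
      variable = variable, test = "chi_squared",
      statistic = unname(fit$statistic), df = unname(fit$parameter),
      overall_p = fit$p.value, pairwise_p = pairwise
    ),
    class = "comparison_result"
  )
}

#' One-way ANOVA on per-visit costs with contrasts against a reference
#'
#' Overall F-test p-value comparing all groups, then each non-reference
#' group compared to the reference in a two-group one-way ANOVA
#' (equivalent to the pooled-variance two-sided t-test, F = t^2). The
#' conventional 5% significance threshold is recorded in the result.
#'
#' @param values Numeric vector (e.g. per-visit cost in EUR).
#' @param group Group labels, same length as \code{values}.
#' @param ref Reference group label.
#' @param variable Optional variable label carried into the result.
#' @return A list of class \code{comparison_result}: \code{variable},
#'   \code{test = "anova"}, \code{statistic} (overall F), \code{overall_p},
#'   \code{pairwise_p}, \code{group_means} and \code{alpha = 0.05}.
#' @export
anova_costs <- function(values, group, ref = "CM", variable = NA_character_) {
  keep <- !is.na(values) & !is.na(group)
  values <- as.numeric(values[keep])
  group <- as.character(group[keep])
  sizes <- table(group)
  if (length(sizes) < 2) {
    abort_validation("ANOVA needs at least two groups")
  }
  if (any(sizes < 2)) {
    abort_validation(sprintf(
      "ANOVA needs >= 2 observations per group (group '%s' has %d)",
      names(sizes)[which(sizes < 2)[1]], min(sizes)
    ))
  }
  if (!ref %in% names(sizes)) {
    abort_validation(sprintf("reference group '%s' not present", ref))
  }
  # suppress the "essentially perfect fit" warning: near-constant costs
  # (e.g. consultation cost in an all-sector-1 cohort) are legitimate input
  fit <- suppressWarnings(stats::anova(stats::lm(values ~ factor(group))))
  overall_p <- fit[["Pr(>F)"]][1]
  f_stat <- fit[["F value"]][1]
  others <- setdiff(names(sizes), ref)
  pairwise <- vapply(others, function(g) {
    sel <- group %in% c(ref, g)
    sub <- suppressWarnings(stats::anova(stats::lm(values[sel] ~ factor(group[sel]))))
    sub[["Pr(>F)"]][1]
  }, numeric(1))
  names(pairwise) <- paste0(others, "_vs_", ref)
  structure(
    list(
      variable = variable, test = "anova",
      statistic = f_stat, overall_p = overall_p, pairwise_p = pairwise,
      group_means = vapply(split(values, group), mean, numeric(1)),
      alpha = 0.05
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s%s\n", x$test,
              if (!is.na(x$variable)) paste0(" on ", x$variable) else ""))
  cat(sprintf("  overall p = %.4g\n", x$overall_p))
  for (nm in names(x$pairwise_p)) {
    cat(sprintf("  %s: p = %.4g\n", nm, x$pairwise_p[[nm]]))
  }
  invisible(x)
}

#' Percent saving of one mean cost relative to another
#'
#' \code{100 * (mean_b - mean_a) / mean_b}: the percent by which
#' \code{mean_a} undercuts the reference mean \code{mean_b}.
#'
#' @param mean_a Mean cost of the cheaper strategy (EUR).
#' @param mean_b Reference mean cost (EUR), must be positive.
#' @param digits Rounding for the returned value (default 1 decimal).
#' @return The percent difference, rounded.
#' @examples
#' headline_ratio(68.93, 86.63)  # 20.4
#' @export
headline_ratio <- function(mean_a, mean_b, digits = 1) {
  if (!is.numeric(mean_b) || is.na(mean_b) || mean_b <= 0) {
    abort_validation("headline_ratio: the reference mean must be > 0")
  }
  round(100 * (mean_b - mean_a) / mean_b, digits)
}

#' Full group comparison: descriptive tables plus tests
#'
#' Builds the three report tables of the analysis: non-medicinal
#' prescription rates with chi-squared tests; prescription composition
#' (homeopathic-only / conventional-only / mixed shares among visits with
#' at least one drug line, and mean line counts overall and per
#' reimbursement tier) with chi-squared / ANOVA tests; and the three-payer
#' by three-component cost grid with ANOVA tests. "Not under agreement"
#' visits are excluded from the consultation and total cost rows (their
#' consultation cannot be costed) but kept in the prescription rows.
#'
#' @param visits Validated visits table.
#' @param drug_lines Validated drug-lines table.
#' @param breakdowns Output of [cost_visits()] for the same visits.
#' @param ref Reference practice group for pairwise contrasts.
#' @return A list of class \code{gpcost_comparison} with tibbles
#'   \code{nonmedicinal} (Table-1 analogue), \code{prescriptions}
#'   (Table-2 analogue), \code{costs} (Table-4 analogue) and \code{tests}
#'   (one row per tested variable: overall and pairwise p-values).
#' @export
compare_groups <- function(visits, drug_lines, breakdowns, ref = "CM") {
  groups <- sort(unique(visits$practice_group))
  tests <- list()
  note_test <- function(res) {
    tests[[length(tests) + 1]] <<- tibble::tibble(
      variable = res$variable, test = res$test,
      overall_p = res$overall_p,
      pairwise = list(res$pairwise_p)
    )
  }

  # --- non-medicinal prescription rates -------------------------------
  nonmed <- list()
  for (f in NONMEDICINAL_FLAGS) {
    tab <- vapply(groups, function(g) {
      x <- visits[[f]][visits$practice_group == g]
      c(yes = sum(x), no = sum(!x))
    }, numeric(2))
    res <- tryCatch(
      chi_squared_test(tab, ref = if (ref %in% groups) ref else NULL,
                       variable = f),
      gpcost_validation_error = function(e) NULL  # degenerate (all-yes/all-no) flag
    )
    if (!is.null(res)) note_test(res)
    nonmed[[f]] <- tibble::tibble(
      variable = f, group = groups,
      n_yes = tab["yes", ], n = colSums(tab),
      pct = 100 * tab["yes", ] / colSums(tab),
      overall_p = if (is.null(res)) NA_real_ else res$overall_p
    )
  }
  nonmedicinal <- dplyr::bind_rows(nonmed)

  # --- prescription composition ---------------------------------------
  per_visit <- dplyr::count(drug_lines, .data$visit_id, name = "n_lines")
  vtab <- dplyr::left_join(visits, per_visit, by = "visit_id")
  vtab$n_lines[is.na(vtab$n_lines)] <- 0L
  homeo_per_visit <- dplyr::summarise(
    dplyr::group_by(drug_lines, .data$visit_id),
    n_homeo = sum(.data$is_homeopathic), .groups = "drop"
  )
  vtab <- dplyr::left_join(vtab, homeo_per_visit, by = "visit_id")
  vtab$n_homeo[is.na(vtab$n_homeo)] <- 0L
  vtab$rx_type <- dplyr::case_when(
    vtab$n_lines == 0 ~ NA_character_,
    vtab$n_homeo == 0 ~ "conventional_only",
    vtab$n_homeo == vtab$n_lines ~ "homeopathic_only",
    TRUE ~ "mixed"
  )

  rx_rows <- list()
  typed <- vtab[!is.na(vtab$rx_type), ]
  if (nrow(typed) > 0 && length(unique(typed$practice_group)) >= 2 &&
      length(unique(typed$rx_type)) >= 2) {
    type_tab <- table(typed$rx_type, typed$practice_group)
    res <- chi_squared_test(as.matrix(type_tab),
                            ref = if (ref %in% colnames(type_tab)) ref else NULL,
                            variable = "prescription_type")
    note_test(res)
    type_desc <- describe_qualitative(typed, "rx_type")
    type_desc$variable <- "prescription_type"
    type_desc$overall_p <- res$overall_p
    rx_rows$types <- type_desc
  }

  count_vars <- list(
    drugs_per_rx = vtab$n_lines,
    lines_tier_0 = NULL, lines_tier_0.35 = NULL, lines_tier_0.65 = NULL
  )
  tier_vals <- c(0, 0.35, 0.65)
  for (k in seq_along(tier_vals)) {
    ck <- dplyr::count(drug_lines[abs(drug_lines$tier - tier_vals[k]) < 1e-9, ],
                       .data$visit_id, name = "k")
    v <- dplyr::left_join(visits["visit_id"], ck, by = "visit_id")$k
    v[is.na(v)] <- 0L
    count_vars[[k + 1]] <- v
  }
  count_desc <- list()
  for (nm in names(count_vars)) {
    df <- tibble::tibble(practice_group = visits$practice_group,
                         value = count_vars[[nm]])
    d <- describe_quantitative(df, "value")
    d$variable <- nm
    if (length(groups) >= 2 && all(table(df$practice_group) >= 2)) {
      res <- anova_costs(df$value, df$practice_group,
                         ref = if (ref %in% groups) ref else groups[1],
                         variable = nm)
      note_test(res)
      d$overall_p <- res$overall_p
    } else {
      d$overall_p <- NA_real_
    }
    count_desc[[nm]] <- d
  }
  prescriptions <- list(
    types = rx_rows$types,
    line_counts = dplyr::bind_rows(count_desc)
  )

  # --- cost grid -------------------------------------------------------
  stopifnot(nrow(breakdowns) == nrow(visits))
  cost_rows <- c(
    "total_ss", "consultation_ss", "prescription_ss",
    "total_remaining", "consultation_remaining", "prescription_remaining",
    "health_expenditure", "consultation_total", "prescription_total"
  )
  consultation_scope <- c(
    "total_ss", "consultation_ss", "total_remaining",
    "consultation_remaining", "health_expenditure", "consultation_total"
  )
  costs_desc <- list()
  for (nm in cost_rows) {
    b <- breakdowns
    if (nm %in% consultation_scope) b <- b[b$consultation_costed, ]
    df <- tibble::tibble(practice_group = b$practice_group, value = b[[nm]])
    d <- describe_quantitative(df, "value")
    d$variable <- nm
    if (length(unique(df$practice_group)) >= 2 &&
        all(table(df$practice_group) >= 2)) {
      res <- anova_costs(df$value, df$practice_group,
                         ref = if (ref %in% df$practice_group) ref else unique(df$practice_group)[1],
                         variable = nm)
      note_test(res)
      d$overall_p <- res$overall_p
    } else {
      d$overall_p <- NA_real_
    }
    costs_desc[[nm]] <- d
  }

  tests_tbl <- if (length(tests)) {
    tidy <- dplyr::bind_rows(tests)
    pw <- lapply(tidy$pairwise, function(p) {
      tibble::as_tibble(as.list(p))
    })
    dplyr::bind_cols(tidy[, c("variable", "test", "overall_p")],
                     dplyr::bind_rows(pw))
  } else {
    tibble::tibble(variable = character(0), test = character(0),
                   overall_p = numeric(0))
  }

  structure(
    list(
      nonmedicinal = nonmedicinal,
      prescriptions = prescriptions,
      costs = dplyr::bind_rows(costs_desc),
      tests = tests_tbl,
      ref = ref
    ),
    class = "gpcost_comparison"
  )
}

#' @export
print.gpcost_comparison <- function(x, ...) {
  cat("<gpcost_comparison>\n")
  cat(sprintf("  reference group: %s\n", x$ref))
  cat(sprintf("  non-medicinal flags tested: %d\n",
              length(unique(x$nonmedicinal$variable))))
  cat(sprintf("  cost rows tested: %d\n", length(unique(x$costs$variable))))
  invisible(x)
}
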