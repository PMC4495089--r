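# Two-file tabular layout: one visits table (one row per consultation) and
# one drug-lines table keyed by visit_id. Extra descriptive columns (gender,
# professional group, SF12 scores ...) pass through untouched; only the
# columns the costing model uses are typed and validated.

PRACTICE_GROUPS <- c("CM", "Mx", "Ho")
SECTORS <- c("S1", "S2", "NUA")

NONMEDICINAL_FLAGS <- c(
  "sick_leave", "radiology", "ct_scan", "mri", "lab_test",
  "nursing", "physiotherapy", "specialist_referral"
)

VISIT_COLUMNS <- c(
  "visit_id", "practice_group", "sector", "age", "has_dld",
  "has_supplementary_insurance", "sick_leave", "sick_leave_days",
  "radiology", "ct_scan", "mri", "lab_test", "nursing", "physiotherapy",
  "specialist_referral"
)

DRUGLINE_COLUMNS <- c(
  "visit_id", "unit_price", "n_boxes", "tier", "dld_related",
  "is_homeopathic", "drug_class"
)

BREAKDOWN_MONEY_COLUMNS <- c(
  "consultation_ss", "consultation_remaining", "consultation_total",
  "prescription_ss", "prescription_remaining", "prescription_total",
  "total_ss", "total_remaining", "health_expenditure"
)

# Lenient flag coercion: logical, 0/1, or the usual text spellings.
#' @noRd
as_flag <- function(x, column) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) {
      abort_validation(sprintf(
        "column '%s': numeric flags must be 0/1 (first bad row: %d)",
        column, which(bad)[1]
      ))
    }
    return(x == 1)
  }
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[lx %in% c("false", "f", "no", "n", "0")] <- FALSE
  bad <- !is.na(lx) & lx != "" & is.na(out)
  if (any(bad)) {
    abort_validation(sprintf(
      "column '%s': cannot interpret '%s' as a flag (row %d)",
      column, x[which(bad)[1]], which(bad)[1]
    ))
  }
  out
}

#' @noRd
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf(
        "%s: missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "",
        paste(missing, collapse = ", ")
      ),
      class = c("gpcost_schema_error", "gpcost_validation_error")
    )
  }
  invisible(df)
}

#' Validate a visits table
#'
#' Checks the documented schema and the row-level invariants: known practice
#' group and sector codes, non-negative age, logical flags, and
#' \code{sick_leave_days > 0} only when the sick-leave flag is set. Row order
#' is preserved; extra columns pass through.
#'
#' @param visits A data frame of visits (see [read_visits()] for columns).
#' @return The validated tibble, with typed columns.
#' @export
validate_visits <- function(visits) {
  check_columns(visits, VISIT_COLUMNS, "visits")
  visits <- tibble::as_tibble(visits)
  visits$visit_id <- as.character(visits$visit_id)
  if (anyNA(visits$visit_id) || any(visits$visit_id == "")) {
    abort_validation("visits: visit_id must be non-missing")
  }
  if (anyDuplicated(visits$visit_id)) {
    abort_validation(sprintf(
      "visits: duplicated visit_id '%s'",
      visits$visit_id[anyDuplicated(visits$visit_id)]
    ))
  }
  bad <- !visits$practice_group %in% PRACTICE_GROUPS
  if (any(bad)) {
    abort_validation(sprintf(
      "visits: unknown practice_group '%s' (row %d); expected one of %s",
      visits$practice_group[which(bad)[1]], which(bad)[1],
      paste(PRACTICE_GROUPS, collapse = "/")
    ))
  }
  bad <- !visits$sector %in% SECTORS
  if (any(bad)) {
    abort_validation(sprintf(
      "visits: unknown sector '%s' (row %d); expected one of %s",
      visits$sector[which(bad)[1]], which(bad)[1],
      paste(SECTORS, collapse = "/")
    ))
  }
  visits$age <- as.numeric(visits$age)
  bad <- is.na(visits$age) | visits$age < 0
  if (any(bad)) {
    abort_validation(sprintf("visits: age must be >= 0 (row %d)", which(bad)[1]))
  }
  for (col in c("has_dld", "has_supplementary_insurance", NONMEDICINAL_FLAGS)) {
    visits[[col]] <- as_flag(visits[[col]], col)
    if (anyNA(visits[[col]])) {
      abort_validation(sprintf(
        "visits: column '%s' has missing values (row %d)",
        col, which(is.na(visits[[col]]))[1]
      ))
    }
  }
  visits$sick_leave_days <- as.integer(visits$sick_leave_days)
  bad <- is.na(visits$sick_leave_days) | visits$sick_leave_days < 0
  if (any(bad)) {
    abort_validation(sprintf(
      "visits: sick_leave_days must be a non-negative integer (row %d)",
      which(bad)[1]
    ))
  }
  bad <- visits$sick_leave_days > 0 & !visits$sick_leave
  if (any(bad)) {
    abort_validation(sprintf(
      "visits: sick_leave_days > 0 without the sick_leave flag (row %d)",
      which(bad)[1]
    ))
  }
  visits
}

#' Validate a drug-lines table
#'
#' Checks prices, box counts, reimbursement tiers against the admissible
#' tiers, and (when \code{visits} is supplied) the cross-table invariants:
#' every line belongs to a known visit and \code{dld_related} lines occur
#' only on visits of DLD patients.
#'
#' @param drug_lines A data frame of prescription lines.
#' @param visits Optional validated visits table for cross-checks.
#' @param drug_tiers Admissible reimbursement fractions.
#' @return The validated tibble.
#' @export
validate_drug_lines <- function(drug_lines, visits = NULL,
                                drug_tiers = c(0.00, 0.35, 0.65, 1.00)) {
  check_columns(drug_lines, DRUGLINE_COLUMNS, "drug lines")
  drug_lines <- tibble::as_tibble(drug_lines)
  drug_lines$visit_id <- as.character(drug_lines$visit_id)
  drug_lines$unit_price <- as.numeric(drug_lines$unit_price)
  bad <- is.na(drug_lines$unit_price) | drug_lines$unit_price < 0
  if (any(bad)) {
    abort_validation(sprintf(
      "drug lines: unit_price must be >= 0 (row %d)", which(bad)[1]
    ))
  }
  drug_lines$n_boxes <- as.integer(drug_lines$n_boxes)
  bad <- is.na(drug_lines$n_boxes) | drug_lines$n_boxes < 1
  if (any(bad)) {
    abort_validation(sprintf(
      "drug lines: n_boxes must be an integer >= 1 (row %d)", which(bad)[1]
    ))
  }
  drug_lines$tier <- as.numeric(drug_lines$tier)
  bad <- is.na(drug_lines$tier) |
    !vapply(drug_lines$tier, function(t) any(abs(t - drug_tiers) < 1e-9), logical(1))
  if (any(bad)) {
    abort_validation(sprintf(
      "drug lines: tier %s not in the admissible tiers {%s} (row %d)",
      drug_lines$tier[which(bad)[1]],
      paste(format(drug_tiers), collapse = ", "), which(bad)[1]
    ))
  }
  for (col in c("dld_related", "is_homeopathic")) {
    drug_lines[[col]] <- as_flag(drug_lines[[col]], col)
    if (anyNA(drug_lines[[col]])) {
      abort_validation(sprintf(
        "drug lines: column '%s' has missing values (row %d)",
        col, which(is.na(drug_lines[[col]]))[1]
      ))
    }
  }
  drug_lines$drug_class <- as.character(drug_lines$drug_class)
  if (!is.null(visits)) {
    unknown <- !drug_lines$visit_id %in% visits$visit_id
    if (any(unknown)) {
      abort_validation(sprintf(
        "drug lines: visit_id '%s' not present in the visits table (row %d)",
        drug_lines$visit_id[which(unknown)[1]], which(unknown)[1]
      ))
    }
    dld_by_visit <- stats::setNames(visits$has_dld, visits$visit_id)
    bad <- drug_lines$dld_related & !dld_by_visit[drug_lines$visit_id]
    if (any(bad)) {
      abort_validation(sprintf(
        "drug lines: dld_related line on a visit without DLD status (row %d, visit '%s')",
        which(bad)[1], drug_lines$visit_id[which(bad)[1]]
      ))
    }
  }
  drug_lines
}

#' Read and validate a visits CSV
#'
#' Expected columns: \code{visit_id, practice_group, sector, age, has_dld,
#' has_supplementary_insurance, sick_leave, sick_leave_days, radiology,
#' ct_scan, mri, lab_test, nursing, physiotherapy, specialist_referral}.
#' Additional columns are kept as-is. Row order is preserved.
#'
#' @param path Path to the visits CSV.
#' @return A validated tibble of visits.
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("visits file not found: %s", path))
  validate_visits(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Read and validate a drug-lines CSV
#'
#' Expected columns: \code{visit_id, unit_price, n_boxes, tier, dld_related,
#' is_homeopathic, drug_class}. When a visits table is supplied the
#' cross-table invariants are enforced as well.
#'
#' @inheritParams validate_drug_lines
#' @param path Path to the drug-lines CSV.
#' @return A validated tibble of drug lines.
#' @export
read_drug_lines <- function(path, visits = NULL,
                            drug_tiers = c(0.00, 0.35, 0.65, 1.00)) {
  if (!file.exists(path)) abort_io(sprintf("drug-lines file not found: %s", path))
  lines <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(drug_class = readr::col_character()))
  validate_drug_lines(lines, visits = visits, drug_tiers = drug_tiers)
}

#' Read a full cohort (visits plus drug lines)
#'
#' Convenience wrapper reading and cross-validating the two-file layout.
#'
#' @param visits_path,drugs_path CSV paths.
#' @param tariff Optional \code{tariff_schedule} supplying the admissible
#'   drug tiers (defaults to the 2008 schedule).
#' @return A list with elements \code{visits} and \code{drug_lines}.
#' @export
read_cohort <- function(visits_path, drugs_path, tariff = tariff_schedule()) {
  visits <- read_visits(visits_path)
  drug_lines <- read_drug_lines(drugs_path, visits = visits,
                                drug_tiers = tariff$drug_tiers)
  list(visits = visits, drug_lines = drug_lines)
}

#' Write per-visit cost breakdowns to CSV
#'
#' One row per visit; the nine money cells are written at exact two-decimal
#' precision so that a read-back round-trips cent-for-cent. An empty input
#' produces a header-only file.
#'
#' @param breakdowns A breakdown table from [cost_visits()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_breakdowns <- function(breakdowns, path) {
  check_columns(breakdowns,
                c("visit_id", BREAKDOWN_MONEY_COLUMNS, "consultation_costed"),
                "breakdowns")
  out <- tibble::as_tibble(breakdowns)
  for (col in BREAKDOWN_MONEY_COLUMNS) {
    out[[col]] <- format_eur(out[[col]])
  }
  if (nrow(breakdowns) == 0) {
    # keep the empty-table header identical to the non-empty case
    for (col in BREAKDOWN_MONEY_COLUMNS) out[[col]] <- character(0)
  }
  ok <- tryCatch(
    {
      readr::write_csv(out, path, progress = FALSE)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) abort_io(sprintf("cannot write breakdowns to '%s'", path))
  invisible(path)
}

#' Read a cost-breakdown CSV written by [write_breakdowns()]
#'
#' @param path Input CSV path.
#' @return A tibble with numeric money columns and a logical
#'   \code{consultation_costed} flag.
#' @export
read_breakdowns <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("breakdowns file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("visit_id", BREAKDOWN_MONEY_COLUMNS, "consultation_costed"),
                "breakdowns")
  df$visit_id <- as.character(df$visit_id)
  for (col in BREAKDOWN_MONEY_COLUMNS) df[[col]] <- as.numeric(df[[col]])
  df$consultation_costed <- as_flag(df$consultation_costed, "consultation_costed")
  df
}
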