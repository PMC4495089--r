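#' Tariff schedule for the 2008 French GP costing model
#'
#' Bundles every monetary parameter of the costing rules: sector-1 and
#' sector-2 consultation tariffs, the contractual base on which Social
#' Security computes its share (for both sectors), the statutory consultation
#' share, the adult per-consultation lump sum (participation forfaitaire),
#' the per-box franchise on reimbursed medicines, and the admissible drug
#' reimbursement tiers.
#'
#' Defaults are the 2008 statutory values: 22 EUR (sector 1) and a flat
#' 32 EUR (sector 2) consultation, Social Security bearing 70% of the 22 EUR
#' contractual base (100% for long-duration-disease care), a 1 EUR lump sum
#' for patients aged over 18, a 0.25 EUR franchise per reimbursed box, and
#' reimbursement tiers 0%, 35%, 65% and 100%.
#'
#' @param consultation_tariff_sector1 Consultation price, sector-1 GPs (EUR).
#' @param consultation_tariff_sector2 Consultation price, sector-2 GPs (EUR).
#'   Must be at least the sector-1 tariff.
#' @param contractual_base Amount on which the Social-Security share is
#'   computed, for both sectors (EUR). The sector-2 excess over this base is
#'   never reimbursed.
#' @param ss_consultation_share Fraction of the contractual base borne by
#'   Social Security for non-DLD care, in \code{[0, 1]}.
#' @param adult_lump_sum Per-consultation patient participation deducted from
#'   the Social-Security share for adults (EUR).
#' @param adult_age_threshold Strict age threshold (years): the lump sum
#'   applies to patients aged strictly above it.
#' @param franchise_per_box Patient franchise per reimbursed box of medicine
#'   (EUR); not levied on unreimbursed (tier 0) drugs.
#' @param drug_tiers Admissible reimbursement fractions for drug lines.
#' @param child_franchise_exempt If \code{TRUE}, patients at or below
#'   \code{adult_age_threshold} pay no per-box franchise. Off by default: the
#'   2008 accounting convention modelled here applies the franchise
#'   unconditionally.
#' @param lump_sum_mode How the adult lump sum enters the consultation split:
#'   \code{"net_ss"} (default) nets it against the Social-Security share, so
#'   it appears in the remaining cost; \code{"add_patient"} charges it on top
#'   of the tariff as a separate patient amount.
#'
#' @return A validated object of class \code{tariff_schedule} (a named list).
#' @examples
#' tariff_schedule()
#' tariff_schedule(child_franchise_exempt = TRUE)
#' @seealso [read_tariff()] to load a schedule from YAML/JSON.
#' @export
tariff_schedule <- function(consultation_tariff_sector1 = 22.00,
                            consultation_tariff_sector2 = 32.00,
                            contractual_base = 22.00,
                            ss_consultation_share = 0.70,
                            adult_lump_sum = 1.00,
                            adult_age_threshold = 18,
                            franchise_per_box = 0.25,
                            drug_tiers = c(0.00, 0.35, 0.65, 1.00),
                            child_franchise_exempt = FALSE,
                            lump_sum_mode = c("net_ss", "add_patient")) {
  tariff <- list(
    consultation_tariff_sector1 = as.numeric(consultation_tariff_sector1),
    consultation_tariff_sector2 = as.numeric(consultation_tariff_sector2),
    contractual_base = as.numeric(contractual_base),
    ss_consultation_share = as.numeric(ss_consultation_share),
    adult_lump_sum = as.numeric(adult_lump_sum),
    adult_age_threshold = as.numeric(adult_age_threshold),
    franchise_per_box = as.numeric(franchise_per_box),
    drug_tiers = sort(as.numeric(drug_tiers)),
    child_franchise_exempt = isTRUE(child_franchise_exempt),
    lump_sum_mode = match.arg(lump_sum_mode)
  )
  class(tariff) <- "tariff_schedule"
  validate_tariff(tariff)
}

#' @noRd
validate_tariff <- function(tariff) {
  money_fields <- c(
    "consultation_tariff_sector1", "consultation_tariff_sector2",
    "contractual_base", "adult_lump_sum", "franchise_per_box"
  )
  for (f in money_fields) {
    v <- tariff[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      abort_validation(sprintf("tariff field '%s' must be a single non-negative number", f))
    }
  }
  s <- tariff$ss_consultation_share
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0 || s > 1) {
    abort_validation("tariff field 'ss_consultation_share' must lie in [0, 1]")
  }
  if (tariff$consultation_tariff_sector2 < tariff$consultation_tariff_sector1) {
    abort_validation("sector-2 consultation tariff must be >= sector-1 tariff")
  }
  if (any(is.na(tariff$drug_tiers)) || any(tariff$drug_tiers < 0) ||
      any(tariff$drug_tiers > 1)) {
    abort_validation("tariff field 'drug_tiers' must be fractions in [0, 1]")
  }
  if (!is.numeric(tariff$adult_age_threshold) || tariff$adult_age_threshold < 0) {
    abort_validation("tariff field 'adult_age_threshold' must be non-negative")
  }
  tariff
}

#' Read a tariff schedule from a YAML or JSON file
#'
#' Field names in the file mirror the arguments of [tariff_schedule()];
#' omitted fields keep their defaults. Unknown keys are an error so that
#' typos in a config file do not silently fall back to defaults.
#'
#' @param path Path to a YAML (or JSON, by extension) tariff file.
#' @return A validated \code{tariff_schedule}.
#' @export
read_tariff <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("tariff file not found: %s", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- names(formals(tariff_schedule))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "unknown tariff key%s: %s",
      if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")
    ))
  }
  do.call(tariff_schedule, raw)
}

#' Write a tariff schedule to YAML
#'
#' @param tariff A \code{tariff_schedule}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tariff <- function(tariff, path) {
  stopifnot(inherits(tariff, "tariff_schedule"))
  yaml::write_yaml(unclass(tariff), path)
  invisible(path)
}

#' @export
print.tariff_schedule <- function(x, ...) {
  cat("<tariff_schedule> 2008 French GP costing parameters\n")
  cat(sprintf("  consultation: sector 1 %s EUR, sector 2 %s EUR (contractual base %s EUR)\n",
              format_eur(x$consultation_tariff_sector1),
              format_eur(x$consultation_tariff_sector2),
              format_eur(x$contractual_base)))
  cat(sprintf("  Social-Security share %.0f%% (100%% for DLD care); adult lump sum %s EUR (age > %g, %s)\n",
              100 * x$ss_consultation_share, format_eur(x$adult_lump_sum),
              x$adult_age_threshold, x$lump_sum_mode))
  cat(sprintf("  drug tiers: %s; franchise %s EUR/box%s\n",
              paste(sprintf("%.0f%%", 100 * x$drug_tiers), collapse = "/"),
              format_eur(x$franchise_per_box),
              if (x$child_franchise_exempt) " (children exempt)" else ""))
  invisible(x)
}
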