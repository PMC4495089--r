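# Cost-attribution rules of the 2008 French statutory system.
#
# Consultation: sector-1 visits cost the statutory tariff (22 EUR), sector-2
# visits a flat 32 EUR. Social Security reimburses its share on the 22 EUR
# contractual base in both sectors (70%, or 100% for DLD patients); the
# sector-2 excess is never reimbursed and falls entirely on the patient /
# supplementary insurer. Adults pay a 1 EUR lump sum, netted against the
# Social-Security share by default. "Not under agreement" (NUA) consultations
# are not reimbursed and cannot be costed: they contribute zero and carry
# consultation_costed = FALSE; their prescriptions are costed normally.
#
# Drugs: line total = unit price x boxes. Effective reimbursement rate is
# 100% for DLD-related lines, otherwise the drug's statutory tier. The
# Social-Security amount is rate x total minus the 0.25 EUR per-box
# franchise, floored at zero per line; tier-0 drugs carry no franchise and
# no reimbursement. All arithmetic is in integer cents.

#' Consultation cost split for one visit
#'
#' Applies the consultation rules to a single visit and returns the
#' Social-Security share, the remaining cost (patient and/or supplementary
#' insurance), the total, and whether the consultation could be costed at
#' all (\code{FALSE} for "Not under agreement" GPs).
#'
#' @param visit A one-row data frame or named list with at least
#'   \code{sector}, \code{age} and \code{has_dld}.
#' @param tariff A [tariff_schedule()].
#' @return A named list \code{(ss, remaining, total, costed)}, money in EUR.
#' @examples
#' v <- list(sector = "S1", age = 40, has_dld = FALSE)
#' consultation_cost(v, tariff_schedule())  # ss 14.40, remaining 7.60
#' @export
consultation_cost <- function(visit, tariff = tariff_schedule()) {
  sector <- as.character(visit$sector)
  if (sector == "NUA") {
    return(list(ss = 0, remaining = 0, total = 0, costed = FALSE))
  }
  tariff_c <- as_cents(switch(sector,
    S1 = tariff$consultation_tariff_sector1,
    S2 = tariff$consultation_tariff_sector2,
    abort_validation(sprintf("unknown sector '%s'", sector))
  ))
  base_c <- as_cents(tariff$contractual_base)
  share <- if (isTRUE(visit$has_dld)) 1 else tariff$ss_consultation_share
  ss_c <- mul_rate_cents(share, base_c)
  adult <- visit$age > tariff$adult_age_threshold
  lump_c <- if (adult) as_cents(tariff$adult_lump_sum) else 0L
  if (tariff$lump_sum_mode == "net_ss") {
    total_c <- tariff_c
    ss_c <- max(0L, ss_c - lump_c)
  } else {
    total_c <- tariff_c + lump_c
  }
  ss_c <- min(ss_c, total_c)
  list(
    ss = cents_to_eur(ss_c),
    remaining = cents_to_eur(total_c - ss_c),
    total = cents_to_eur(total_c),
    costed = TRUE
  )
}

#' Payer split for one prescribed drug line
#'
#' @param line A one-row data frame or named list with \code{unit_price},
#'   \code{n_boxes}, \code{tier} and \code{dld_related}.
#' @param tariff A [tariff_schedule()].
#' @param apply_franchise Whether the per-box franchise is levied (set to
#'   \code{FALSE} by [prescription_cost()] for children when the schedule
#'   exempts them).
#' @return A named list \code{(ss, remaining, total)}, money in EUR.
#' @examples
#' l <- list(unit_price = 10, n_boxes = 1, tier = 0.65, dld_related = FALSE)
#' drug_line_split(l, tariff_schedule())  # ss 6.25, remaining 3.75
#' @export
drug_line_split <- function(line, tariff = tariff_schedule(),
                            apply_franchise = TRUE) {
  price_c <- as_cents(line$unit_price)
  n <- as.integer(line$n_boxes)
  total_c <- price_c * n
  rate <- if (isTRUE(line$dld_related)) 1 else as.numeric(line$tier)
  if (rate <= 0) {
    ss_c <- 0L
  } else {
    franchise_c <- if (apply_franchise) as_cents(tariff$franchise_per_box) * n else 0L
    ss_c <- max(0L, mul_rate_cents(rate, total_c) - franchise_c)
  }
  ss_c <- min(ss_c, total_c)
  list(
    ss = cents_to_eur(ss_c),
    remaining = cents_to_eur(total_c - ss_c),
    total = cents_to_eur(total_c)
  )
}

#' @noRd
franchise_applies <- function(visit, tariff) {
  !(tariff$child_franchise_exempt && visit$age <= tariff$adult_age_threshold)
}

#' Prescription cost split for one visit
#'
#' Component-wise sum of [drug_line_split()] over the visit's drug lines;
#' an empty prescription costs zero to every payer.
#'
#' @param visit A one-row data frame or named list (needs \code{visit_id}
#'   and \code{age}).
#' @param drug_lines Drug-lines table; only rows matching
#'   \code{visit$visit_id} are used.
#' @param tariff A [tariff_schedule()].
#' @return A named list \code{(ss, remaining, total)}, money in EUR.
#' @export
prescription_cost <- function(visit, drug_lines, tariff = tariff_schedule()) {
  lines <- drug_lines[as.character(drug_lines$visit_id) == as.character(visit$visit_id), ,
                      drop = FALSE]
  ss_c <- 0L; rem_c <- 0L; tot_c <- 0L
  apply_fr <- franchise_applies(visit, tariff)
  if (nrow(lines) > 0) {
    for (i in seq_len(nrow(lines))) {
      s <- drug_line_split(lines[i, ], tariff, apply_franchise = apply_fr)
      ss_c <- ss_c + as_cents(s$ss)
      rem_c <- rem_c + as_cents(s$remaining)
      tot_c <- tot_c + as_cents(s$total)
    }
  }
  list(ss = cents_to_eur(ss_c), remaining = cents_to_eur(rem_c),
       total = cents_to_eur(tot_c))
}

#' Full three-by-three cost breakdown for one visit
#'
#' Assembles the consultation, prescription and total rows, each split into
#' Social-Security, remaining and total (health-expenditure) columns. For
#' NUA visits the consultation row is zero and \code{consultation_costed}
#' is \code{FALSE}; the totals then equal the prescription row alone.
#'
#' @inheritParams prescription_cost
#' @return A one-row tibble with the nine money cells and the
#'   \code{consultation_costed} flag.
#' @export
total_management_cost <- function(visit, drug_lines, tariff = tariff_schedule()) {
  cons <- consultation_cost(visit, tariff)
  rx <- prescription_cost(visit, drug_lines, tariff)
  tibble::tibble(
    visit_id = as.character(visit$visit_id),
    consultation_ss = cons$ss,
    consultation_remaining = cons$remaining,
    consultation_total = cons$total,
    prescription_ss = rx$ss,
    prescription_remaining = rx$remaining,
    prescription_total = rx$total,
    total_ss = cons$ss + rx$ss,
    total_remaining = cons$remaining + rx$remaining,
    health_expenditure = cons$total + rx$total,
    consultation_costed = cons$costed
  )
}

#' Cost every visit in a cohort (vectorized engine)
#'
#' Applies the full costing model to a visits table and its drug lines in
#' one vectorized pass. This is the production engine; it is checked
#' field-for-field against the straight-line reference
#' [cost_visits_reference()] in the test suite.
#'
#' @param visits Validated visits table.
#' @param drug_lines Validated drug-lines table.
#' @param tariff A [tariff_schedule()].
#' @return A tibble with one row per visit, in the input order: identifiers
#'   (\code{visit_id, practice_group, sector}), the nine money cells of the
#'   breakdown, and \code{consultation_costed}.
#' @export
cost_visits <- function(visits, drug_lines, tariff = tariff_schedule()) {
  n <- nrow(visits)
  sector <- as.character(visits$sector)
  costed <- sector != "NUA"

  t1 <- as_cents(tariff$consultation_tariff_sector1)
  t2 <- as_cents(tariff$consultation_tariff_sector2)
  base_c <- as_cents(tariff$contractual_base)
  lump_c <- as_cents(tariff$adult_lump_sum)

  tariff_c <- ifelse(sector == "S2", t2, t1)
  share <- ifelse(visits$has_dld, 1, tariff$ss_consultation_share)
  ss_c <- mul_rate_cents(share, base_c)
  adult <- visits$age > tariff$adult_age_threshold
  if (tariff$lump_sum_mode == "net_ss") {
    cons_total_c <- tariff_c
    ss_c <- pmax(0L, ss_c - lump_c * adult)
  } else {
    cons_total_c <- tariff_c + lump_c * adult
  }
  ss_c <- pmin(ss_c, cons_total_c)
  cons_ss_c <- ifelse(costed, ss_c, 0L)
  cons_total_c <- ifelse(costed, cons_total_c, 0L)
  cons_rem_c <- cons_total_c - cons_ss_c

  # drug lines, vectorized then aggregated per visit
  if (nrow(drug_lines) > 0) {
    price_c <- as_cents(drug_lines$unit_price)
    boxes <- as.integer(drug_lines$n_boxes)
    line_total_c <- price_c * boxes
    rate <- ifelse(drug_lines$dld_related, 1, drug_lines$tier)
    idx <- match(as.character(drug_lines$visit_id), as.character(visits$visit_id))
    apply_fr <- if (tariff$child_franchise_exempt) {
      visits$age[idx] > tariff$adult_age_threshold
    } else {
      rep(TRUE, nrow(drug_lines))
    }
    franchise_c <- as_cents(tariff$franchise_per_box) * boxes * apply_fr
    line_ss_c <- ifelse(
      rate > 0,
      pmax(0L, mul_rate_cents(rate, line_total_c) - franchise_c),
      0L
    )
    line_ss_c <- pmin(line_ss_c, line_total_c)
    rx_ss_c <- as.integer(rowsum_by(line_ss_c, idx, n))
    rx_total_c <- as.integer(rowsum_by(line_total_c, idx, n))
  } else {
    rx_ss_c <- rx_total_c <- integer(n)
  }
  rx_rem_c <- rx_total_c - rx_ss_c

  tibble::tibble(
    visit_id = as.character(visits$visit_id),
    practice_group = as.character(visits$practice_group),
    sector = sector,
    consultation_ss = cents_to_eur(cons_ss_c),
    consultation_remaining = cents_to_eur(cons_rem_c),
    consultation_total = cents_to_eur(cons_total_c),
    prescription_ss = cents_to_eur(rx_ss_c),
    prescription_remaining = cents_to_eur(rx_rem_c),
    prescription_total = cents_to_eur(rx_total_c),
    total_ss = cents_to_eur(cons_ss_c + rx_ss_c),
    total_remaining = cents_to_eur(cons_rem_c + rx_rem_c),
    health_expenditure = cents_to_eur(cons_total_c + rx_total_c),
    consultation_costed = costed
  )
}

# sum x within groups given by idx (1..n), returning a length-n vector
#' @noRd
rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(as.numeric(x), idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Straight-line reference costing (per visit, per line, per box)
#'
#' Independent scalar implementation of the same attribution rules, looping
#' over visits, lines and boxes with no vectorization. Exists to
#' cross-check [cost_visits()]; the two must agree cent-for-cent on every
#' cell.
#'
#' @inheritParams cost_visits
#' @return Same shape as [cost_visits()].
#' @export
cost_visits_reference <- function(visits, drug_lines, tariff = tariff_schedule()) {
  if (nrow(visits) == 0) {
    return(cost_visits(visits[0, ], drug_lines[0, ], tariff))
  }
  rows <- vector("list", nrow(visits))
  for (i in seq_len(nrow(visits))) {
    visit <- visits[i, ]
    cons <- consultation_cost(visit, tariff)
    lines <- drug_lines[as.character(drug_lines$visit_id) == visit$visit_id, ,
                        drop = FALSE]
    apply_fr <- franchise_applies(visit, tariff)
    rx_ss_c <- 0L; rx_total_c <- 0L
    if (nrow(lines) > 0) {
      for (j in seq_len(nrow(lines))) {
        price_c <- as_cents(lines$unit_price[j])
        nb <- as.integer(lines$n_boxes[j])
        rate <- if (isTRUE(lines$dld_related[j])) 1 else lines$tier[j]
        rate_bp <- round(rate * 1e4)    # rate in basis points: exact integers
        acc_bp <- 0
        total_c <- 0L
        franchise_c <- 0L
        for (b in seq_len(nb)) {        # box-by-box accumulation
          total_c <- total_c + price_c
          acc_bp <- acc_bp + rate_bp * price_c
          if (apply_fr) franchise_c <- franchise_c + as_cents(tariff$franchise_per_box)
        }
        line_ss_c <- if (rate > 0) {
          max(0L, as.integer((acc_bp + 5e3) %/% 1e4) - franchise_c)
        } else {
          0L
        }
        line_ss_c <- min(line_ss_c, total_c)
        rx_ss_c <- rx_ss_c + line_ss_c
        rx_total_c <- rx_total_c + total_c
      }
    }
    cons_ss_c <- as_cents(cons$ss)
    cons_total_c <- as_cents(cons$total)
    rows[[i]] <- tibble::tibble(
      visit_id = as.character(visit$visit_id),
      practice_group = as.character(visit$practice_group),
      sector = as.character(visit$sector),
      consultation_ss = cents_to_eur(cons_ss_c),
      consultation_remaining = cents_to_eur(cons_total_c - cons_ss_c),
      consultation_total = cents_to_eur(cons_total_c),
      prescription_ss = cents_to_eur(rx_ss_c),
      prescription_remaining = cents_to_eur(rx_total_c - rx_ss_c),
      prescription_total = cents_to_eur(rx_total_c),
      total_ss = cents_to_eur(cons_ss_c + rx_ss_c),
      total_remaining = cents_to_eur((cons_total_c - cons_ss_c) + (rx_total_c - rx_ss_c)),
      health_expenditure = cents_to_eur(cons_total_c + rx_total_c),
      consultation_costed = cons$costed
    )
  }
  dplyr::bind_rows(rows)
}
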