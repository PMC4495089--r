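# Builders for in-code fixtures: a minimal visit row, diverse random
# cohorts for property tests (wider parameter coverage than the survey
# emulator: all sectors, tier 1.00 lines, odd-cent prices, extreme ages),
# and random but internally consistent breakdown tables.

make_visit <- function(visit_id = "V1", practice_group = "CM", sector = "S1",
                       age = 40, has_dld = FALSE,
                       has_supplementary_insurance = TRUE,
                       sick_leave = FALSE, sick_leave_days = 0L) {
  tibble::tibble(
    visit_id = visit_id, practice_group = practice_group, sector = sector,
    age = age, has_dld = has_dld,
    has_supplementary_insurance = has_supplementary_insurance,
    sick_leave = sick_leave, sick_leave_days = as.integer(sick_leave_days),
    radiology = FALSE, ct_scan = FALSE, mri = FALSE, lab_test = FALSE,
    nursing = FALSE, physiotherapy = FALSE, specialist_referral = FALSE
  )
}

make_line <- function(visit_id = "V1", unit_price = 10, n_boxes = 1L,
                      tier = 0.65, dld_related = FALSE,
                      is_homeopathic = FALSE, drug_class = NA_character_) {
  tibble::tibble(
    visit_id = visit_id, unit_price = unit_price,
    n_boxes = as.integer(n_boxes), tier = tier, dld_related = dld_related,
    is_homeopathic = is_homeopathic, drug_class = drug_class
  )
}

# Diverse random cohort, independent of the survey emulator.
make_random_cohort <- function(n, seed) {
  set.seed(seed)
  visits <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_visit(
      visit_id = sprintf("R%05d", i),
      practice_group = sample(c("CM", "Mx", "Ho"), 1),
      sector = sample(c("S1", "S2", "NUA"), 1, prob = c(0.6, 0.3, 0.1)),
      age = sample(0:100, 1),
      has_dld = runif(1) < 0.3
    )
  }))
  n_lines <- rpois(n, 2.5)
  idx <- rep(seq_len(n), n_lines)
  m <- length(idx)
  lines <- if (m == 0) make_line()[0, ] else tibble::tibble(
    visit_id = visits$visit_id[idx],
    unit_price = round(runif(m, 0.01, 60), 2),
    n_boxes = sample(1:5, m, replace = TRUE),
    tier = sample(c(0, 0.35, 0.65, 1), m, replace = TRUE),
    dld_related = visits$has_dld[idx] & runif(m) < 0.5,
    is_homeopathic = runif(m) < 0.2,
    drug_class = sample(c("N02", "J01", NA), m, replace = TRUE)
  )
  list(visits = validate_visits(visits),
       drug_lines = validate_drug_lines(lines, visits = visits))
}

make_random_breakdowns <- function(n, seed) {
  set.seed(seed)
  cons_ss <- sample(0:3200, n, replace = TRUE)
  cons_tot <- cons_ss + sample(0:1500, n, replace = TRUE)
  rx_ss <- sample(0:9000, n, replace = TRUE)
  rx_tot <- rx_ss + sample(0:4000, n, replace = TRUE)
  costed <- runif(n) < 0.9
  cons_ss[!costed] <- 0; cons_tot[!costed] <- 0
  tibble::tibble(
    visit_id = sprintf("B%05d", seq_len(n)),
    practice_group = sample(c("CM", "Mx", "Ho"), n, replace = TRUE),
    sector = ifelse(costed, "S1", "NUA"),
    consultation_ss = cons_ss / 100,
    consultation_remaining = (cons_tot - cons_ss) / 100,
    consultation_total = cons_tot / 100,
    prescription_ss = rx_ss / 100,
    prescription_remaining = (rx_tot - rx_ss) / 100,
    prescription_total = rx_tot / 100,
    total_ss = (cons_ss + rx_ss) / 100,
    total_remaining = (cons_tot - cons_ss + rx_tot - rx_ss) / 100,
    health_expenditure = (cons_tot + rx_tot) / 100,
    consultation_costed = costed
  )
}

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "gpcost")
  if (path == "") path <- file.path("..", "..", "inst", "extdata", name)
  path
}

cents <- function(x) as.integer(round(x * 100))
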