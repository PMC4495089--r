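tariff <- tariff_schedule()

test_that("consultation split follows the sector, DLD, age and NUA rules", {
  # adult, non-DLD, sector 1: SS pays 70% of 22 minus the 1 EUR lump sum
  r <- consultation_cost(make_visit(age = 40), tariff)
  expect_equal(r$ss, 14.40)
  expect_equal(r$remaining, 7.60)
  expect_equal(r$total, 22)
  expect_true(r$costed)

  # child: no lump sum
  r <- consultation_cost(make_visit(age = 10), tariff)
  expect_equal(r$ss, 15.40)
  expect_equal(r$remaining, 6.60)

  # age exactly at the threshold is not "aged > 18"
  r18 <- consultation_cost(make_visit(age = 18), tariff)
  expect_equal(r18$ss, 15.40)

  # adult DLD, sector 2: SS pays the full contractual base minus the lump
  # sum; the 10 EUR sector-2 excess falls entirely in the remaining cost
  r <- consultation_cost(make_visit(age = 50, sector = "S2", has_dld = TRUE), tariff)
  expect_equal(r$ss, 21)
  expect_equal(r$remaining, 11)
  expect_equal(r$total, 32)

  # not under agreement: nothing can be costed
  r <- consultation_cost(make_visit(sector = "NUA"), tariff)
  expect_equal(unlist(r[c("ss", "remaining", "total")]), c(ss = 0, remaining = 0, total = 0))
  expect_false(r$costed)
})

test_that("drug-line split applies tier, DLD override, franchise and the zero floor", {
  s <- drug_line_split(make_line(unit_price = 10, n_boxes = 1, tier = 0.65), tariff)
  expect_equal(s$ss, 6.25)
  expect_equal(s$remaining, 3.75)

  # unreimbursed drug: no SS share, no franchise
  s <- drug_line_split(make_line(unit_price = 8, tier = 0), tariff)
  expect_equal(s$ss, 0)
  expect_equal(s$remaining, 8)

  # floor at zero when the reimbursement is below the franchise
  s <- drug_line_split(make_line(unit_price = 0.20, tier = 0.35), tariff)
  expect_equal(s$ss, 0)
  expect_equal(s$remaining, 0.20)

  # DLD-related: 100% rate regardless of tier, franchise still due per box
  s <- drug_line_split(make_line(unit_price = 10, n_boxes = 2, tier = 0.35,
                                 dld_related = TRUE), tariff)
  expect_equal(s$ss, 19.50)
  expect_equal(s$remaining, 0.50)
})

test_that("prescription cost is the component-wise sum over lines", {
  v <- make_visit("V1", age = 40)
  expect_equal(prescription_cost(v, make_line()[0, ], tariff),
               list(ss = 0, remaining = 0, total = 0))

  lines <- dplyr::bind_rows(
    make_line("V1", unit_price = 10, tier = 0.65),
    make_line("V1", unit_price = 4.5, n_boxes = 2, tier = 0.35),
    make_line("V1", unit_price = 3, tier = 0)
  )
  got <- prescription_cost(v, lines, tariff)
  parts <- lapply(seq_len(nrow(lines)), function(i)
    drug_line_split(lines[i, ], tariff))
  expect_equal(got$ss, sum(vapply(parts, `[[`, numeric(1), "ss")))
  expect_equal(got$remaining, sum(vapply(parts, `[[`, numeric(1), "remaining")))
  expect_equal(got$total, sum(vapply(parts, `[[`, numeric(1), "total")))
})

test_that("full breakdown assembles the grid with conservation in every row", {
  # NUA, no drugs: all-zero grid
  b <- total_management_cost(make_visit("V1", sector = "NUA"), make_line()[0, ], tariff)
  expect_false(b$consultation_costed)
  money_cols <- c("consultation_ss", "consultation_remaining", "consultation_total",
                  "prescription_ss", "prescription_remaining", "prescription_total",
                  "total_ss", "total_remaining", "health_expenditure")
  expect_true(all(b[, money_cols] == 0))

  # adult sector-1 non-DLD with one 10 EUR tier-0.65 box
  b <- total_management_cost(make_visit("V1", age = 40),
                             make_line("V1", unit_price = 10, tier = 0.65), tariff)
  expect_equal(b$health_expenditure, 32)
  expect_equal(b$total_ss, 20.65)
  expect_equal(b$total_remaining, 11.35)
  expect_equal(b$consultation_ss + b$consultation_remaining, b$consultation_total)
  expect_equal(b$prescription_ss + b$prescription_remaining, b$prescription_total)
  expect_equal(b$total_ss + b$total_remaining, b$health_expenditure)
})

test_that("conservation holds cent-exactly across a diverse random cohort", {
  co <- make_random_cohort(400, seed = 3)
  b <- cost_visits(co$visits, co$drug_lines, tariff)
  expect_equal(cents(b$consultation_ss) + cents(b$consultation_remaining),
               cents(b$consultation_total))
  expect_equal(cents(b$prescription_ss) + cents(b$prescription_remaining),
               cents(b$prescription_total))
  expect_equal(cents(b$total_ss) + cents(b$total_remaining),
               cents(b$health_expenditure))
  expect_equal(cents(b$total_ss), cents(b$consultation_ss) + cents(b$prescription_ss))
  expect_true(all(as.matrix(b[, c("consultation_ss", "consultation_remaining",
                                  "prescription_ss", "prescription_remaining")]) >= 0))
  # NUA visits: zero consultation, prescriptions still costed
  nua <- b[b$sector == "NUA", ]
  expect_true(all(!nua$consultation_costed))
  expect_true(all(nua$consultation_total == 0))
  expect_equal(cents(nua$health_expenditure), cents(nua$prescription_total))
})

test_that("raising a line's tier never lowers its Social-Security share", {
  set.seed(5)
  for (i in 1:200) {
    price <- round(runif(1, 0.01, 50), 2)
    boxes <- sample(1:4, 1)
    ss <- vapply(c(0, 0.35, 0.65, 1), function(t) {
      drug_line_split(make_line(unit_price = price, n_boxes = boxes, tier = t),
                      tariff)$ss
    }, numeric(1))
    expect_true(all(diff(ss) >= 0),
                info = sprintf("price %.2f x %d boxes", price, boxes))
  }
})

test_that("granting DLD status never lowers the Social-Security total", {
  set.seed(6)
  for (i in 1:100) {
    v0 <- make_visit("X", age = sample(0:90, 1),
                     sector = sample(c("S1", "S2"), 1), has_dld = FALSE)
    lines0 <- make_line("X", unit_price = round(runif(1, 0.1, 40), 2),
                        n_boxes = sample(1:3, 1),
                        tier = sample(c(0, 0.35, 0.65), 1))
    v1 <- v0; v1$has_dld <- TRUE
    lines1 <- lines0; lines1$dld_related <- TRUE
    b0 <- total_management_cost(v0, lines0, tariff)
    b1 <- total_management_cost(v1, lines1, tariff)
    expect_gte(b1$total_ss, b0$total_ss)
  }
})

test_that("adult remaining consultation cost is bounded below and exact for sector 1", {
  co <- make_random_cohort(300, seed = 9)
  b <- cost_visits(co$visits, co$drug_lines, tariff)
  adult <- co$visits$age > 18 & co$visits$sector != "NUA"
  excess <- ifelse(co$visits$sector == "S2", 10, 0)
  expect_true(all(b$consultation_remaining[adult] >= (1 + excess[adult]) - 1e-9))
  s1 <- adult & co$visits$sector == "S1" & !co$visits$has_dld
  expect_true(all(abs(b$consultation_remaining[s1] - 7.60) < 1e-9))
})

test_that("vectorized engine equals the straight-line reference on every cell", {
  co <- make_random_cohort(250, seed = 21)
  a <- cost_visits(co$visits, co$drug_lines, tariff)
  r <- cost_visits_reference(co$visits, co$drug_lines, tariff)
  for (col in c("consultation_ss", "consultation_remaining", "consultation_total",
                "prescription_ss", "prescription_remaining", "prescription_total",
                "total_ss", "total_remaining", "health_expenditure")) {
    expect_identical(cents(a[[col]]), cents(r[[col]]), info = col)
  }
  expect_identical(a$consultation_costed, r$consultation_costed)
})

test_that("config switches: child franchise exemption and gross lump sum", {
  t_exempt <- tariff_schedule(child_franchise_exempt = TRUE)
  v_child <- make_visit("C", age = 10)
  l <- make_line("C", unit_price = 10, tier = 0.65)
  expect_equal(prescription_cost(v_child, l, t_exempt)$ss, 6.50)
  expect_equal(prescription_cost(make_visit("C", age = 40), l, t_exempt)$ss, 6.25)

  t_gross <- tariff_schedule(lump_sum_mode = "add_patient")
  r <- consultation_cost(make_visit(age = 40), t_gross)
  expect_equal(r$total, 23)          # lump sum charged on top
  expect_equal(r$ss, 15.40)          # SS share not netted
  expect_equal(r$remaining, 7.60)
  expect_equal(r$ss + r$remaining, r$total)
})
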