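test_that("the shipped three-visit example reads with all invariants satisfied", {
  co <- read_cohort(fixture_path("example_visits.csv"),
                    fixture_path("example_druglines.csv"))
  expect_equal(nrow(co$visits), 3)
  expect_equal(nrow(co$drug_lines), 5)
  expect_type(co$visits$has_dld, "logical")
  expect_true(all(co$drug_lines$tier %in% c(0, 0.35, 0.65, 1)))
  # row order preserved
  expect_equal(co$visits$visit_id, c("V1", "V2", "V3"))
})

test_that("a visit with an empty drug-lines file yields zero lines", {
  vp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_visit(), vp)
  readr::write_csv(make_line()[0, ], dp)
  co <- read_cohort(vp, dp)
  expect_equal(nrow(co$visits), 1)
  expect_equal(nrow(co$drug_lines), 0)
})

test_that("schema errors name the missing column", {
  v <- make_visit()
  v$sector <- NULL
  expect_error(validate_visits(v), "sector", class = "gpcost_schema_error")
  l <- make_line()
  l$tier <- NULL
  expect_error(validate_drug_lines(l), "tier", class = "gpcost_schema_error")
})

test_that("validation rejects exactly the rows violating an invariant", {
  visits <- dplyr::bind_rows(
    make_visit("V1"),
    make_visit("V2", has_dld = TRUE),
    make_visit("V3", sick_leave = TRUE, sick_leave_days = 4)
  )
  lines <- dplyr::bind_rows(
    make_line("V1", tier = 0.65),
    make_line("V2", tier = 0, dld_related = TRUE),
    make_line("V3", tier = 0.35)
  )
  expect_silent({
    validate_visits(visits)
    validate_drug_lines(lines, visits = visits)
  })

  # each single-field mutation is rejected with the right row reference
  mutations <- list(
    list(fun = function(l) { l$tier[3] <- 0.50; l }, msg = "row 3"),
    list(fun = function(l) { l$unit_price[1] <- -2; l }, msg = "row 1"),
    list(fun = function(l) { l$n_boxes[2] <- 0L; l }, msg = "row 2"),
    list(fun = function(l) { l$dld_related[1] <- TRUE; l }, msg = "row 1")
  )
  for (m in mutations) {
    expect_error(validate_drug_lines(m$fun(lines), visits = visits),
                 m$msg, class = "gpcost_validation_error")
  }

  bad_days <- visits
  bad_days$sick_leave_days[1] <- 3L  # flag not set on row 1
  expect_error(validate_visits(bad_days), "row 1",
               class = "gpcost_validation_error")
  bad_age <- visits
  bad_age$age[2] <- -1
  expect_error(validate_visits(bad_age), "row 2",
               class = "gpcost_validation_error")
  dup <- dplyr::bind_rows(make_visit("V1"), make_visit("V1"))
  expect_error(validate_visits(dup), "duplicated",
               class = "gpcost_validation_error")
  orphan <- make_line("V9")
  expect_error(validate_drug_lines(orphan, visits = visits), "V9",
               class = "gpcost_validation_error")
})

test_that("breakdown CSV cells carry exact two-decimal money", {
  b <- make_random_breakdowns(1, seed = 1)
  b$consultation_total <- 22
  path <- withr::local_tempfile(fileext = ".csv")
  write_breakdowns(b, path)
  raw <- readLines(path)
  expect_match(raw[2], "22\\.00")

  empty <- b[0, ]
  write_breakdowns(empty, path)
  expect_length(readLines(path), 1)  # header only
  back <- read_breakdowns(path)
  expect_equal(nrow(back), 0)
})

test_that("breakdown write -> read round-trips cent-for-cent on random tables", {
  b <- make_random_breakdowns(100, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_breakdowns(b, path)
  back <- read_breakdowns(path)
  expect_equal(back$visit_id, b$visit_id)
  expect_equal(back$consultation_costed, b$consultation_costed)
  for (col in c("consultation_ss", "consultation_remaining",
                "consultation_total", "prescription_ss",
                "prescription_remaining", "prescription_total",
                "total_ss", "total_remaining", "health_expenditure")) {
    expect_equal(cents(back[[col]]), cents(b[[col]]), info = col)
  }
})

test_that("visits and drug lines survive a write -> read cycle unchanged", {
  co <- make_random_cohort(60, seed = 11)
  vp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(co$visits, vp)
  readr::write_csv(co$drug_lines, dp)
  back <- read_cohort(vp, dp)
  expect_equal(as.data.frame(back$visits), as.data.frame(co$visits))
  expect_equal(as.data.frame(back$drug_lines), as.data.frame(co$drug_lines))
})

test_that("extra descriptive columns pass through untouched", {
  v <- make_visit()
  v$gender <- "F"
  v$sf12_physical <- 47.2
  out <- validate_visits(v)
  expect_equal(out$gender, "F")
  expect_equal(out$sf12_physical, 47.2)
})
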