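# Seeded synthetic-cohort generator emulating the marginal structure of the
# EPI3 cross-sectional survey of French general practice: three practice
# groups (conventional CM, mixed Mx, homeopathic Ho), per-group sector
# mixes, DLD prevalence, prescription-size distributions by reimbursement
# tier, and non-medicinal prescription rates. Joint correlations the survey
# never reported are not emulated: all patient-level attributes are drawn
# independently.

#' Configuration of the synthetic cohort
#'
#' All marginal parameters of the generator, with defaults set to the EPI3
#' economic-study margins: group sizes 1691 (CM) / 3187 (Mx) / 1501 (Ho),
#' sector-2 shares 6.9% / 4.9% / 49.3%, "Not under agreement" shares
#' 0% / 0.5% / 2%, DLD prevalence 29.5% (CM) and 18.7% (Ho), mean
#' prescription sizes by reimbursement tier, and the published
#' non-medicinal prescription rates.
#'
#' Per-group drug-line counts are generated as independent per-tier counts
#' (negative binomial matched to the configured per-tier mean and SD, or
#' Poisson when the SD implies under-dispersion); the prescription total is
#' their sum. The headline total-drug moments (`drugs_per_rx_mean_sd`) are
#' retained for reporting but are not a generator constraint: the per-tier
#' margins determine the totals.
#'
#' @param group_sizes Named integer vector, patients per practice group.
#' @param sector2_share,nua_share Named per-group probabilities of a
#'   sector-2 / not-under-agreement GP; the remainder is sector 1.
#' @param dld_prevalence Named per-group probability of long-duration
#'   disease (DLD/ALD) status. The Mx value was not published; the default
#'   is an intermediate 0.25.
#' @param adult_share Probability a patient is an adult (age over 18).
#' @param supplementary_share Named per-group probability of supplementary
#'   health insurance.
#' @param tier_line_means,tier_line_sds Per-group mean/SD counts of drug
#'   lines at the 0%, 35% and 65% reimbursement tiers (3x3 matrices,
#'   rows \code{c("0", "0.35", "0.65")}, columns groups).
#' @param drugs_per_rx_mean_sd Headline (mean, SD) of drugs per
#'   prescription, per group; reporting only.
#' @param price_median,price_sdlog Log-normal unit-price model (EUR); the
#'   survey published no price distribution, so the median and spread are
#'   free parameters that the costing rules never depend on.
#' @param boxes_extra_mean Boxes per line are 1 + Poisson(this mean).
#' @param dld_line_share Probability that a line of a DLD patient is
#'   related to the long-duration disease (and hence covered at 100%).
#' @param homeo_line_prob Named per-group probability that a line is
#'   homeopathic (descriptive only; drives the homeopathic-only /
#'   conventional-only / mixed prescription shares).
#' @param nonmedicinal_rates Matrix of per-group rates for the eight
#'   non-medicinal prescription flags (rows = flags, columns = groups).
#' @param sick_leave_days_mean Named per-group mean sick-leave duration in
#'   days (drawn Poisson, truncated at 1, only when sick leave is
#'   prescribed).
#' @param drug_class_probs Matrix of per-group probabilities over
#'   therapeutic-class tags (rows = classes, columns = groups);
#'   descriptive only.
#' @param seed Integer seed making the generator deterministic.
#' @return A validated object of class \code{cohort_config}.
#' @export
cohort_config <- function(
    group_sizes = c(CM = 1691, Mx = 3187, Ho = 1501),
    sector2_share = c(CM = 0.069, Mx = 0.049, Ho = 0.493),
    nua_share = c(CM = 0, Mx = 0.005, Ho = 0.02),
    dld_prevalence = c(CM = 0.295, Mx = 0.25, Ho = 0.187),
    adult_share = 0.85,
    supplementary_share = c(CM = 0.94, Mx = 0.95, Ho = 0.96),
    tier_line_means = matrix(
      c(0.2, 0.7, 2.2,   0.2, 0.8, 1.9,   0.3, 2.0, 1.1),
      nrow = 3, dimnames = list(c("0", "0.35", "0.65"), c("CM", "Mx", "Ho"))
    ),
    tier_line_sds = matrix(
      c(0.4, 0.9, 1.9,   0.5, 1.1, 1.6,   0.6, 1.9, 1.5),
      nrow = 3, dimnames = list(c("0", "0.35", "0.65"), c("CM", "Mx", "Ho"))
    ),
    drugs_per_rx_mean_sd = matrix(
      c(3.1, 2.1,  2.8, 1.9,  3.5, 2.2),
      nrow = 2, dimnames = list(c("mean", "sd"), c("CM", "Mx", "Ho"))
    ),
    price_median = 5,
    price_sdlog = 0.8,
    boxes_extra_mean = 0.4,
    dld_line_share = 0.5,
    homeo_line_prob = c(CM = 0.01, Mx = 0.08, Ho = 0.45),
    nonmedicinal_rates = matrix(
      c(0.112, 0.066, 0.010, 0.010, 0.157, 0.009, 0.062, 0.124,
        0.108, 0.059, 0.009, 0.009, 0.125, 0.009, 0.058, 0.100,
        0.079, 0.056, 0.005, 0.006, 0.139, 0.005, 0.076, 0.095),
      nrow = 8,
      dimnames = list(
        c("sick_leave", "radiology", "ct_scan", "mri", "lab_test",
          "nursing", "physiotherapy", "specialist_referral"),
        c("CM", "Mx", "Ho")
      )
    ),
    sick_leave_days_mean = c(CM = 11, Mx = 13, Ho = 12),
    drug_class_probs = matrix(
      c(0.10, 0.08, 0.03, 0.04, 0.04, 0.02, 0.04, 0.65,
        0.09, 0.07, 0.03, 0.04, 0.03, 0.02, 0.03, 0.69,
        0.05, 0.04, 0.015, 0.02, 0.02, 0.01, 0.02, 0.825),
      nrow = 8,
      dimnames = list(
        c("N02", "M01", "R01", "J01", "N05B", "N05C", "N06A", "OTHER"),
        c("CM", "Mx", "Ho")
      )
    ),
    seed = 42) {
  config <- list(
    group_sizes = group_sizes,
    sector2_share = sector2_share,
    nua_share = nua_share,
    dld_prevalence = dld_prevalence,
    adult_share = adult_share,
    supplementary_share = supplementary_share,
    tier_line_means = tier_line_means,
    tier_line_sds = tier_line_sds,
    drugs_per_rx_mean_sd = drugs_per_rx_mean_sd,
    price_median = price_median,
    price_sdlog = price_sdlog,
    boxes_extra_mean = boxes_extra_mean,
    dld_line_share = dld_line_share,
    homeo_line_prob = homeo_line_prob,
    nonmedicinal_rates = nonmedicinal_rates,
    sick_leave_days_mean = sick_leave_days_mean,
    drug_class_probs = drug_class_probs,
    seed = as.integer(seed)
  )
  class(config) <- "cohort_config"
  validate_cohort_config(config)
}

#' @noRd
validate_cohort_config <- function(config) {
  g <- PRACTICE_GROUPS
  if (!all(g %in% names(config$group_sizes))) {
    abort_validation("group_sizes must name all of CM, Mx, Ho")
  }
  if (any(config$group_sizes < 0)) {
    abort_validation("group_sizes must be non-negative")
  }
  fracs <- list(
    sector2_share = config$sector2_share,
    nua_share = config$nua_share,
    dld_prevalence = config$dld_prevalence,
    supplementary_share = config$supplementary_share,
    homeo_line_prob = config$homeo_line_prob,
    adult_share = config$adult_share,
    dld_line_share = config$dld_line_share
  )
  for (nm in names(fracs)) {
    v <- fracs[[nm]]
    if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
      abort_validation(sprintf("'%s' must lie in [0, 1]", nm))
    }
  }
  if (any(config$sector2_share[g] + config$nua_share[g] > 1)) {
    abort_validation("sector2_share + nua_share must not exceed 1 in any group")
  }
  if (any(config$tier_line_means < 0) || any(config$tier_line_sds < 0)) {
    abort_validation("tier line means and sds must be non-negative")
  }
  if (any(abs(colSums(config$drug_class_probs) - 1) > 1e-6)) {
    abort_validation("drug_class_probs columns must each sum to 1")
  }
  config
}

# Per-tier line counts: negative binomial matched to (mean, sd) by moments;
# when sd^2 <= mean the NB is undefined and we fall back to Poisson with a
# notice (message, not warning: this is expected for narrow tiers).
#' @noRd
draw_tier_counts <- function(n, mean, sd, tier_label, group) {
  if (n == 0) return(integer(0))
  if (mean <= 0) return(integer(n))
  if (sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else {
    message(sprintf(
      "cohort generator: tier %s counts in group %s use Poisson (configured sd^2 <= mean)",
      tier_label, group
    ))
    stats::rpois(n, mean)
  }
}

#' Generate a synthetic cohort
#'
#' Draws a visits table and a drug-lines table with the marginal structure
#' of the configuration. Deterministic for a fixed seed. Realized group
#' sizes equal the configuration exactly; all other attributes are
#' independent draws at the configured rates. \code{dld_related} lines are
#' drawn only for patients with DLD status.
#'
#' @param config A [cohort_config()].
#' @param seed Optional override of \code{config$seed}.
#' @return A list with validated \code{visits} and \code{drug_lines}
#'   tibbles.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(if (is.null(seed)) config$seed else as.integer(seed),
           kind = "Mersenne-Twister")

  visits_list <- list()
  lines_list <- list()
  offset <- 0
  for (g in PRACTICE_GROUPS) {
    n <- as.integer(config$group_sizes[[g]])
    if (n == 0) next
    visit_id <- sprintf("V%06d", offset + seq_len(n))
    offset <- offset + n

    p2 <- config$sector2_share[[g]]
    pn <- config$nua_share[[g]]
    u <- stats::runif(n)
    sector <- ifelse(u < p2, "S2", ifelse(u < p2 + pn, "NUA", "S1"))

    has_dld <- stats::runif(n) < config$dld_prevalence[[g]]
    adult <- stats::runif(n) < config$adult_share
    # two-point age mixture: the costing rules only use the >18 threshold
    age <- ifelse(adult,
                  sample(19:90, n, replace = TRUE),
                  sample(0:18, n, replace = TRUE))
    has_supp <- stats::runif(n) < config$supplementary_share[[g]]

    flags <- matrix(FALSE, n, length(NONMEDICINAL_FLAGS),
                    dimnames = list(NULL, NONMEDICINAL_FLAGS))
    for (f in NONMEDICINAL_FLAGS) {
      flags[, f] <- stats::runif(n) < config$nonmedicinal_rates[f, g]
    }
    sick_leave_days <- integer(n)
    n_sick <- sum(flags[, "sick_leave"])
    if (n_sick > 0) {
      sick_leave_days[flags[, "sick_leave"]] <-
        pmax(1L, stats::rpois(n_sick, config$sick_leave_days_mean[[g]]))
    }

    visits_list[[g]] <- tibble::tibble(
      visit_id = visit_id,
      practice_group = g,
      sector = sector,
      age = as.numeric(age),
      has_dld = has_dld,
      has_supplementary_insurance = has_supp,
      sick_leave = flags[, "sick_leave"],
      sick_leave_days = sick_leave_days,
      radiology = flags[, "radiology"],
      ct_scan = flags[, "ct_scan"],
      mri = flags[, "mri"],
      lab_test = flags[, "lab_test"],
      nursing = flags[, "nursing"],
      physiotherapy = flags[, "physiotherapy"],
      specialist_referral = flags[, "specialist_referral"]
    )

    # per-tier line counts, then expand to one row per line
    tiers <- c(0, 0.35, 0.65)
    tier_rows <- rownames(config$tier_line_means)
    counts <- sapply(seq_along(tiers), function(k) {
      draw_tier_counts(n, config$tier_line_means[tier_rows[k], g],
                       config$tier_line_sds[tier_rows[k], g],
                       tier_rows[k], g)
    })
    counts <- matrix(as.integer(counts), nrow = n)
    line_visit <- character(0)
    line_tier <- numeric(0)
    line_dld <- logical(0)
    for (k in seq_along(tiers)) {
      ck <- counts[, k]
      if (sum(ck) == 0) next
      vidx <- rep(seq_len(n), ck)
      line_visit <- c(line_visit, visit_id[vidx])
      line_tier <- c(line_tier, rep(tiers[k], sum(ck)))
      line_dld <- c(line_dld, has_dld[vidx])
    }
    m <- length(line_visit)
    if (m > 0) {
      unit_price <- round(stats::rlnorm(m, meanlog = log(config$price_median),
                                        sdlog = config$price_sdlog), 2)
      unit_price <- pmax(unit_price, 0.01)
      n_boxes <- 1L + stats::rpois(m, config$boxes_extra_mean)
      dld_related <- line_dld & stats::runif(m) < config$dld_line_share
      is_homeo <- stats::runif(m) < config$homeo_line_prob[[g]]
      drug_class <- sample(rownames(config$drug_class_probs), m,
                           replace = TRUE, prob = config$drug_class_probs[, g])
      lines_list[[g]] <- tibble::tibble(
        visit_id = line_visit,
        unit_price = unit_price,
        n_boxes = n_boxes,
        tier = line_tier,
        dld_related = dld_related,
        is_homeopathic = is_homeo,
        drug_class = drug_class
      )
    }
  }

  empty_visits <- tibble::tibble(
    visit_id = character(0), practice_group = character(0),
    sector = character(0), age = numeric(0), has_dld = logical(0),
    has_supplementary_insurance = logical(0), sick_leave = logical(0),
    sick_leave_days = integer(0), radiology = logical(0),
    ct_scan = logical(0), mri = logical(0), lab_test = logical(0),
    nursing = logical(0), physiotherapy = logical(0),
    specialist_referral = logical(0)
  )
  empty_lines <- tibble::tibble(
    visit_id = character(0), unit_price = numeric(0), n_boxes = integer(0),
    tier = numeric(0), dld_related = logical(0), is_homeopathic = logical(0),
    drug_class = character(0)
  )
  visits <- if (length(visits_list)) dplyr::bind_rows(visits_list) else empty_visits
  drug_lines <- if (length(lines_list)) dplyr::bind_rows(lines_list) else empty_lines
  # order drug lines by visit to keep the CSV layout tidy and deterministic
  drug_lines <- drug_lines[order(match(drug_lines$visit_id, visits$visit_id)), ]
  list(
    visits = validate_visits(visits),
    drug_lines = validate_drug_lines(drug_lines, visits = visits)
  )
}

#' Fidelity report of a generated cohort against its configuration
#'
#' For each configured marginal (per group): the realized value, the
#' configured target, the standard error of the realized value at the
#' realized group size, and the z-score (realized minus target over SE).
#' Marginals with |z| > 4 are flagged. The target for the total
#' drugs-per-prescription mean is the sum of the configured per-tier means,
#' i.e. what the generator is constructed to achieve.
#'
#' @param visits,drug_lines A generated (or observed) cohort.
#' @param config The [cohort_config()] the cohort is compared against.
#' @return A tibble with columns \code{group, metric, target, realized,
#'   se, z, flagged}; empty for an empty cohort.
#' @export
validate_fidelity <- function(visits, drug_lines, config = cohort_config()) {
  if (nrow(visits) == 0) {
    return(tibble::tibble(
      group = character(0), metric = character(0), target = numeric(0),
      realized = numeric(0), se = numeric(0), z = numeric(0),
      flagged = logical(0)
    ))
  }
  rows <- list()
  add <- function(group, metric, target, realized, se) {
    z <- if (is.na(se) || se == 0) NA_real_ else (realized - target) / se
    rows[[length(rows) + 1]] <<- tibble::tibble(
      group = group, metric = metric, target = target,
      realized = realized, se = se, z = z,
      flagged = !is.na(z) & abs(z) > 4
    )
  }
  prop_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)

  for (g in intersect(PRACTICE_GROUPS, unique(visits$practice_group))) {
    vg <- visits[visits$practice_group == g, ]
    n <- nrow(vg)
    add(g, "sector2_share", config$sector2_share[[g]],
        mean(vg$sector == "S2"), prop_se(config$sector2_share[[g]], n))
    add(g, "nua_share", config$nua_share[[g]],
        mean(vg$sector == "NUA"), prop_se(config$nua_share[[g]], n))
    add(g, "dld_prevalence", config$dld_prevalence[[g]],
        mean(vg$has_dld), prop_se(config$dld_prevalence[[g]], n))
    add(g, "adult_share", config$adult_share,
        mean(vg$age > 18), prop_se(config$adult_share, n))
    add(g, "supplementary_share", config$supplementary_share[[g]],
        mean(vg$has_supplementary_insurance),
        prop_se(config$supplementary_share[[g]], n))
    for (f in NONMEDICINAL_FLAGS) {
      add(g, paste0("rate_", f), config$nonmedicinal_rates[f, g],
          mean(vg[[f]]), prop_se(config$nonmedicinal_rates[f, g], n))
    }
    lg <- drug_lines[drug_lines$visit_id %in% vg$visit_id, ]
    n_lines <- as.numeric(table(factor(lg$visit_id, levels = vg$visit_id)))
    tiers <- c("0" = 0, "0.35" = 0.35, "0.65" = 0.65)
    for (k in names(tiers)) {
      ck <- as.numeric(table(factor(lg$visit_id[abs(lg$tier - tiers[[k]]) < 1e-9],
                                    levels = vg$visit_id)))
      add(g, paste0("lines_tier_", k), config$tier_line_means[k, g],
          mean(ck), stats::sd(ck) / sqrt(n))
    }
    add(g, "drugs_per_rx", sum(config$tier_line_means[, g]),
        mean(n_lines), stats::sd(n_lines) / sqrt(n))
    if (any(vg$sick_leave)) {
      d <- vg$sick_leave_days[vg$sick_leave]
      add(g, "sick_leave_days_mean", config$sick_leave_days_mean[[g]],
          mean(d), stats::sd(d) / sqrt(length(d)))
    }
  }
  dplyr::bind_rows(rows)
}
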