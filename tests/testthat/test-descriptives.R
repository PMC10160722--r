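test_that("percentage shares reproduce printed-table arithmetic", {
  expect_equal(pct_share(0.82, 3.67), 22.3)
  expect_equal(pct_share(22.69, 28.00), 81.0)
  expect_equal(pct_share(5, 5), 100.0)
  # half-up at the boundary: 91.2509... rounds up
  expect_equal(pct_share(162.72, 178.32), 91.3)
  expect_error(pct_share(1, 0), class = "tdabcost_undefined_share")
})

test_that("facility IQR interpolates linearly and is permutation invariant", {
  expect_equal(facility_iqr(c(1, 2, 3, 4)), c(q25 = 1.75, q75 = 3.25))
  expect_equal(facility_iqr(c(7, 7, 7)), c(q25 = 7, q75 = 7))
  expect_equal(facility_iqr(c(4, 2, 1, 3)), facility_iqr(c(1, 2, 3, 4)))
  expect_equal(facility_iqr(5), c(q25 = 5, q75 = 5))
  expect_error(facility_iqr(numeric(0)), class = "tdabcost_invalid_input")
  # monotonicity: appending a value above q75 cannot lower q75
  set.seed(3)
  for (i in 1:20) {
    v <- runif(sample(3:12, 1), 0, 100)
    q <- facility_iqr(v)
    q2 <- facility_iqr(c(v, q[["q75"]] + runif(1, 0.1, 50)))
    expect_gte(q2[["q75"]], q[["q75"]] - 1e-12)
  }
})

make_costs <- function() {
  # 3 facilities x 4 encounters of HTC plus 2 ART_STABLE encounters with a
  # constant consumable cost (standardized bundle)
  set.seed(21)
  htc <- tibble::tibble(
    encounter_id = paste0("E", 1:12),
    patient_id = paste0("P", 1:12),
    facility_id = rep(c("F1", "F2", "F3"), each = 4),
    service = "HTC",
    human_resources_usd = runif(12, 0.5, 1.5),
    space_equipment_usd = runif(12, 0.05, 0.2),
    indirects_usd = runif(12, 0.1, 0.6),
    consumables_usd = runif(12, 1.5, 3)
  )
  art <- tibble::tibble(
    encounter_id = paste0("E", 13:18),
    patient_id = paste0("P", 13:18),
    facility_id = rep(c("F1", "F2", "F3"), each = 2),
    service = "ART_STABLE",
    human_resources_usd = runif(6, 0.5, 1),
    space_equipment_usd = runif(6, 0.05, 0.2),
    indirects_usd = runif(6, 0.1, 0.4),
    consumables_usd = 21.49
  )
  dplyr::bind_rows(htc, art) |>
    dplyr::mutate(
      total_per_visit_usd = human_resources_usd + space_equipment_usd +
        indirects_usd + consumables_usd,
      annualized_total_usd = annualize_service_cost(total_per_visit_usd, service),
      provider_minutes = 10
    )
}

test_that("service cost summaries match brute-force statistics", {
  costs <- make_costs()
  s <- summarize_service_costs(costs, annualize = FALSE)

  htc <- costs[costs$service == "HTC", ]
  row <- s[s$service == "HTC" & s$category == "HUMAN_RESOURCES", ]
  expect_equal(row$mean_usd, mean(htc$human_resources_usd))
  # two-pass sample SD oracle
  m <- mean(htc$human_resources_usd)
  expect_equal(
    row$sd_usd,
    sqrt(sum((htc$human_resources_usd - m)^2) / (nrow(htc) - 1))
  )
  # IQR computed over facility means
  fac_means <- tapply(htc$human_resources_usd, htc$facility_id, mean)
  expect_equal(
    c(q25 = row$q25_usd, q75 = row$q75_usd),
    facility_iqr(as.numeric(fac_means))
  )

  # unrounded shares close to within rounding slack, and recomputable
  tot <- s[s$service == "HTC" & s$category == "TOTAL", ]
  expect_equal(tot$pct_of_total, 100)
  shares <- s$pct_of_total[s$service == "HTC" & s$category != "TOTAL"]
  expect_lt(abs(sum(shares) - 100), 0.3)
  raw_share <- 100 * mean(htc$human_resources_usd) / mean(htc$total_per_visit_usd)
  expect_equal(row$pct_of_total, round_half_up(raw_share, 1))
})

test_that("share closure holds exactly before rounding", {
  costs <- make_costs()
  for (svc in unique(costs$service)) {
    rows <- costs[costs$service == svc, ]
    cat_means <- c(
      mean(rows$human_resources_usd), mean(rows$space_equipment_usd),
      mean(rows$indirects_usd), mean(rows$consumables_usd)
    )
    expect_equal(sum(100 * cat_means / mean(rows$total_per_visit_usd)), 100)
  }
})

test_that("constant consumables across facilities are flagged not applicable", {
  costs <- make_costs()
  s <- summarize_service_costs(costs, annualize = TRUE)
  art_cons <- s[s$service == "ART_STABLE" & s$category == "CONSUMABLES", ]
  expect_false(art_cons$iqr_applicable)
  expect_true(is.na(art_cons$q25_usd))
  # annualization multiplies ART means by 4
  art_mean_per_visit <- mean(costs$consumables_usd[costs$service == "ART_STABLE"])
  expect_equal(art_cons$mean_usd, 4 * art_mean_per_visit)
  # HTC consumables vary, IQR applies
  expect_true(s$iqr_applicable[s$service == "HTC" & s$category == "CONSUMABLES"])
})

test_that("a single facility gives a degenerate IQR at its own mean", {
  costs <- make_costs()
  one <- costs[costs$facility_id == "F1" & costs$service == "HTC", ]
  s <- summarize_service_costs(one, annualize = FALSE)
  row <- s[s$category == "TOTAL", ]
  expect_equal(row$q25_usd, mean(one$total_per_visit_usd))
  expect_equal(row$q75_usd, mean(one$total_per_visit_usd))
})

test_that("empty service lines are omitted with a warning", {
  costs <- make_costs()
  expect_warning(
    s <- summarize_service_costs(costs, services = c("HTC", "ART_STABLE", "VMMC")),
    class = "tdabcost_empty_service"
  )
  expect_false("VMMC" %in% s$service)
})

test_that("cohort summaries recount exactly and include a consistent total row", {
  set.seed(5)
  n <- 120
  patients <- tibble::tibble(
    patient_id = paste0("P", 1:n),
    service = sample(c("HTC", "PMTCT", "VMMC"), n,
      replace = TRUE,
      prob = c(0.5, 0.3, 0.2)
    ),
    gender = sample(c("FEMALE", "MALE"), n, replace = TRUE),
    age = sample(18:80, n, replace = TRUE),
    married = runif(n) < 0.5,
    education_years = sample(0:8, n, replace = TRUE),
    comorbidity = runif(n) < 0.15
  )
  patients$gender[patients$service == "PMTCT"] <- "FEMALE"
  patients$gender[patients$service == "VMMC"] <- "MALE"

  s <- summarize_cohort(patients)
  total <- s[s$service == "TOTAL", ]
  per <- s[s$service != "TOTAL", ]
  expect_equal(sum(per$n), total$n)
  expect_equal(sum(per$n_female), total$n_female)
  expect_equal(sum(per$n_married), total$n_married)
  expect_equal(sum(per$n_comorbid), total$n_comorbid)

  # brute-force recount of one service line
  htc <- patients[patients$service == "HTC", ]
  row <- s[s$service == "HTC", ]
  expect_equal(row$n, nrow(htc))
  expect_equal(row$n_female, sum(htc$gender == "FEMALE"))
  expect_equal(row$pct_female, round_half_up(100 * sum(htc$gender == "FEMALE") / nrow(htc), 0))
  expect_equal(row$age_mean, round_half_up(mean(htc$age), 1))

  # gender eligibility shows up as 100% / 0% female
  expect_equal(s$pct_female[s$service == "PMTCT"], 100)
  expect_equal(s$pct_female[s$service == "VMMC"], 0)

  # empty input gives the all-zero summary
  empty <- summarize_cohort(patients[0, ])
  expect_equal(empty$n, 0L)
  expect_equal(empty$n_female, 0L)
})

test_that("half-up rounding behaves at representative boundaries", {
  expect_equal(round_half_up(91.25, 1), 91.3)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(2.5), 3)
})
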