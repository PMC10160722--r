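test_that("equipment annualization follows linear depreciation", {
  expect_equal(annualize_equipment(1000, 5), 200)
  expect_equal(annualize_equipment(0, 10), 0)
  expect_equal(annualize_equipment(787.5, 7), 112.5)
  expect_error(annualize_equipment(100, 0), class = "tdabcost_invalid_parameter")
  expect_error(annualize_equipment(100, -2), class = "tdabcost_invalid_parameter")
  expect_error(annualize_equipment(-5, 3), class = "tdabcost_invalid_parameter")
})

test_that("capacity cost rates divide annual cost by practical capacity", {
  expect_equal(capacity_cost_rate(120000, 100000), 1.2)
  expect_equal(capacity_cost_rate(0, 50000), 0)
  # elementwise over a small registry of cadres, against hand division
  annual <- c(13800000, 20700000, 9200000)
  capacity <- c(100000, 115000, 80000)
  expect_equal(
    capacity_cost_rate(annual, capacity),
    c(138, 180, 115)
  )
  expect_error(capacity_cost_rate(100, 0), class = "tdabcost_invalid_parameter")
  expect_error(capacity_cost_rate(100, -1), class = "tdabcost_invalid_parameter")
})

test_that("currency conversion uses the stated rate and applies once", {
  expect_equal(convert_tzs_to_usd(2300), 1)
  expect_equal(convert_tzs_to_usd(0), 0)
  expect_equal(convert_tzs_to_usd(1150), 0.5)
  expect_equal(convert_tzs_to_usd(2300, rate = 1000), 2.3)
  expect_error(convert_tzs_to_usd(100, rate = 0), class = "tdabcost_invalid_parameter")
})

test_that("service annualization multiplies by visit frequency", {
  expect_equal(annualize_service_cost(3.67, "HTC"), 3.67)
  expect_equal(annualize_service_cost(10, "ART_STABLE"), 40)
  expect_equal(annualize_service_cost(10, "ART_UNSTABLE"), 120)
  expect_identical(visits_per_year(service_lines()), c(4L, 12L, 1L, 1L, 1L, 1L))
  expect_error(visits_per_year("ART"), class = "tdabcost_invalid_input")
})

test_that("indirect allocation is proportional, prorated and conserving", {
  expect_equal(
    unname(allocate_indirects(0, c(a = 10, b = 20))), c(0, 0)
  )
  expect_equal(
    allocate_indirects(100, c(a = 30, b = 10)), c(a = 75, b = 25)
  )
  # brute-force proportional split oracle on random pools/minutes
  set.seed(42)
  for (i in 1:25) {
    k <- sample(1:8, 1)
    m <- runif(k, 0.1, 120)
    names(m) <- paste0("e", seq_len(k))
    pool <- runif(1, 0, 5e6)
    days <- sample(c(45, 90, 365), 1)
    got <- allocate_indirects(pool, m, period_days = days)
    want <- (pool * days / 365) * m / sum(m)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(got), pool * days / 365, tolerance = 1e-9)
  }
  # equal-share basis
  expect_equal(
    unname(allocate_indirects(90, c(a = 5, b = 100), basis = "equal_share")),
    c(45, 45)
  )
  expect_error(
    allocate_indirects(100, c(a = 0, b = 0)),
    class = "tdabcost_degenerate_basis"
  )
  expect_error(
    allocate_indirects(100, setNames(numeric(0), character(0))),
    class = "tdabcost_invalid_input"
  )
})

test_that("a two-step worked encounter costs out by hand", {
  w <- worked_example()
  got <- cost_encounters(w$observations, w$resources, w$prices)
  expect_equal(got$human_resources_usd, 10 * 0.05 + 15 * 0.04) # 1.10
  expect_equal(got$space_equipment_usd, 25 * 0.004) # 0.10
  expect_equal(got$consumables_usd, 1.20)
  expect_equal(got$indirects_usd, 0)
  expect_equal(got$total_per_visit_usd, 2.40)
  expect_equal(got$provider_minutes, 25)
  expect_equal(got$annualized_total_usd, 2.40) # HTC is one-time
})

test_that("an encounter with no observations costs zero in every category", {
  w <- worked_example()
  roster <- tibble::tibble(
    encounter_id = c("E1", "E2"), patient_id = c("P1", "P2"),
    facility_id = "F01", service = "HTC"
  )
  got <- cost_encounters(w$observations, w$resources, w$prices,
    encounters = roster
  )
  empty <- got[got$encounter_id == "E2", ]
  expect_equal(empty$total_per_visit_usd, 0)
  expect_equal(empty$human_resources_usd, 0)
  expect_equal(empty$consumables_usd, 0)
  expect_equal(empty$provider_minutes, 0)
})

test_that("unknown identifiers and negative inputs are rejected by name", {
  w <- worked_example()
  bad <- w$observations
  bad$resource_id[1] <- "ghost_cadre"
  err <- expect_error(
    cost_encounters(bad, w$resources, w$prices),
    class = "tdabcost_missing_reference"
  )
  expect_match(conditionMessage(err), "ghost_cadre")
  bad2 <- w$observations
  bad2$item_id[5] <- "ghost_item"
  err2 <- expect_error(
    cost_encounters(bad2, w$resources, w$prices),
    class = "tdabcost_missing_reference"
  )
  expect_match(conditionMessage(err2), "ghost_item")
  bad3 <- w$observations
  bad3$quantity[5] <- -1
  expect_error(
    cost_encounters(bad3, w$resources, w$prices),
    class = "tdabcost_invalid_input"
  )
  bad4 <- w$observations
  bad4$observed_minutes[1] <- -3
  expect_error(
    cost_encounters(bad4, w$resources, w$prices),
    class = "tdabcost_invalid_input"
  )
})

test_that("cost_encounters agrees with the brute-force hand-sum oracle", {
  fix <- random_encounter_set(200, seed = 7)
  got <- cost_encounters(fix$observations, fix$resources, fix$prices)
  for (e in got$encounter_id) {
    rows <- fix$observations[fix$observations$encounter_id == e, ]
    want <- oracle_cost_one(rows, fix$resources, fix$prices)
    row <- got[got$encounter_id == e, ]
    expect_equal(row$human_resources_usd, unname(want["hr"]), tolerance = 1e-12)
    expect_equal(row$space_equipment_usd, unname(want["space"]), tolerance = 1e-12)
    expect_equal(row$consumables_usd, unname(want["cons"]), tolerance = 1e-12)
    expect_equal(row$provider_minutes, unname(want["staff_min"]), tolerance = 1e-12)
  }
})

test_that("costing invariants: additivity, conservation, scaling, currency, annualization", {
  fix <- random_encounter_set(60, seed = 13)
  pools <- tibble::tibble(facility_id = "F01", annual_indirect_cost_tzs = 3.65e6)
  got <- cost_encounters(fix$observations, fix$resources, fix$prices,
    indirect_pools = pools, period_days = 45
  )

  # additivity
  expect_equal(
    got$total_per_visit_usd,
    got$human_resources_usd + got$space_equipment_usd + got$indirects_usd +
      got$consumables_usd,
    tolerance = 1e-9
  )
  # conservation of the prorated pool
  expect_equal(
    sum(got$indirects_usd) * 2300,
    3.65e6 * 45 / 365,
    tolerance = 1e-9
  )
  # annualized/total ratio is exactly the visit frequency
  expect_equal(
    got$annualized_total_usd / got$total_per_visit_usd,
    as.numeric(visits_per_year(got$service))
  )

  # doubling minutes doubles time-driven categories, leaves consumables alone
  doubled <- fix$observations
  doubled$observed_minutes <- doubled$observed_minutes * 2
  got2 <- cost_encounters(doubled, fix$resources, fix$prices)
  base <- cost_encounters(fix$observations, fix$resources, fix$prices)
  expect_equal(got2$human_resources_usd, 2 * base$human_resources_usd)
  expect_equal(got2$space_equipment_usd, 2 * base$space_equipment_usd)
  expect_equal(got2$consumables_usd, base$consumables_usd)

  # currency homogeneity: costing in TZS then converting equals costing
  # pre-converted inputs at rate 1
  conv <- fix$resources
  conv$annual_cost_tzs <- conv$annual_cost_tzs / 2300
  pconv <- fix$prices
  pconv$unit_price_tzs <- pconv$unit_price_tzs / 2300
  got3 <- cost_encounters(fix$observations, conv, pconv, usd_rate = 1)
  expect_equal(got3$total_per_visit_usd, base$total_per_visit_usd, tolerance = 1e-9)
})
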