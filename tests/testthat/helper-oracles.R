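# Independent oracles and fixture builders. These deliberately avoid the
# package's own costing/PCA code paths: plain loops and base linear algebra
# only, so agreement is a genuine cross-check.

# brute-force hand-sum of one encounter's cost from raw observation rows,
# in USD; returns the four categories plus staff minutes
oracle_cost_one <- function(obs_rows, resources, prices, usd_rate = 2300) {
  hr <- 0
  space <- 0
  cons <- 0
  staff_min <- 0
  for (i in seq_len(nrow(obs_rows))) {
    row <- obs_rows[i, ]
    if (!is.na(row$resource_id)) {
      j <- which(resources$resource_id == row$resource_id)
      rate <- resources$annual_cost_tzs[j] / resources$practical_capacity_min[j]
      amt <- rate * row$observed_minutes
      if (resources$category[j] == "HUMAN_RESOURCES") {
        hr <- hr + amt
        staff_min <- staff_min + row$observed_minutes
      } else {
        space <- space + amt
      }
    }
    if (!is.na(row$item_id)) {
      j <- which(prices$item_id == row$item_id)
      cons <- cons + prices$unit_price_tzs[j] * row$quantity
    }
  }
  c(
    hr = hr / usd_rate, space = space / usd_rate,
    cons = cons / usd_rate, staff_min = staff_min
  )
}

# first-principal-component scores by direct covariance eigendecomposition
# of the standardized matrix (constant columns removed), oriented like the
# implementation (positive correlation with the raw row sums)
oracle_pc_scores <- function(x) {
  x <- as.matrix(x)
  keep <- apply(x, 2, sd) > 0
  z <- scale(x[, keep, drop = FALSE])
  ev <- eigen(cov(z), symmetric = TRUE)
  s <- as.numeric(z %*% ev$vectors[, 1])
  if (cor(s, rowSums(x)) < 0) s <- -s
  s
}

# random small encounter set for property tests: n encounters with up to
# max_steps steps each, random rates, prices and minutes
random_encounter_set <- function(n, seed, max_steps = 5) {
  set.seed(seed)
  resources <- tibble::tibble(
    resource_id = paste0("R", 1:6),
    category = c(rep("HUMAN_RESOURCES", 4), rep("SPACE_EQUIPMENT", 2)),
    annual_cost_tzs = round(runif(6, 1e5, 2e7)),
    practical_capacity_min = round(runif(6, 5e4, 2e5))
  )
  prices <- tibble::tibble(
    item_id = paste0("I", 1:4),
    unit_price_tzs = round(runif(4, 100, 50000))
  )
  obs <- purrr::map_dfr(seq_len(n), function(e) {
    k <- sample.int(max_steps, 1)
    res_part <- tibble::tibble(
      encounter_id = paste0("E", e),
      patient_id = paste0("P", e),
      facility_id = "F01",
      service = sample(service_lines(), 1),
      step_id = paste0("S", seq_len(k)),
      resource_id = sample(resources$resource_id, k, replace = TRUE),
      observed_minutes = round(runif(k, 0, 60), 1),
      item_id = NA_character_,
      quantity = NA_real_
    )
    m <- sample.int(3, 1) - 1L
    item_part <- if (m > 0) {
      tibble::tibble(
        encounter_id = paste0("E", e),
        patient_id = paste0("P", e),
        facility_id = "F01",
        service = res_part$service[1],
        step_id = "S1",
        resource_id = NA_character_,
        observed_minutes = NA_real_,
        item_id = sample(prices$item_id, m, replace = TRUE),
        quantity = sample(1:5, m, replace = TRUE)
      )
    } else {
      NULL
    }
    dplyr::bind_rows(res_part, item_part)
  })
  list(observations = obs, resources = resources, prices = prices)
}

# small deterministic two-step worked encounter used in several tests:
# nurse 10 min @ 0.05 USD/min, counselor 15 min @ 0.04, room 25 min @
# 0.004, one test kit @ 1.20 USD (all entered in TZS at 2300/USD)
worked_example <- function() {
  list(
    observations = tibble::tibble(
      encounter_id = "E1", patient_id = "P1", facility_id = "F01",
      service = "HTC",
      step_id = c("S1", "S2", "S1", "S2", "S2"),
      resource_id = c("nurse", "counselor", "room", "room", NA),
      observed_minutes = c(10, 15, 10, 15, NA),
      item_id = c(NA, NA, NA, NA, "kit"),
      quantity = c(NA, NA, NA, NA, 1)
    ),
    resources = tibble::tibble(
      resource_id = c("nurse", "counselor", "room"),
      category = c("HUMAN_RESOURCES", "HUMAN_RESOURCES", "SPACE_EQUIPMENT"),
      annual_cost_tzs = c(0.05, 0.04, 0.004) * 2300 * 100000,
      practical_capacity_min = c(100000, 100000, 100000)
    ),
    prices = tibble::tibble(item_id = "kit", unit_price_tzs = 1.20 * 2300)
  )
}

# small simulated study config for structural pipeline tests (fast)
small_config <- function(seed = 11) {
  sim_config(
    seed = seed,
    sample_sizes = c(
      ART_STABLE = 40L, ART_UNSTABLE = 35L, HTC = 30L,
      PMTCT = 30L, PREP = 6L, VMMC = 8L
    )
  )
}
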