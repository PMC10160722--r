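#' Annualize an equipment purchase by linear depreciation
#'
#' Spreads a purchase cost evenly over the item's estimated useful lifespan
#' (zero salvage value), yielding an annual cost that can be entered in a
#' resource registry alongside recurrent costs.
#'
#' @param purchase_cost Purchase cost (any currency), `>= 0`.
#' @param useful_life_years Estimated useful lifespan in years, `> 0`.
#' @return Annual cost in the same currency, `purchase_cost / useful_life_years`.
#' @examples
#' annualize_equipment(1000, 5) # 200
#' @export
annualize_equipment <- function(purchase_cost, useful_life_years) {
  if (any(!is.finite(useful_life_years)) || any(useful_life_years <= 0)) {
    stop_invalid_parameter("`useful_life_years` must be a positive, finite number of years.")
  }
  if (any(!is.finite(purchase_cost)) || any(purchase_cost < 0)) {
    stop_invalid_parameter("`purchase_cost` must be finite and >= 0.")
  }
  purchase_cost / useful_life_years
}

#' Capacity cost rate of a resource
#'
#' The core TDABC rate: a resource's total annual cost divided by its
#' practical capacity, the minutes per year the resource is actually
#' available for patient-facing work. Multiplying this per-minute rate by
#' observed contact minutes assigns the resource's cost to patients.
#'
#' @param annual_cost Annual cost of the resource (salary incl. fringe,
#'   annualized equipment, space), `>= 0`.
#' @param practical_capacity_minutes Practical capacity in minutes/year, `> 0`.
#' @return Cost per minute, in the currency of `annual_cost`.
#' @examples
#' capacity_cost_rate(120000, 100000) # 1.2 per minute
#' @export
capacity_cost_rate <- function(annual_cost, practical_capacity_minutes) {
  if (any(!is.finite(practical_capacity_minutes)) || any(practical_capacity_minutes <= 0)) {
    stop_invalid_parameter(
      "`practical_capacity_minutes` must be > 0; a non-positive capacity signals a mis-specified capacity profile."
    )
  }
  if (any(!is.finite(annual_cost)) || any(annual_cost < 0)) {
    stop_invalid_parameter("`annual_cost` must be finite and >= 0.")
  }
  annual_cost / practical_capacity_minutes
}

#' Convert Tanzanian Shillings to US Dollars
#'
#' Applied once, at reporting time; all internal costing arithmetic stays in
#' TZS. The default rate is 2,300 TZS per USD.
#'
#' @param amount_tzs Amount in TZS.
#' @param rate TZS per USD, `> 0` (default 2300).
#' @return Amount in USD.
#' @examples
#' convert_tzs_to_usd(2300) # 1
#' @export
convert_tzs_to_usd <- function(amount_tzs, rate = 2300) {
  if (length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop_invalid_parameter("`rate` must be a single positive number of TZS per USD.")
  }
  amount_tzs / rate
}

#' Annualize a per-visit cost by service line
#'
#' Multiplies a per-visit cost by the service line's annual visit frequency:
#' 4 for quarterly stable-ART care, 12 for monthly unstable-ART care, and 1
#' for one-time services (identity).
#'
#' @param per_visit_cost Cost of a single visit, `>= 0`.
#' @param service Service line code, recycled against `per_visit_cost`.
#' @return Annualized cost.
#' @examples
#' annualize_service_cost(22.72, "ART_STABLE") # 90.88
#' annualize_service_cost(14.86, "ART_UNSTABLE") # 178.32
#' @export
annualize_service_cost <- function(per_visit_cost, service) {
  if (any(!is.finite(per_visit_cost)) || any(per_visit_cost < 0)) {
    stop_invalid_parameter("`per_visit_cost` must be finite and >= 0.")
  }
  per_visit_cost * visits_per_year(service)
}

#' Allocate a facility indirect-cost pool across encounters
#'
#' Facility overhead (support staff, utilities and other costs not directly
#' attributable to service provision) is prorated to the observation window
#' (`period_days / 365`) and split across encounters. The default basis is
#' proportional to each encounter's direct staff minutes — the standard
#' TDABC convention, since overhead scales with clinical activity; an
#' equal-share basis is available as an option.
#'
#' @param pool Annual indirect cost of the facility, `>= 0`.
#' @param staff_minutes Named numeric vector of direct staff minutes per
#'   encounter (names are encounter ids).
#' @param basis `"staff_minutes"` (default) or `"equal_share"`.
#' @param period_days Length of the accounting period in days (default 365,
#'   i.e. no proration).
#' @return Named numeric vector of allocations summing to
#'   `pool * period_days / 365`.
#' @examples
#' allocate_indirects(100, c(a = 30, b = 10)) # 75, 25
#' @export
allocate_indirects <- function(pool, staff_minutes,
                               basis = c("staff_minutes", "equal_share"),
                               period_days = 365) {
  basis <- match.arg(basis)
  if (length(pool) != 1 || !is.finite(pool) || pool < 0) {
    stop_invalid_parameter("`pool` must be a single finite number >= 0.")
  }
  if (length(period_days) != 1 || !is.finite(period_days) || period_days <= 0) {
    stop_invalid_parameter("`period_days` must be a single positive number.")
  }
  if (any(!is.finite(staff_minutes)) || any(staff_minutes < 0)) {
    stop_invalid_input("`staff_minutes` must be finite and >= 0.")
  }
  prorated <- pool * period_days / 365
  if (length(staff_minutes) == 0) {
    if (prorated > 0) {
      stop_invalid_input("A positive indirect pool requires at least one encounter.")
    }
    return(setNames(numeric(0), character(0)))
  }
  out <- switch(basis,
    staff_minutes = {
      total <- sum(staff_minutes)
      if (total <= 0 && prorated > 0) {
        abort_tdabc(
          "Cannot allocate a positive indirect pool over zero total staff minutes (degenerate allocation basis).",
          "tdabcost_degenerate_basis"
        )
      }
      if (total <= 0) {
        rep(0, length(staff_minutes))
      } else {
        prorated * staff_minutes / total
      }
    },
    equal_share = rep(prorated / length(staff_minutes), length(staff_minutes))
  )
  setNames(out, names(staff_minutes))
}

#' Cost encounters from step observations
#'
#' The patient-level TDABC costing step. For every encounter, staff and
#' space/equipment costs are the sum over step observations of the
#' resource's capacity cost rate times observed minutes; consumables are
#' priced per dispensed unit; facility indirect pools are prorated to the
#' observation window and allocated across the facility's encounters (see
#' [allocate_indirects()]). All arithmetic is carried out in TZS and
#' converted to USD once at the end.
#'
#' @param observations Tibble of step observations with columns
#'   `encounter_id`, `patient_id`, `facility_id`, `service`, `resource_id`,
#'   `observed_minutes`, `item_id`, `quantity`. Rows with a non-missing
#'   `resource_id` record timed resource use; rows with a non-missing
#'   `item_id` record consumable dispensing.
#' @param resources Resource registry: `resource_id`, `category`
#'   (`"HUMAN_RESOURCES"` or `"SPACE_EQUIPMENT"`), `annual_cost_tzs`,
#'   `practical_capacity_min`.
#' @param prices Consumable price list: `item_id`, `unit_price_tzs`.
#' @param indirect_pools Optional tibble `facility_id`,
#'   `annual_indirect_cost_tzs`. `NULL` means no indirect costs.
#' @param encounters Optional tibble (`encounter_id`, `patient_id`,
#'   `facility_id`, `service`) enumerating encounters; encounters absent
#'   from `observations` are costed at zero. Defaults to the encounters
#'   present in `observations`.
#' @param usd_rate TZS per USD (default 2300).
#' @param allocation_basis Indirect allocation basis, see
#'   [allocate_indirects()].
#' @param period_days Observation window length in days used to prorate
#'   annual indirect pools (default 365).
#' @return Tibble with one row per encounter: the four category costs in
#'   USD, `total_per_visit_usd` (their sum), `annualized_total_usd`
#'   (total times the service line's visits/year) and `provider_minutes`
#'   (summed staff-resource contact minutes).
#' @export
cost_encounters <- function(observations, resources, prices,
                            indirect_pools = NULL, encounters = NULL,
                            usd_rate = 2300,
                            allocation_basis = c("staff_minutes", "equal_share"),
                            period_days = 365) {
  allocation_basis <- match.arg(allocation_basis)
  obs <- tibble::as_tibble(observations)
  needed <- c(
    "encounter_id", "patient_id", "facility_id", "service",
    "resource_id", "observed_minutes", "item_id", "quantity"
  )
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols) > 0) {
    stop_invalid_input(paste0(
      "`observations` is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }

  res_rows <- dplyr::filter(obs, !is.na(resource_id))
  item_rows <- dplyr::filter(obs, !is.na(item_id))

  if (any(!is.finite(res_rows$observed_minutes)) || any(res_rows$observed_minutes < 0)) {
    stop_invalid_input("`observed_minutes` must be finite and >= 0 for resource observations.")
  }
  if (any(is.na(item_rows$quantity)) || any(item_rows$quantity < 0)) {
    stop_invalid_input("Consumable `quantity` must be non-missing and >= 0.")
  }

  unknown_res <- setdiff(unique(res_rows$resource_id), resources$resource_id)
  if (length(unknown_res) > 0) {
    stop_missing_reference(
      paste0(
        "Observations reference unknown resource_id(s): ",
        paste(unknown_res, collapse = ", ")
      ),
      ids = unknown_res
    )
  }
  unknown_items <- setdiff(unique(item_rows$item_id), prices$item_id)
  if (length(unknown_items) > 0) {
    stop_missing_reference(
      paste0(
        "Observations reference unknown item_id(s): ",
        paste(unknown_items, collapse = ", ")
      ),
      ids = unknown_items
    )
  }

  rates <- resources |>
    dplyr::mutate(rate_tzs_min = capacity_cost_rate(annual_cost_tzs, practical_capacity_min)) |>
    dplyr::select(resource_id, category, rate_tzs_min)

  if (is.null(encounters)) {
    encounters <- dplyr::distinct(obs, encounter_id, patient_id, facility_id, service)
  } else {
    encounters <- tibble::as_tibble(encounters) |>
      dplyr::distinct(encounter_id, patient_id, facility_id, service)
  }
  assert_service(encounters$service)
  if (anyDuplicated(encounters$encounter_id) > 0) {
    stop_invalid_input("Encounter ids must be unique across patients/facilities.")
  }

  direct <- res_rows |>
    dplyr::left_join(rates, by = "resource_id") |>
    dplyr::group_by(encounter_id) |>
    dplyr::summarise(
      hr_tzs = sum(rate_tzs_min * observed_minutes * (category == "HUMAN_RESOURCES")),
      space_tzs = sum(rate_tzs_min * observed_minutes * (category == "SPACE_EQUIPMENT")),
      provider_minutes = sum(observed_minutes * (category == "HUMAN_RESOURCES")),
      .groups = "drop"
    )

  cons <- item_rows |>
    dplyr::left_join(dplyr::select(prices, item_id, unit_price_tzs), by = "item_id") |>
    dplyr::group_by(encounter_id) |>
    dplyr::summarise(cons_tzs = sum(unit_price_tzs * quantity), .groups = "drop")

  costed <- encounters |>
    dplyr::left_join(direct, by = "encounter_id") |>
    dplyr::left_join(cons, by = "encounter_id") |>
    dplyr::mutate(
      hr_tzs = dplyr::coalesce(hr_tzs, 0),
      space_tzs = dplyr::coalesce(space_tzs, 0),
      cons_tzs = dplyr::coalesce(cons_tzs, 0),
      provider_minutes = dplyr::coalesce(provider_minutes, 0),
      indirect_tzs = 0
    )

  if (!is.null(indirect_pools)) {
    pools <- tibble::as_tibble(indirect_pools)
    if (any(!is.finite(pools$annual_indirect_cost_tzs)) ||
      any(pools$annual_indirect_cost_tzs < 0)) {
      stop_invalid_parameter("Indirect pools must be finite and >= 0.")
    }
    for (k in seq_len(nrow(pools))) {
      fid <- pools$facility_id[k]
      pool <- pools$annual_indirect_cost_tzs[k]
      idx <- which(costed$facility_id == fid)
      if (length(idx) == 0) {
        if (pool > 0) {
          rlang::warn(
            paste0(
              "Indirect pool for facility ", fid,
              " skipped: no encounters observed at that facility."
            ),
            class = "tdabcost_unallocated_pool"
          )
        }
        next
      }
      alloc <- allocate_indirects(
        pool,
        setNames(costed$provider_minutes[idx], costed$encounter_id[idx]),
        basis = allocation_basis, period_days = period_days
      )
      costed$indirect_tzs[idx] <- unname(alloc)
    }
  }

  costed |>
    dplyr::mutate(
      human_resources_usd = convert_tzs_to_usd(hr_tzs, usd_rate),
      space_equipment_usd = convert_tzs_to_usd(space_tzs, usd_rate),
      indirects_usd = convert_tzs_to_usd(indirect_tzs, usd_rate),
      consumables_usd = convert_tzs_to_usd(cons_tzs, usd_rate),
      total_per_visit_usd = human_resources_usd + space_equipment_usd +
        indirects_usd + consumables_usd,
      annualized_total_usd = annualize_service_cost(total_per_visit_usd, service)
    ) |>
    dplyr::select(
      encounter_id, patient_id, facility_id, service,
      human_resources_usd, space_equipment_usd, indirects_usd, consumables_usd,
      total_per_visit_usd, annualized_total_usd, provider_minutes
    )
}
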