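# Synthetic study generator: a seeded, fully synthetic multi-facility HIV
# service delivery study (facility roster, resource registries, patients,
# step observations, consumable dispensing) with known ground-truth effects,
# so every downstream stage of the costing and equity pipeline is testable
# without field data.

#' Default facility roster
#'
#' 22 facilities spanning the sampling strata of a national HIV service
#' study design: 5 dispensaries, 10 health centres and 7 hospitals across
#' seven regions, urban and rural, public and private/faith-based, with one
#' facility not supported by PEPFAR, and low/medium/high HIV client volume
#' tiers.
#'
#' @return Tibble with columns `region`, `facility_type`, `rurality`,
#'   `sector`, `funder`, `volume_tier`.
#' @export
facility_roster <- function() {
  tibble::tribble(
    ~region, ~facility_type, ~rurality, ~sector, ~funder, ~volume_tier,
    "DAR_ES_SALAAM", "DISPENSARY", "URBAN", "PUBLIC", "PEPFAR", "LOW",
    "MWANZA", "DISPENSARY", "RURAL", "PUBLIC", "PEPFAR", "MEDIUM",
    "MWANZA", "DISPENSARY", "URBAN", "PUBLIC", "PEPFAR", "LOW",
    "TABORA", "DISPENSARY", "RURAL", "PRIVATE_FBO", "PEPFAR", "MEDIUM",
    "TABORA", "DISPENSARY", "RURAL", "PUBLIC", "GOT", "LOW",
    "KAGERA", "HEALTH_CENTRE", "RURAL", "PUBLIC", "PEPFAR", "HIGH",
    "DODOMA", "HEALTH_CENTRE", "RURAL", "PUBLIC", "PEPFAR", "MEDIUM",
    "MBEYA", "HEALTH_CENTRE", "RURAL", "PUBLIC", "PEPFAR", "MEDIUM",
    "MBEYA", "HEALTH_CENTRE", "RURAL", "PUBLIC", "PEPFAR", "MEDIUM",
    "MBEYA", "HEALTH_CENTRE", "URBAN", "PUBLIC", "PEPFAR", "HIGH",
    "NJOMBE", "HEALTH_CENTRE", "RURAL", "PUBLIC", "PEPFAR", "MEDIUM",
    "DAR_ES_SALAAM", "HEALTH_CENTRE", "URBAN", "PUBLIC", "PEPFAR", "HIGH",
    "DODOMA", "HEALTH_CENTRE", "URBAN", "PUBLIC", "PEPFAR", "HIGH",
    "NJOMBE", "HEALTH_CENTRE", "URBAN", "PUBLIC", "PEPFAR", "HIGH",
    "TABORA", "HEALTH_CENTRE", "RURAL", "PUBLIC", "PEPFAR", "LOW",
    "KAGERA", "HOSPITAL", "RURAL", "PUBLIC", "PEPFAR", "HIGH",
    "NJOMBE", "HOSPITAL", "RURAL", "PRIVATE_FBO", "PEPFAR", "HIGH",
    "DAR_ES_SALAAM", "HOSPITAL", "URBAN", "PUBLIC", "PEPFAR", "HIGH",
    "MWANZA", "HOSPITAL", "RURAL", "PUBLIC", "PEPFAR", "HIGH",
    "DODOMA", "HOSPITAL", "RURAL", "PRIVATE_FBO", "PEPFAR", "MEDIUM",
    "TABORA", "HOSPITAL", "RURAL", "PUBLIC", "PEPFAR", "HIGH",
    "MBEYA", "HOSPITAL", "RURAL", "PUBLIC", "PEPFAR", "HIGH"
  )
}

#' Default ground-truth effects on visit duration
#'
#' True regression coefficients, in minutes of provider-patient contact
#' time, for every design-matrix term (see [design_term_names()]). These
#' drive the duration generator; the implied cost-model coefficients are a
#' fixed multiple of them (the combined direct cost rate per minute) plus
#' service-level consumable offsets, and are stored alongside each
#' generated study for recovery testing. Defaults encode plausible patterns
#' for HIV service delivery: a long surgical VMMC visit (+51 min vs
#' testing/counseling), shorter PrEP visits, more provider time for
#' patients with comorbidities (+5.4), a small wealth gradient (+0.9 per
#' asset-index unit), and longer visits at externally funded facilities
#' (+11.6).
#'
#' @return Named numeric vector over [design_term_names()].
#' @export
default_ground_truth_effects <- function() {
  c(
    intercept = 16,
    male = -1,
    age_31_50 = -5, age_51_70 = -4, age_71_plus = -3,
    married = 0.5,
    edu_2_3 = 0.5, edu_4_5 = 1, edu_6_plus = 1.5,
    comorbidity = 5.4,
    asset_index = 0.9,
    svc_art_stable = -1, svc_art_unstable = 0, svc_pmtct = 5,
    svc_prep = -7.5, svc_vmmc = 51,
    region_dodoma = 0.5, region_kagera = -0.5, region_mbeya = 1,
    region_mwanza = 2, region_njombe = 0, region_tabora = -1,
    type_health_centre = 2, type_hospital = 3,
    rural = 1,
    pepfar = 11.6,
    volume_low = 2, volume_medium = 1
  )[design_term_names()]
}

#' Zero out patient-level ground-truth effects
#'
#' Returns a copy of an effects vector with every patient-level term (see
#' [patient_terms()]) set to zero, for type-I-error simulations.
#'
#' @param effects Named effects vector (default
#'   [default_ground_truth_effects()]).
#' @return Named numeric vector.
#' @export
zero_patient_effects <- function(effects = default_ground_truth_effects()) {
  effects[patient_terms()] <- 0
  effects
}

#' Default consumable plan
#'
#' Per-service consumable bundles: item, unit price (TZS) and quantity
#' model. ART bundles are fixed (standardized medication and lab packages,
#' identical across facilities and encounters); other services mix fixed
#' items with Poisson-count items whose facility-level mean varies (see
#' `consumable_facility_cv` in [sim_config()]). Quantity models:
#' `"fixed"` (always `qty_base`), `"one_plus_pois"` (1 + Poisson with mean
#' `qty_base`), `"pois"` (Poisson with mean `qty_base`).
#'
#' @return Tibble: `service`, `item_id`, `name`, `kind`, `unit_price_tzs`,
#'   `qty_base`, `qty_model`.
#' @export
default_consumable_plan <- function() {
  tibble::tribble(
    ~service, ~item_id, ~name, ~kind, ~unit_price_tzs, ~qty_base, ~qty_model,
    "ART_STABLE", "arv_90d_pack", "ARV 90-day pack", "MEDICATION", 45000, 1, "fixed",
    "ART_STABLE", "vl_test", "Viral load test", "LAB", 4427, 1, "fixed",
    "ART_UNSTABLE", "arv_30d_pack", "ARV 30-day pack", "MEDICATION", 15000, 1, "fixed",
    "ART_UNSTABLE", "vl_test", "Viral load test", "LAB", 4427, 1, "fixed",
    "ART_UNSTABLE", "chem_panel", "Chemistry panel", "LAB", 11761, 1, "fixed",
    "HTC", "hiv_rapid_test", "HIV rapid test kit", "LAB", 2300, 1, "fixed",
    "HTC", "htc_counseling_kit", "Counseling and testing materials", "SUPPLY", 4140, 1, "fixed",
    "HTC", "clinic_supplies", "Syringes, gauze, gloves", "SUPPLY", 230, 10, "pois",
    "PMTCT", "pmtct_arv_bundle", "PMTCT ARV/prophylaxis bundle", "MEDICATION", 45080, 1, "fixed",
    "PMTCT", "clinic_supplies", "Syringes, gauze, gloves", "SUPPLY", 230, 8, "pois",
    "PREP", "prep_tdf_ftc", "PrEP TDF/FTC bottle", "MEDICATION", 9200, 1, "fixed",
    "PREP", "hiv_rapid_test", "HIV rapid test kit", "LAB", 2300, 1, "fixed",
    "PREP", "clinic_supplies", "Syringes, gauze, gloves", "SUPPLY", 230, 10, "pois",
    "VMMC", "vmmc_kit", "Circumcision kit", "SUPPLY", 36800, 1, "fixed",
    "VMMC", "vmmc_meds", "Anesthetic and antibiotics", "MEDICATION", 9200, 1, "fixed",
    "VMMC", "vmmc_sutures", "Sutures and dressing", "SUPPLY", 4600, 1, "fixed",
    "VMMC", "clinic_supplies", "Syringes, gauze, gloves", "SUPPLY", 230, 7, "pois"
  )
}

#' Default household asset indicators
#'
#' Indicator items and population prevalences for the latent-wealth model:
#' each indicator is a thresholded function of a standard normal latent
#' wealth plus item-specific noise, so a single recoverable wealth factor
#' underlies the matrix. Prevalences reflect a predominantly low-income
#' cohort (23% electricity, 37% mobile phone, 3% refrigerator).
#'
#' @return Tibble: `item`, `prevalence`.
#' @export
default_asset_items <- function() {
  tibble::tribble(
    ~item, ~prevalence,
    "electricity", 0.23,
    "mobile_phone", 0.37,
    "refrigerator", 0.03,
    "television", 0.15,
    "improved_flooring", 0.30,
    "improved_roofing", 0.40,
    "radio", 0.28,
    "bicycle", 0.35
  )
}

#' Default cohort demographics by service line
#'
#' Marginal distributions used to draw patient covariates: proportion
#' female (1 for PMTCT, 0 for VMMC by eligibility), mean/SD of age
#' (truncated at 18) and of years of education, and proportions married
#' and with comorbid conditions.
#'
#' @return Tibble keyed by `service`.
#' @export
default_demographics <- function() {
  tibble::tribble(
    ~service, ~female_p, ~age_mean, ~age_sd, ~married_p, ~edu_mean, ~edu_sd, ~comorbid_p,
    "ART_STABLE", 147 / 240, 43.3, 11.2, 104 / 240, 2.9, 1.3, 38 / 240,
    "ART_UNSTABLE", 145 / 214, 39.4, 11.9, 85 / 214, 2.7, 1.2, 38 / 214,
    "HTC", 104 / 198, 33.5, 13.2, 101 / 198, 3.2, 1.4, 18 / 198,
    "PMTCT", 1.0, 30.0, 6.6, 128 / 200, 2.9, 1.1, 4 / 200,
    "PREP", 13 / 15, 26.9, 6.3, 7 / 15, 3.3, 1.0, 0,
    "VMMC", 0.0, 29.1, 10.9, 11 / 19, 2.1, 1.1, 0
  )
}

#' Process-step templates by service line
#'
#' The care pathway of each service: ordered steps with location, staffing
#' cadre and the fraction of total provider-patient contact time spent at
#' the step. Fractions sum to one per service so the summed staff minutes
#' of an encounter equal its total contact duration.
#'
#' @return Named list of tibbles (`order`, `location`, `cadre`, `fraction`).
#' @export
step_templates <- function() {
  art <- tibble::tribble(
    ~order, ~location, ~cadre, ~fraction,
    1L, "reception", "nurse", 0.10,
    2L, "consultation_room", "clinician", 0.55,
    3L, "pharmacy", "pharm_tech", 0.35
  )
  list(
    ART_STABLE = art,
    ART_UNSTABLE = art,
    HTC = tibble::tribble(
      ~order, ~location, ~cadre, ~fraction,
      1L, "reception", "nurse", 0.10,
      2L, "counseling_room", "counselor", 0.60,
      3L, "counseling_room", "counselor", 0.30
    ),
    PMTCT = tibble::tribble(
      ~order, ~location, ~cadre, ~fraction,
      1L, "reception", "nurse", 0.10,
      2L, "anc_room", "nurse", 0.40,
      3L, "consultation_room", "clinician", 0.35,
      4L, "pharmacy", "pharm_tech", 0.15
    ),
    PREP = tibble::tribble(
      ~order, ~location, ~cadre, ~fraction,
      1L, "reception", "nurse", 0.10,
      2L, "counseling_room", "counselor", 0.50,
      3L, "pharmacy", "pharm_tech", 0.40
    ),
    VMMC = tibble::tribble(
      ~order, ~location, ~cadre, ~fraction,
      1L, "reception", "nurse", 0.05,
      2L, "counseling_room", "counselor", 0.15,
      3L, "theatre", "clinician", 0.70,
      4L, "recovery_room", "nurse", 0.10
    )
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study generator. Defaults
#' emulate the design of a national HIV service costing study: 22
#' facilities, 886 patients (240 stable ART, 214 unstable ART, 198 HTC,
#' 200 PMTCT, 15 PrEP, 19 VMMC), a 45-day observation window, a 2,300
#' TZS/USD conversion, and a consumables-dominant cost structure.
#'
#' All direct clinical cadres share one capacity cost rate
#' (`staff_annual_cost_tzs / staff_capacity_min`, default 138 TZS/min) and
#' rooms another (9.2 TZS/min incl. annualized equipment); indirect pools
#' are sized so overhead runs at `indirect_rate_tzs_per_min` (default 23)
#' per staff minute. With uniform rates the true cost-model coefficients
#' are exact multiples of the duration coefficients, which keeps
#' parameter-recovery checks well defined (see the methods vignette).
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   seed and configuration.
#' @param n_facilities Number of facilities (default 22; fewer takes the
#'   head of the roster, more recycles sampled strata).
#' @param sample_sizes Named integer vector of patients per service line.
#' @param usd_rate TZS per USD.
#' @param observation_window_days Length of the field observation window.
#' @param staff_annual_cost_tzs,staff_capacity_min Annual cost (salary
#'   incl. fringe) and practical capacity of each clinical cadre.
#' @param space_annual_cost_tzs,space_capacity_min Annual recurrent cost
#'   and practical capacity of a clinical room (equipment depreciation is
#'   added from `equipment`).
#' @param equipment Tibble `item`, `purchase_cost_tzs`, `useful_life_years`
#'   of equipment items per room, annualized by linear depreciation.
#' @param indirect_rate_tzs_per_min Nominal overhead cost per direct staff
#'   minute used to size facility indirect pools.
#' @param duration_noise_sd,duration_noise_shape SD (minutes) and gamma
#'   shape of the mean-zero, right-skewed duration noise.
#' @param duration_floor_minutes Lower bound on simulated durations.
#' @param effects Named ground-truth effects vector (minutes), see
#'   [default_ground_truth_effects()].
#' @param consumable_plan See [default_consumable_plan()].
#' @param consumable_facility_cv Coefficient of variation of the
#'   facility-level multiplier on non-fixed consumable quantities.
#' @param asset_items,asset_loading Asset indicators and the loading of the
#'   latent wealth factor on each indicator's liability scale.
#' @param volume_weights Relative patient-volume weights of the facility
#'   volume tiers, used for patient-facility assignment.
#' @param demographics See [default_demographics()].
#' @return A list of class `tdabc_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_facilities = 22L,
                       sample_sizes = c(
                         ART_STABLE = 240L, ART_UNSTABLE = 214L, HTC = 198L,
                         PMTCT = 200L, PREP = 15L, VMMC = 19L
                       ),
                       usd_rate = 2300,
                       observation_window_days = 45,
                       staff_annual_cost_tzs = 13800000,
                       staff_capacity_min = 100000,
                       space_annual_cost_tzs = 874000,
                       space_capacity_min = 100000,
                       equipment = tibble::tribble(
                         ~item, ~purchase_cost_tzs, ~useful_life_years,
                         "exam_table", 230000, 10,
                         "bp_machine", 46000, 2
                       ),
                       indirect_rate_tzs_per_min = 23,
                       duration_noise_sd = 6,
                       duration_noise_shape = 4,
                       duration_floor_minutes = 1,
                       effects = default_ground_truth_effects(),
                       consumable_plan = default_consumable_plan(),
                       consumable_facility_cv = 0.03,
                       asset_items = default_asset_items(),
                       asset_loading = 1.5,
                       volume_weights = c(LOW = 1, MEDIUM = 3, HIGH = 8),
                       demographics = default_demographics()) {
  if (any(sample_sizes < 0)) stop_invalid_parameter("Sample sizes must be >= 0.")
  if (duration_noise_sd < 0 || duration_noise_shape <= 0) {
    stop_invalid_parameter("Duration noise SD must be >= 0 and shape > 0.")
  }
  missing_terms <- setdiff(design_term_names(), names(effects))
  if (length(missing_terms) > 0) {
    stop_invalid_parameter(paste0(
      "`effects` is missing term(s): ", paste(missing_terms, collapse = ", ")
    ))
  }
  if (n_facilities < 1) stop_invalid_parameter("`n_facilities` must be >= 1.")
  cfg <- list(
    seed = as.integer(seed),
    n_facilities = as.integer(n_facilities),
    sample_sizes = sample_sizes[service_lines()],
    usd_rate = usd_rate,
    observation_window_days = observation_window_days,
    staff_annual_cost_tzs = staff_annual_cost_tzs,
    staff_capacity_min = staff_capacity_min,
    space_annual_cost_tzs = space_annual_cost_tzs,
    space_capacity_min = space_capacity_min,
    equipment = equipment,
    indirect_rate_tzs_per_min = indirect_rate_tzs_per_min,
    duration_noise_sd = duration_noise_sd,
    duration_noise_shape = duration_noise_shape,
    duration_floor_minutes = duration_floor_minutes,
    effects = effects[design_term_names()],
    consumable_plan = consumable_plan,
    consumable_facility_cv = consumable_facility_cv,
    asset_items = asset_items,
    asset_loading = asset_loading,
    volume_weights = volume_weights,
    demographics = demographics
  )
  class(cfg) <- "tdabc_sim_config"
  cfg
}

# derived per-minute rates -------------------------------------------------

staff_rate_tzs <- function(config) {
  config$staff_annual_cost_tzs / config$staff_capacity_min
}

space_rate_tzs <- function(config) {
  equip_annual <- sum(annualize_equipment(
    config$equipment$purchase_cost_tzs, config$equipment$useful_life_years
  ))
  (config$space_annual_cost_tzs + equip_annual) / config$space_capacity_min
}

#' Combined direct cost rate implied by a configuration
#'
#' Staff plus space plus nominal indirect cost per provider-patient minute,
#' in USD. Under the generator's uniform-rate design this is the exact
#' factor linking true duration coefficients to true
#' cost-without-consumables coefficients.
#'
#' @param config A [sim_config()].
#' @return USD per minute.
#' @export
direct_rate_usd_per_min <- function(config) {
  (staff_rate_tzs(config) + space_rate_tzs(config) +
    config$indirect_rate_tzs_per_min) / config$usd_rate
}

# analytic expectations ----------------------------------------------------

# P(age group) for a rounded, >=18-truncated normal age
age_group_probs <- function(mean, sd) {
  lo <- stats::pnorm((17.5 - mean) / sd)
  cdf <- function(b) (stats::pnorm((b - mean) / sd) - lo) / (1 - lo)
  p <- c(cdf(30.5), cdf(50.5) - cdf(30.5), cdf(70.5) - cdf(50.5))
  c(p, 1 - sum(p))
}

# P(education level) for a rounded normal clipped to [0, 11]
edu_level_probs <- function(mean, sd) {
  cdf <- function(b) stats::pnorm((b - mean) / sd)
  p <- c(cdf(1.5), cdf(3.5) - cdf(1.5), cdf(5.5) - cdf(3.5))
  c(p, 1 - sum(p))
}

# expected duration components: patient-mix effect per service and the
# facility effect of each roster row
expected_patient_effect <- function(config, svc) {
  b <- config$effects
  d <- config$demographics[config$demographics$service == svc, ]
  agep <- age_group_probs(d$age_mean, d$age_sd)
  edup <- edu_level_probs(d$edu_mean, d$edu_sd)
  (1 - d$female_p) * b[["male"]] +
    sum(agep[2:4] * b[c("age_31_50", "age_51_70", "age_71_plus")]) +
    d$married_p * b[["married"]] +
    sum(edup[2:4] * b[c("edu_2_3", "edu_4_5", "edu_6_plus")]) +
    d$comorbid_p * b[["comorbidity"]]
}

service_offset <- function(config, svc) {
  b <- config$effects
  svc_terms <- c(
    HTC = NA, ART_STABLE = "svc_art_stable", ART_UNSTABLE = "svc_art_unstable",
    PMTCT = "svc_pmtct", PREP = "svc_prep", VMMC = "svc_vmmc"
  )
  if (svc == "HTC") 0 else b[[svc_terms[[svc]]]]
}

facility_effect <- function(config, facilities) {
  b <- config$effects
  f <- equity_factors()
  eff <- rep(0, nrow(facilities))
  pick <- function(values, spec) {
    out <- rep(0, length(values))
    for (lev in names(spec$terms)) {
      out <- out + b[[spec$terms[[lev]]]] * (values == lev)
    }
    out
  }
  eff + pick(facilities$region, f$region) +
    pick(facilities$facility_type, f$facility_type) +
    pick(facilities$rurality, f$rurality) +
    pick(facilities$funder, f$funder) +
    pick(facilities$volume_tier, f$volume_tier)
}

expected_consumables_tzs <- function(config, svc) {
  plan <- config$consumable_plan[config$consumable_plan$service == svc, ]
  if (nrow(plan) == 0) {
    return(0)
  }
  eq <- ifelse(plan$qty_model == "one_plus_pois", 1 + plan$qty_base, plan$qty_base)
  sum(plan$unit_price_tzs * eq)
}

#' Expected category means implied by a configuration
#'
#' Analytic per-visit expectations of the four cost categories and the
#' total, per service line, in USD, averaging facility effects over the
#' volume-weighted facility assignment distribution. Used for
#' law-of-large-numbers calibration checks of the generator.
#'
#' @param config A [sim_config()].
#' @param facilities Optional facility table (defaults to the roster the
#'   config would generate).
#' @return Tibble keyed by `service` with columns per category, total and
#'   `expected_duration_min`.
#' @export
expected_category_means <- function(config, facilities = NULL) {
  if (is.null(facilities)) {
    facilities <- simulate_facilities(config)$facilities
  }
  w <- config$volume_weights[facilities$volume_tier]
  p_f <- w / sum(w)
  fac_eff <- sum(p_f * facility_effect(config, facilities))
  purrr::map_dfr(service_lines(), function(svc) {
    mu <- config$effects[["intercept"]] + service_offset(config, svc) +
      expected_patient_effect(config, svc) + fac_eff
    hr <- mu * staff_rate_tzs(config) / config$usd_rate
    sp <- mu * space_rate_tzs(config) / config$usd_rate
    ind <- mu * config$indirect_rate_tzs_per_min / config$usd_rate
    cons <- expected_consumables_tzs(config, svc) / config$usd_rate
    tibble::tibble(
      service = svc,
      expected_duration_min = mu,
      human_resources_usd = hr,
      space_equipment_usd = sp,
      indirects_usd = ind,
      consumables_usd = cons,
      total_per_visit_usd = hr + sp + ind + cons
    )
  })
}

# component simulators ------------------------------------------------------

# collision-free component seeds: distinct study seeds never share a
# component seed (offsets 1..3 with stride 5)
derive_seed <- function(seed, offset) {
  as.integer((5 * as.numeric(seed) + offset) %% (.Machine$integer.max - 1))
}

#' Simulate the facility layer
#'
#' Generates the facility roster (default: the 22-facility design of
#' [facility_roster()]), per-facility resource registries (four clinical
#' cadres and a clinical room, with annual costs and practical capacities),
#' equipment inventories, process maps, and annual indirect pools sized
#' from each facility's expected workload at the configured overhead rate.
#'
#' @param config A [sim_config()].
#' @return List: `facilities`, `resources`, `equipment`, `process_maps`,
#'   `indirect_pools`.
#' @export
simulate_facilities <- function(config) {
  set.seed(derive_seed(config$seed, 1))
  roster <- facility_roster()
  n <- config$n_facilities %||% 22L
  if (n <= nrow(roster)) {
    roster <- roster[seq_len(n), ]
  } else {
    extra <- roster[sample.int(nrow(roster), n - nrow(roster), replace = TRUE), ]
    roster <- dplyr::bind_rows(roster, extra)
  }
  facilities <- roster |>
    dplyr::mutate(
      facility_id = sprintf("F%02d", dplyr::row_number()),
      name = sprintf("Facility %02d", dplyr::row_number()),
      .before = 1
    )

  cadres <- c("nurse", "clinician", "counselor", "pharm_tech")
  equip_annual <- sum(annualize_equipment(
    config$equipment$purchase_cost_tzs, config$equipment$useful_life_years
  ))
  resources <- purrr::map_dfr(facilities$facility_id, function(fid) {
    dplyr::bind_rows(
      tibble::tibble(
        facility_id = fid,
        resource_id = paste0(fid, "_", cadres),
        name = cadres,
        category = "HUMAN_RESOURCES",
        annual_cost_tzs = config$staff_annual_cost_tzs,
        practical_capacity_min = config$staff_capacity_min
      ),
      tibble::tibble(
        facility_id = fid,
        resource_id = paste0(fid, "_room"),
        name = "clinical_room",
        category = "SPACE_EQUIPMENT",
        annual_cost_tzs = config$space_annual_cost_tzs + equip_annual,
        practical_capacity_min = config$space_capacity_min
      )
    )
  })

  equipment <- tidyr::crossing(
    facility_id = facilities$facility_id, config$equipment
  )

  templates <- step_templates()
  expected <- expected_category_means(config, facilities)
  process_maps <- purrr::map_dfr(facilities$facility_id, function(fid) {
    purrr::imap_dfr(templates, function(tmpl, svc) {
      mu <- expected$expected_duration_min[expected$service == svc]
      tibble::tibble(
        facility_id = fid,
        service = svc,
        step_id = paste0(svc, "_S", tmpl$order),
        order = tmpl$order,
        location = tmpl$location,
        resource_id = paste0(fid, "_", tmpl$cadre),
        default_minutes = round(tmpl$fraction * mu, 1),
        frequency = 1
      )
    })
  })

  # indirect pools: overhead scaled to expected direct staff minutes in the
  # observation window, grossed back up to an annual figure
  w <- config$volume_weights[facilities$volume_tier]
  p_f <- w / sum(w)
  fac_eff <- facility_effect(config, facilities)
  base_minutes <- sum(purrr::map_dbl(service_lines(), function(svc) {
    config$sample_sizes[[svc]] *
      (config$effects[["intercept"]] + service_offset(config, svc) +
        expected_patient_effect(config, svc))
  }))
  n_total <- sum(config$sample_sizes)
  exp_window_minutes <- p_f * (base_minutes + n_total * fac_eff)
  indirect_pools <- tibble::tibble(
    facility_id = facilities$facility_id,
    annual_indirect_cost_tzs = config$indirect_rate_tzs_per_min *
      pmax(exp_window_minutes, 0) * 365 / config$observation_window_days
  )

  list(
    facilities = facilities,
    resources = resources,
    equipment = equipment,
    process_maps = process_maps,
    indirect_pools = indirect_pools
  )
}

#' Simulate the patient cohort
#'
#' Draws patient exit-interview covariates per service line from the
#' configured demographic margins (ages truncated at 18; every PMTCT
#' patient female and every VMMC patient male by eligibility), assigns
#' patients to facilities with probability proportional to the facility's
#' volume-tier weight, and generates household asset indicators from a
#' latent Gaussian wealth factor so that a single recoverable dimension
#' underlies the asset matrix.
#'
#' @param config A [sim_config()].
#' @param facilities Facility table from [simulate_facilities()].
#' @return List: `patients` (tibble incl. `asset_*` indicator columns) and
#'   `latent_wealth` (tibble `patient_id`, `latent_wealth`; kept out of the
#'   analysis inputs).
#' @export
simulate_patients <- function(config, facilities) {
  set.seed(derive_seed(config$seed, 2))
  w <- config$volume_weights[facilities$volume_tier]
  items <- config$asset_items
  lam <- config$asset_loading
  tau <- stats::qnorm(1 - items$prevalence) * sqrt(1 + lam^2)

  pats <- purrr::map_dfr(service_lines(), function(svc) {
    n <- config$sample_sizes[[svc]]
    if (n == 0) {
      return(tibble::tibble())
    }
    d <- config$demographics[config$demographics$service == svc, ]
    # inverse-CDF truncated normal so rounded ages are always >= 18
    lo <- stats::pnorm((17.5 - d$age_mean) / d$age_sd)
    age <- round(d$age_mean + d$age_sd * stats::qnorm(stats::runif(n, lo, 1)))
    tibble::tibble(
      service = svc,
      gender = ifelse(stats::runif(n) < d$female_p, "FEMALE", "MALE"),
      age = as.numeric(age),
      married = stats::runif(n) < d$married_p,
      education_years = pmin(11, pmax(0, round(stats::rnorm(n, d$edu_mean, d$edu_sd)))),
      comorbidity = stats::runif(n) < d$comorbid_p
    )
  })
  n_total <- nrow(pats)
  pats <- pats |>
    dplyr::mutate(
      patient_id = sprintf("P%04d", dplyr::row_number()),
      facility_id = sample(facilities$facility_id, n_total,
        replace = TRUE, prob = w
      ),
      .before = 1
    )

  wlt <- stats::rnorm(n_total)
  ind <- vapply(seq_len(nrow(items)), function(j) {
    as.numeric(lam * wlt + stats::rnorm(n_total) > tau[j])
  }, numeric(n_total))
  colnames(ind) <- paste0("asset_", items$item)
  patients <- dplyr::bind_cols(pats, tibble::as_tibble(ind))

  list(
    patients = patients,
    latent_wealth = tibble::tibble(
      patient_id = patients$patient_id,
      latent_wealth = wlt
    )
  )
}

#' Simulate encounters and step observations
#'
#' One encounter per patient. Total provider-patient contact minutes are a
#' linear predictor over the ground-truth effects (using the same design
#' encoding as the analysis, with the wealth effect applied to the realized
#' PCA asset index) plus mean-zero gamma-shaped noise, floored at
#' `duration_floor_minutes`. The duration is split over the service's
#' process-map steps in fixed fractions; each step contributes a staff
#' observation and a matching room observation, and consumables are
#' dispensed at the final step per the consumable plan.
#'
#' @param config A [sim_config()].
#' @param facilities Facility table from [simulate_facilities()].
#' @param patients Patient table from [simulate_patients()].
#' @return List: `observations` (step/consumable rows), `prices` (item
#'   price list), `encounters` (encounter roster with the true linear
#'   predictor and realized duration).
#' @export
simulate_encounters <- function(config, facilities, patients) {
  set.seed(derive_seed(config$seed, 3))
  asset_cols <- grep("^asset_", names(patients), value = TRUE)
  idx <- build_asset_index(patients[asset_cols], ids = patients$patient_id)

  frame <- patients |>
    dplyr::left_join(dplyr::rename(idx, asset_index = "score"), by = "patient_id") |>
    dplyr::mutate(
      age_group = as.character(cut(age,
        breaks = c(-Inf, 30, 50, 70, Inf),
        labels = c("18-30", "31-50", "51-70", "71+"), right = TRUE
      )),
      education_level = as.character(cut(education_years,
        breaks = c(-Inf, 1, 3, 5, Inf),
        labels = c("0-1", "2-3", "4-5", "6+"), right = TRUE
      ))
    ) |>
    dplyr::left_join(
      dplyr::select(
        facilities, facility_id, region, facility_type, rurality, funder,
        volume_tier
      ),
      by = "facility_id"
    )

  X <- withCallingHandlers(
    encode_design_matrix(frame),
    tdabcost_empty_level = function(w) rlang::cnd_muffle(w)
  )
  beta <- config$effects[colnames(X)]
  mu <- as.numeric(X %*% beta)
  n <- nrow(frame)
  eps <- if (config$duration_noise_sd > 0) {
    shape <- config$duration_noise_shape
    scale <- config$duration_noise_sd / sqrt(shape)
    stats::rgamma(n, shape = shape, scale = scale) - shape * scale
  } else {
    rep(0, n)
  }
  duration <- pmax(config$duration_floor_minutes, mu + eps)

  encounters <- tibble::tibble(
    encounter_id = sprintf("E%04d", seq_len(n)),
    patient_id = frame$patient_id,
    facility_id = frame$facility_id,
    service = frame$service,
    linear_predictor_min = mu,
    duration_min = duration
  )

  # staff + room rows per process step
  templates <- step_templates()
  step_rows <- purrr::imap_dfr(templates, function(tmpl, svc) {
    enc <- encounters[encounters$service == svc, ]
    if (nrow(enc) == 0) {
      return(tibble::tibble())
    }
    grid <- tidyr::crossing(
      dplyr::select(enc, encounter_id, patient_id, facility_id, service, duration_min),
      tmpl
    ) |>
      dplyr::mutate(
        step_id = paste0(svc, "_S", order),
        minutes = duration_min * fraction
      )
    dplyr::bind_rows(
      dplyr::transmute(
        grid, encounter_id, patient_id, facility_id, service, step_id,
        resource_id = paste0(facility_id, "_", cadre),
        observed_minutes = minutes, item_id = NA_character_, quantity = NA_real_
      ),
      dplyr::transmute(
        grid, encounter_id, patient_id, facility_id, service, step_id,
        resource_id = paste0(facility_id, "_room"),
        observed_minutes = minutes, item_id = NA_character_, quantity = NA_real_
      )
    )
  })

  # consumables at the final step; facility-level multiplier on non-fixed
  # quantities
  cv <- config$consumable_facility_cv
  fac_factor <- tidyr::crossing(
    facility_id = facilities$facility_id, service = service_lines()
  ) |>
    dplyr::mutate(factor = if (cv > 0) {
      stats::rgamma(dplyr::n(), shape = 1 / cv^2, scale = cv^2)
    } else {
      1
    })

  cons_rows <- purrr::map_dfr(service_lines(), function(svc) {
    enc <- encounters[encounters$service == svc, ]
    plan <- config$consumable_plan[config$consumable_plan$service == svc, ]
    if (nrow(enc) == 0 || nrow(plan) == 0) {
      return(tibble::tibble())
    }
    last_step <- paste0(svc, "_S", max(templates[[svc]]$order))
    ff <- fac_factor$factor[match(
      paste(enc$facility_id, svc),
      paste(fac_factor$facility_id, fac_factor$service)
    )]
    purrr::map_dfr(seq_len(nrow(plan)), function(j) {
      qty <- switch(plan$qty_model[j],
        fixed = rep(plan$qty_base[j], nrow(enc)),
        one_plus_pois = 1 + stats::rpois(nrow(enc), plan$qty_base[j] * ff),
        pois = stats::rpois(nrow(enc), plan$qty_base[j] * ff),
        stop_invalid_parameter(paste0("Unknown qty_model: ", plan$qty_model[j]))
      )
      tibble::tibble(
        encounter_id = enc$encounter_id,
        patient_id = enc$patient_id,
        facility_id = enc$facility_id,
        service = svc,
        step_id = last_step,
        resource_id = NA_character_,
        observed_minutes = NA_real_,
        item_id = plan$item_id[j],
        quantity = qty
      ) |>
        dplyr::filter(quantity > 0)
    })
  })

  observations <- dplyr::bind_rows(step_rows, cons_rows) |>
    dplyr::arrange(encounter_id, step_id, resource_id, item_id)

  prices <- config$consumable_plan |>
    dplyr::distinct(item_id, name, kind, unit_price_tzs) |>
    dplyr::arrange(item_id)

  list(observations = observations, prices = prices, encounters = encounters)
}

#' Simulate a complete study
#'
#' Runs the three component simulators in sequence (facilities, patients,
#' encounters) under seeds derived from `config$seed`, and assembles the
#' ground-truth record: true duration coefficients, the implied
#' cost-model coefficients (duration effects times the combined direct
#' cost rate, plus expected consumable offsets on the service terms for
#' the with-consumables outcome), expected consumable means, and the
#' latent wealth draws. Ground truth is bundled separately from the
#' analysis inputs and is never read by any analysis stage.
#'
#' @param config A [sim_config()].
#' @return List of class `tdabc_study`: `facilities`, `resources`,
#'   `equipment`, `process_maps`, `indirect_pools`, `prices`, `patients`,
#'   `observations`, `encounters`, `ground_truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  fac <- simulate_facilities(config)
  pat <- simulate_patients(config, fac$facilities)
  enc <- simulate_encounters(config, fac$facilities, pat$patients)

  # size indirect pools on the realized workload: support-staff overhead
  # scales with clinical activity, so every facility runs at the nominal
  # overhead rate per direct staff minute
  realized <- enc$encounters |>
    dplyr::group_by(facility_id) |>
    dplyr::summarise(window_minutes = sum(duration_min), .groups = "drop")
  fac$indirect_pools <- fac$indirect_pools |>
    dplyr::left_join(realized, by = "facility_id") |>
    dplyr::mutate(
      annual_indirect_cost_tzs = config$indirect_rate_tzs_per_min *
        dplyr::coalesce(window_minutes, 0) * 365 /
        config$observation_window_days
    ) |>
    dplyr::select(facility_id, annual_indirect_cost_tzs)

  rho <- direct_rate_usd_per_min(config)
  dur_beta <- config$effects
  cost_no_beta <- dur_beta * rho
  cons_usd <- vapply(
    service_lines(),
    function(s) expected_consumables_tzs(config, s) / config$usd_rate,
    numeric(1)
  )
  cost_with_beta <- cost_no_beta
  cost_with_beta[["intercept"]] <- cost_with_beta[["intercept"]] + cons_usd[["HTC"]]
  svc_terms <- c(
    ART_STABLE = "svc_art_stable", ART_UNSTABLE = "svc_art_unstable",
    PMTCT = "svc_pmtct", PREP = "svc_prep", VMMC = "svc_vmmc"
  )
  for (svc in names(svc_terms)) {
    cost_with_beta[[svc_terms[[svc]]]] <-
      cost_with_beta[[svc_terms[[svc]]]] + cons_usd[[svc]] - cons_usd[["HTC"]]
  }

  ground_truth <- list(
    seed = config$seed,
    direct_rate_usd_per_min = rho,
    effects = list(
      duration_minutes = as.list(dur_beta),
      cost_no_consumables_usd = as.list(cost_no_beta),
      cost_with_consumables_usd = as.list(cost_with_beta)
    ),
    expected_consumables_usd = as.list(cons_usd),
    duration_noise_sd = config$duration_noise_sd,
    latent_wealth = pat$latent_wealth
  )

  out <- list(
    facilities = fac$facilities,
    resources = fac$resources,
    equipment = fac$equipment,
    process_maps = fac$process_maps,
    indirect_pools = fac$indirect_pools,
    prices = enc$prices,
    patients = pat$patients,
    observations = enc$observations,
    encounters = enc$encounters,
    ground_truth = ground_truth,
    config = config
  )
  class(out) <- "tdabc_study"
  out
}

#' Cost a simulated study with its own configuration
#'
#' Convenience wrapper running [cost_encounters()] on a simulated study
#' with the study's currency rate and observation window.
#'
#' @param study A `tdabc_study` from [simulate_study()].
#' @param allocation_basis See [cost_encounters()].
#' @return Encounter-cost tibble.
#' @export
cost_study <- function(study, allocation_basis = "staff_minutes") {
  cost_encounters(
    study$observations, study$resources, study$prices,
    indirect_pools = study$indirect_pools,
    usd_rate = study$config$usd_rate,
    allocation_basis = allocation_basis,
    period_days = study$config$observation_window_days
  )
}

#' Write a simulated study to CSV inputs
#'
#' Writes the full CSV input set consumed by the costing, descriptive and
#' equity stages (`facilities.csv`, `resources.csv`, `equipment.csv`,
#' `process_maps.csv`, `prices.csv`, `patients.csv`, `observations.csv`,
#' `indirect_pools.csv`) plus `ground_truth.json`, which no analysis stage
#' reads.
#'
#' @param study A `tdabc_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c(
    "facilities", "resources", "equipment", "process_maps", "prices",
    "patients", "observations", "indirect_pools"
  )
  paths <- character(0)
  for (tb in tables) {
    p <- file.path(dir, paste0(tb, ".csv"))
    readr::write_csv(study[[tb]], p)
    paths[tb] <- p
  }
  gt <- study$ground_truth
  gt$latent_wealth <- NULL
  gt$latent_wealth_by_patient <- as.list(setNames(
    study$ground_truth$latent_wealth$latent_wealth,
    study$ground_truth$latent_wealth$patient_id
  ))
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, p, auto_unbox = TRUE, digits = NA)
  paths["ground_truth"] <- p
  invisible(paths)
}

#' Read study CSV inputs
#'
#' Reads the CSV bundle written by [write_study()] (or prepared by hand in
#' the same schema). `ground_truth.json` is never read here.
#'
#' @param dir Directory containing the CSV inputs.
#' @return List of tibbles named like the files.
#' @export
read_study <- function(dir) {
  spec <- list(
    facilities = readr::cols(.default = readr::col_character()),
    resources = readr::cols(
      facility_id = readr::col_character(),
      resource_id = readr::col_character(),
      name = readr::col_character(),
      category = readr::col_character(),
      annual_cost_tzs = readr::col_double(),
      practical_capacity_min = readr::col_double()
    ),
    equipment = readr::cols(
      facility_id = readr::col_character(),
      item = readr::col_character(),
      purchase_cost_tzs = readr::col_double(),
      useful_life_years = readr::col_double()
    ),
    process_maps = readr::cols(
      facility_id = readr::col_character(),
      service = readr::col_character(),
      step_id = readr::col_character(),
      order = readr::col_integer(),
      location = readr::col_character(),
      resource_id = readr::col_character(),
      default_minutes = readr::col_double(),
      frequency = readr::col_double()
    ),
    prices = readr::cols(
      item_id = readr::col_character(),
      name = readr::col_character(),
      kind = readr::col_character(),
      unit_price_tzs = readr::col_double()
    ),
    patients = readr::cols(
      patient_id = readr::col_character(),
      facility_id = readr::col_character(),
      service = readr::col_character(),
      gender = readr::col_character(),
      age = readr::col_double(),
      married = readr::col_logical(),
      education_years = readr::col_double(),
      comorbidity = readr::col_logical(),
      .default = readr::col_double()
    ),
    observations = readr::cols(
      encounter_id = readr::col_character(),
      patient_id = readr::col_character(),
      facility_id = readr::col_character(),
      service = readr::col_character(),
      step_id = readr::col_character(),
      resource_id = readr::col_character(),
      observed_minutes = readr::col_double(),
      item_id = readr::col_character(),
      quantity = readr::col_double()
    ),
    indirect_pools = readr::cols(
      facility_id = readr::col_character(),
      annual_indirect_cost_tzs = readr::col_double()
    )
  )
  out <- list()
  for (tb in names(spec)) {
    p <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(p)) {
      abort_tdabc(paste0("Input file not found: ", p), "tdabcost_io")
    }
    out[[tb]] <- readr::read_csv(p, col_types = spec[[tb]], progress = FALSE)
  }
  out
}
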