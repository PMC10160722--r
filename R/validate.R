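#' Validate study CSV inputs
#'
#' Schema and referential-integrity checks over a study input directory:
#' required files and columns, enum vocabularies (service lines, cost
#' categories, consumable kinds, facility strata), numeric sign
#' constraints, and cross-file references (observations to resources,
#' prices, patients and facilities; patients to facilities). Every
#' violation is reported with file, row number, field and value.
#'
#' @param dir Directory containing the study CSV inputs (see
#'   [write_study()] for the schema).
#' @return Tibble of violations (`file`, `row`, `field`, `value`, `rule`);
#'   zero rows means the bundle is valid.
#' @export
validate_inputs <- function(dir) {
  violations <- list()
  note <- function(file, row, field, value, rule) {
    violations[[length(violations) + 1]] <<- tibble::tibble(
      file = file, row = as.integer(row), field = field,
      value = as.character(value), rule = rule
    )
  }

  required <- list(
    facilities = c(
      "facility_id", "region", "facility_type", "rurality", "funder",
      "volume_tier"
    ),
    resources = c(
      "facility_id", "resource_id", "category", "annual_cost_tzs",
      "practical_capacity_min"
    ),
    equipment = c("facility_id", "item", "purchase_cost_tzs", "useful_life_years"),
    process_maps = c(
      "facility_id", "service", "step_id", "order", "resource_id",
      "default_minutes", "frequency"
    ),
    prices = c("item_id", "kind", "unit_price_tzs"),
    patients = c(
      "patient_id", "facility_id", "service", "gender", "age", "married",
      "education_years", "comorbidity"
    ),
    observations = c(
      "encounter_id", "patient_id", "facility_id", "service", "resource_id",
      "observed_minutes", "item_id", "quantity"
    ),
    indirect_pools = c("facility_id", "annual_indirect_cost_tzs")
  )

  tabs <- list()
  for (tb in names(required)) {
    p <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(p)) {
      note(paste0(tb, ".csv"), NA, NA_character_, NA_character_, "missing_file")
      next
    }
    dat <- tryCatch(
      suppressWarnings(readr::read_csv(p,
        col_types = readr::cols(.default = readr::col_guess()),
        progress = FALSE, show_col_types = FALSE
      )),
      error = function(e) NULL
    )
    if (is.null(dat)) {
      note(paste0(tb, ".csv"), NA, NA_character_, NA_character_, "unreadable_file")
      next
    }
    for (col in setdiff(required[[tb]], names(dat))) {
      note(paste0(tb, ".csv"), NA, col, NA_character_, "missing_column")
    }
    tabs[[tb]] <- dat
  }

  check_enum <- function(tb, field, allowed, allow_na = FALSE) {
    dat <- tabs[[tb]]
    if (is.null(dat) || !field %in% names(dat)) {
      return()
    }
    vals <- as.character(dat[[field]])
    bad <- which(!(vals %in% allowed) & !(allow_na & is.na(vals)))
    for (i in bad) note(paste0(tb, ".csv"), i, field, vals[i], "invalid_enum")
  }
  check_nonneg <- function(tb, field, strict = FALSE, allow_na = FALSE) {
    dat <- tabs[[tb]]
    if (is.null(dat) || !field %in% names(dat)) {
      return()
    }
    vals <- suppressWarnings(as.numeric(dat[[field]]))
    bad <- which(
      (is.na(vals) & !(allow_na & is.na(dat[[field]]))) |
        (!is.na(vals) & (if (strict) vals <= 0 else vals < 0))
    )
    for (i in bad) {
      note(
        paste0(tb, ".csv"), i, field, dat[[field]][i],
        if (strict) "not_positive" else "negative_value"
      )
    }
  }
  check_ref <- function(tb, field, parent_tb, parent_field, allow_na = FALSE) {
    dat <- tabs[[tb]]
    parent <- tabs[[parent_tb]]
    if (is.null(dat) || is.null(parent) ||
      !field %in% names(dat) || !parent_field %in% names(parent)) {
      return()
    }
    vals <- as.character(dat[[field]])
    known <- as.character(parent[[parent_field]])
    bad <- which(!(vals %in% known) & !(allow_na & is.na(vals)))
    for (i in bad) {
      note(paste0(tb, ".csv"), i, field, vals[i], "unknown_reference")
    }
  }

  f <- equity_factors()
  check_enum("facilities", "region", f$region$levels)
  check_enum("facilities", "facility_type", f$facility_type$levels)
  check_enum("facilities", "rurality", f$rurality$levels)
  check_enum("facilities", "funder", f$funder$levels)
  check_enum("facilities", "volume_tier", f$volume_tier$levels)
  check_enum("resources", "category", c("HUMAN_RESOURCES", "SPACE_EQUIPMENT"))
  check_enum("prices", "kind", c("MEDICATION", "LAB", "SUPPLY"))
  check_enum("patients", "service", service_lines())
  check_enum("patients", "gender", c("FEMALE", "MALE"))
  check_enum("observations", "service", service_lines())
  check_enum("process_maps", "service", service_lines())

  check_nonneg("resources", "annual_cost_tzs")
  check_nonneg("resources", "practical_capacity_min", strict = TRUE)
  check_nonneg("equipment", "purchase_cost_tzs")
  check_nonneg("equipment", "useful_life_years", strict = TRUE)
  check_nonneg("prices", "unit_price_tzs")
  check_nonneg("observations", "observed_minutes", allow_na = TRUE)
  check_nonneg("observations", "quantity", allow_na = TRUE)
  check_nonneg("indirect_pools", "annual_indirect_cost_tzs")

  check_ref("resources", "facility_id", "facilities", "facility_id")
  check_ref("patients", "facility_id", "facilities", "facility_id")
  check_ref("observations", "facility_id", "facilities", "facility_id")
  check_ref("observations", "patient_id", "patients", "patient_id")
  check_ref("observations", "resource_id", "resources", "resource_id", allow_na = TRUE)
  check_ref("observations", "item_id", "prices", "item_id", allow_na = TRUE)
  check_ref("process_maps", "resource_id", "resources", "resource_id")
  check_ref("indirect_pools", "facility_id", "facilities", "facility_id")

  if (length(violations) == 0) {
    tibble::tibble(
      file = character(0), row = integer(0), field = character(0),
      value = character(0), rule = character(0)
    )
  } else {
    dplyr::bind_rows(violations)
  }
}
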