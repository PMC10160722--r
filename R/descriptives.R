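#' Percentage share of a cost category
#'
#' The share of a service line's mean total cost attributable to one cost
#' category, reported half-up to one decimal as in printed cost tables.
#'
#' @param category_mean Mean cost of the category.
#' @param total_mean Mean total cost, `> 0`.
#' @return Percentage (0-100 scale), rounded half-up to 1 decimal.
#' @examples
#' pct_share(0.82, 3.67) # 22.3
#' @export
pct_share <- function(category_mean, total_mean) {
  if (any(!is.finite(total_mean)) || any(total_mean <= 0)) {
    abort_tdabc(
      "`total_mean` must be > 0: the share of a zero total is undefined.",
      "tdabcost_undefined_share"
    )
  }
  round_half_up(100 * category_mean / total_mean, 1)
}

#' Interquartile range across facilities
#'
#' 25th and 75th percentiles of a set of facility-level values, using linear
#' interpolation between order statistics (the common scientific-computing
#' default; [stats::quantile()] type 7).
#'
#' @param values Numeric vector (typically one mean per facility), length >= 1.
#' @return Named numeric vector `c(q25 = , q75 = )`.
#' @examples
#' facility_iqr(c(1, 2, 3, 4)) # 1.75, 3.25
#' @export
facility_iqr <- function(values) {
  if (length(values) < 1 || any(!is.finite(values))) {
    stop_invalid_input("`values` must be a non-empty vector of finite numbers.")
  }
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = 7, names = FALSE)
  c(q25 = q[1], q75 = q[2])
}

#' Summarize service-line costs per visit and across-facility variation
#'
#' Produces, per service line, the mean and sample SD of each cost category
#' and of the total, the category's percentage share of total mean cost,
#' and the interquartile range across facility-level mean costs. For ART
#' service lines the summary is annualized by default (4 quarterly / 12
#' monthly visits per year); shares are unaffected by annualization.
#'
#' The IQR is computed across facility means (one value per facility)
#' because it summarizes between-facility variation; set
#' `iqr_by = "encounter"` for the encounter-level alternative. When a
#' category is constant across facilities (e.g. a standardized consumable
#' bundle), its IQR is flagged not applicable (`iqr_applicable = FALSE`,
#' quantiles `NA`).
#'
#' @param encounter_costs Output of [cost_encounters()].
#' @param services Service lines expected in the summary; lines with no
#'   encounters are omitted with a warning. Defaults to the lines present.
#' @param annualize Multiply costs by the service line's visits/year
#'   (default `TRUE`, matching printed cost tables).
#' @param iqr_by `"facility"` (default) or `"encounter"`.
#' @param constant_tol Absolute tolerance below which facility means are
#'   considered constant (default 1e-9).
#' @return Tibble with columns `service`, `category` (`"TOTAL"` plus the
#'   four categories), `mean_usd`, `sd_usd`, `pct_of_total`, `q25_usd`,
#'   `q75_usd`, `iqr_applicable`.
#' @export
summarize_service_costs <- function(encounter_costs,
                                    services = NULL,
                                    annualize = TRUE,
                                    iqr_by = c("facility", "encounter"),
                                    constant_tol = 1e-9) {
  iqr_by <- match.arg(iqr_by)
  costs <- tibble::as_tibble(encounter_costs)
  services <- services %||% intersect(service_lines(), unique(costs$service))
  assert_service(services)

  empty <- setdiff(services, unique(costs$service))
  if (length(empty) > 0) {
    rlang::warn(
      paste0(
        "Service line(s) with no encounters omitted from summary: ",
        paste(empty, collapse = ", ")
      ),
      class = "tdabcost_empty_service"
    )
    services <- setdiff(services, empty)
  }

  cat_cols <- c(
    HUMAN_RESOURCES = "human_resources_usd",
    SPACE_EQUIPMENT = "space_equipment_usd",
    INDIRECTS = "indirects_usd",
    CONSUMABLES = "consumables_usd",
    TOTAL = "total_per_visit_usd"
  )

  purrr::map_dfr(services, function(svc) {
    rows <- dplyr::filter(costs, service == svc)
    mult <- if (annualize) visits_per_year(svc) else 1L
    total_mean <- mean(rows$total_per_visit_usd) * mult
    purrr::map_dfr(names(cat_cols), function(cat) {
      x <- rows[[cat_cols[[cat]]]] * mult
      fac_means <- if (iqr_by == "facility") {
        tapply(x, rows$facility_id, mean)
      } else {
        x
      }
      applicable <- (max(fac_means) - min(fac_means)) > constant_tol ||
        length(fac_means) == 1
      q <- if (applicable) facility_iqr(as.numeric(fac_means)) else c(q25 = NA_real_, q75 = NA_real_)
      tibble::tibble(
        service = svc,
        category = cat,
        mean_usd = mean(x),
        sd_usd = stats::sd(x),
        pct_of_total = pct_share(mean(x), total_mean),
        q25_usd = q[["q25"]],
        q75_usd = q[["q75"]],
        iqr_applicable = applicable
      )
    })
  })
}

#' Summarize cohort characteristics by service line
#'
#' Counts and summary statistics of exit-interview covariates per service
#' line plus a total row: sample size, female count and percent, mean (SD)
#' age, married count and percent, mean (SD) years of education, and
#' comorbid-condition count and percent. Percents are reported as integers
#' and means/SDs to one decimal (half-up), matching printed cohort tables.
#'
#' @param patients Tibble with columns `service`, `gender` (`"FEMALE"` /
#'   `"MALE"`), `age`, `married` (logical/0-1), `education_years`,
#'   `comorbidity` (logical/0-1).
#' @return Tibble with one row per service line present plus a `"TOTAL"` row.
#' @export
summarize_cohort <- function(patients) {
  patients <- tibble::as_tibble(patients)
  if (nrow(patients) == 0) {
    return(tibble::tibble(
      service = "TOTAL", n = 0L, n_female = 0L, pct_female = 0,
      age_mean = NA_real_, age_sd = NA_real_,
      n_married = 0L, pct_married = 0,
      edu_mean = NA_real_, edu_sd = NA_real_,
      n_comorbid = 0L, pct_comorbid = 0
    ))
  }
  assert_service(patients$service)
  one <- function(rows, label) {
    n <- nrow(rows)
    pct <- function(k) round_half_up(100 * k / n, 0)
    tibble::tibble(
      service = label,
      n = n,
      n_female = sum(rows$gender == "FEMALE"),
      pct_female = pct(sum(rows$gender == "FEMALE")),
      age_mean = round_half_up(mean(rows$age), 1),
      age_sd = round_half_up(stats::sd(rows$age), 1),
      n_married = sum(as.logical(rows$married)),
      pct_married = pct(sum(as.logical(rows$married))),
      edu_mean = round_half_up(mean(rows$education_years), 1),
      edu_sd = round_half_up(stats::sd(rows$education_years), 1),
      n_comorbid = sum(as.logical(rows$comorbidity)),
      pct_comorbid = pct(sum(as.logical(rows$comorbidity)))
    )
  }
  lines <- intersect(service_lines(), unique(patients$service))
  per_line <- purrr::map_dfr(lines, function(svc) {
    one(dplyr::filter(patients, service == svc), svc)
  })
  dplyr::bind_rows(per_line, one(patients, "TOTAL"))
}
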