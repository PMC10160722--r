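#' Service lines and cost categories
#'
#' The six HIV service lines covered by the costing model. Antiretroviral
#' therapy is split by viral-suppression status because the two groups follow
#' different visit schedules: stable (suppressed) clients attend quarterly,
#' unstable clients monthly. All other services are one-time encounters.
#'
#' @return `service_lines()` returns the six service codes;
#'   `cost_categories()` the four cost categories that partition every
#'   encounter's total cost.
#' @examples
#' service_lines()
#' cost_categories()
#' @export
service_lines <- function() {
  c("ART_STABLE", "ART_UNSTABLE", "HTC", "PMTCT", "PREP", "VMMC")
}

#' @rdname service_lines
#' @export
cost_categories <- function() {
  c("HUMAN_RESOURCES", "SPACE_EQUIPMENT", "INDIRECTS", "CONSUMABLES")
}

#' Annual visit frequency of a service line
#'
#' Stable ART clients are seen once per quarter (4 visits/year), unstable ART
#' clients once per month (12 visits/year); all other service lines are
#' interpreted as one-time encounters.
#'
#' @param service Character vector of service codes (see [service_lines()]).
#' @return Integer vector of visits per year.
#' @examples
#' visits_per_year("ART_STABLE") # 4
#' visits_per_year(c("HTC", "ART_UNSTABLE")) # 1 12
#' @export
visits_per_year <- function(service) {
  assert_service(service)
  freq <- c(
    ART_STABLE = 4L, ART_UNSTABLE = 12L, HTC = 1L,
    PMTCT = 1L, PREP = 1L, VMMC = 1L
  )
  unname(freq[service])
}

assert_service <- function(service) {
  bad <- setdiff(unique(service), service_lines())
  if (length(bad) > 0) {
    stop_invalid_input(paste0(
      "Unknown service line code(s): ", paste(bad, collapse = ", "),
      ". Known codes: ", paste(service_lines(), collapse = ", ")
    ))
  }
  invisible(service)
}
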