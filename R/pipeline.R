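#' Run the full costing and equity pipeline on a study input directory
#'
#' Validates the CSV bundle, costs every encounter, produces the
#' service-line cost and cohort summaries, builds the asset index, fits
#' the three equity models, and writes all outputs
#' (`encounter_costs.csv`, `service_cost_summary.csv`,
#' `cohort_summary.csv`, `asset_index.csv`, `equity_models.csv`,
#' `report.md`, `run_log.csv`) to `output_dir`. Outputs are staged in a
#' temporary directory and moved only when every stage has succeeded, so
#' a failing run leaves no partial outputs. Re-running on unchanged
#' inputs produces identical files.
#'
#' @param input_dir Directory with the study CSV inputs (see
#'   [write_study()]).
#' @param output_dir Directory for outputs (created if needed).
#' @param usd_rate TZS per USD (default 2300).
#' @param period_days Observation window length used to prorate annual
#'   indirect pools (default 45 days).
#' @param allocation_basis Indirect allocation basis (see
#'   [allocate_indirects()]).
#' @param se_type `"classical"` or `"cluster"` standard errors for the
#'   equity models.
#' @param annualize Annualize service-line summaries (default `TRUE`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the computed objects (`costs`,
#'   `service_summary`, `cohort`, `asset_index`, `equity`), the run log,
#'   and output file paths.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         usd_rate = 2300, period_days = 45,
                         allocation_basis = "staff_minutes",
                         se_type = "classical",
                         annualize = TRUE, quiet = FALSE) {
  log_rows <- list()
  t0 <- Sys.time()
  log_stage <- function(stage, rows_in, rows_out, note = "") {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage,
      rows_in = as.integer(rows_in), rows_out = as.integer(rows_out),
      note = note,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    )
    if (!quiet) message("[", stage, "] in=", rows_in, " out=", rows_out, " ", note)
  }

  report <- validate_inputs(input_dir)
  if (nrow(report) > 0) {
    abort_tdabc(
      paste0(
        "Input validation failed with ", nrow(report), " violation(s); ",
        "first: ", report$file[1], " row ", report$row[1], " field ",
        report$field[1], " (", report$rule[1], ")"
      ),
      "tdabcost_validation", report = report
    )
  }
  study <- read_study(input_dir)
  log_stage("validate", nrow(study$observations), nrow(study$observations), "0 violations")

  costs <- cost_encounters(
    study$observations, study$resources, study$prices,
    indirect_pools = study$indirect_pools,
    usd_rate = usd_rate, allocation_basis = allocation_basis,
    period_days = period_days
  )
  log_stage("cost", nrow(study$observations), nrow(costs))

  service_summary <- summarize_service_costs(costs, annualize = annualize)
  cohort <- summarize_cohort(study$patients)
  log_stage("summarize", nrow(costs), nrow(service_summary))

  asset_cols <- grep("^asset_", names(study$patients), value = TRUE)
  asset_index <- build_asset_index(
    study$patients[asset_cols],
    ids = study$patients$patient_id
  )
  equity <- run_equity_models(
    costs, study$patients, study$facilities,
    se_type = se_type, quiet = quiet
  )
  log_stage(
    "equity", nrow(costs), equity$n,
    paste0(equity$n_excluded, " excluded for missing covariates")
  )

  stage_dir <- tempfile("tdabcost_out_")
  dir.create(stage_dir)
  readr::write_csv(costs, file.path(stage_dir, "encounter_costs.csv"))
  readr::write_csv(service_summary, file.path(stage_dir, "service_cost_summary.csv"))
  readr::write_csv(cohort, file.path(stage_dir, "cohort_summary.csv"))
  readr::write_csv(asset_index, file.path(stage_dir, "asset_index.csv"))
  readr::write_csv(equity_model_table(equity), file.path(stage_dir, "equity_models.csv"))
  writeLines(
    render_report(service_summary, cohort, equity),
    file.path(stage_dir, "report.md")
  )
  run_log <- dplyr::bind_rows(log_rows)
  readr::write_csv(run_log, file.path(stage_dir, "run_log.csv"))

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  staged <- list.files(stage_dir, full.names = TRUE)
  ok <- file.copy(staged, output_dir, overwrite = TRUE)
  if (!all(ok)) abort_tdabc("Failed to move staged outputs into place.", "tdabcost_io")
  unlink(stage_dir, recursive = TRUE)

  invisible(list(
    costs = costs, service_summary = service_summary, cohort = cohort,
    asset_index = asset_index, equity = equity, log = run_log,
    outputs = file.path(output_dir, basename(staged))
  ))
}

# plain-text/markdown report assembly --------------------------------------

md_table <- function(df, digits = 2) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.na(x), "na", formatC(x, digits = digits, format = "f"))
    } else {
      ifelse(is.na(x), "na", as.character(x))
    }
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

render_report <- function(service_summary, cohort, equity) {
  out <- c(
    "# TDABC costing and equity report", "",
    "## Cohort by service line", "",
    md_table(cohort, digits = 1), "",
    "## Service-line costs per visit (ART annualized)", "",
    md_table(service_summary, digits = 2), ""
  )
  for (nm in names(equity$models)) {
    m <- equity$models[[nm]]
    out <- c(
      out,
      paste0(
        "## Model: ", nm, " (n = ", m$n, ", R-squared = ",
        formatC(m$r_squared, digits = 3, format = "f"), ")"
      ), "",
      md_table(m$coefficients, digits = 3), ""
    )
  }
  out
}
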