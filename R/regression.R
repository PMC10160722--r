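# Covariate vocabulary for the equity models.
#
# Reference levels: age 18-30, unmarried, 0-1 years of education, no
# comorbidity, HTC service, Dar es Salaam region, dispensary, urban,
# government funding, high HIV client volume. The asset index enters as a
# continuous score.
equity_factors <- function() {
  list(
    gender = list(
      levels = c("FEMALE", "MALE"), ref = "FEMALE",
      terms = c(MALE = "male")
    ),
    age_group = list(
      levels = c("18-30", "31-50", "51-70", "71+"), ref = "18-30",
      terms = c(`31-50` = "age_31_50", `51-70` = "age_51_70", `71+` = "age_71_plus")
    ),
    education_level = list(
      levels = c("0-1", "2-3", "4-5", "6+"), ref = "0-1",
      terms = c(`2-3` = "edu_2_3", `4-5` = "edu_4_5", `6+` = "edu_6_plus")
    ),
    service = list(
      levels = c("HTC", "ART_STABLE", "ART_UNSTABLE", "PMTCT", "PREP", "VMMC"),
      ref = "HTC",
      terms = c(
        ART_STABLE = "svc_art_stable", ART_UNSTABLE = "svc_art_unstable",
        PMTCT = "svc_pmtct", PREP = "svc_prep", VMMC = "svc_vmmc"
      )
    ),
    region = list(
      levels = c(
        "DAR_ES_SALAAM", "DODOMA", "KAGERA", "MBEYA", "MWANZA", "NJOMBE",
        "TABORA"
      ),
      ref = "DAR_ES_SALAAM",
      terms = c(
        DODOMA = "region_dodoma", KAGERA = "region_kagera",
        MBEYA = "region_mbeya", MWANZA = "region_mwanza",
        NJOMBE = "region_njombe", TABORA = "region_tabora"
      )
    ),
    facility_type = list(
      levels = c("DISPENSARY", "HEALTH_CENTRE", "HOSPITAL"), ref = "DISPENSARY",
      terms = c(HEALTH_CENTRE = "type_health_centre", HOSPITAL = "type_hospital")
    ),
    rurality = list(
      levels = c("URBAN", "RURAL"), ref = "URBAN",
      terms = c(RURAL = "rural")
    ),
    funder = list(
      levels = c("GOT", "PEPFAR"), ref = "GOT",
      terms = c(PEPFAR = "pepfar")
    ),
    volume_tier = list(
      levels = c("HIGH", "LOW", "MEDIUM"), ref = "HIGH",
      terms = c(LOW = "volume_low", MEDIUM = "volume_medium")
    )
  )
}

#' Design-matrix term names for the equity models
#'
#' Deterministic column order of the full design matrix: intercept, patient
#' dummies and the continuous asset index, service-line dummies (reference
#' HTC), then facility fixed effects (region, type, rurality, funder,
#' volume tier).
#'
#' @return Character vector of term (column) names.
#' @export
design_term_names <- function() {
  f <- equity_factors()
  c(
    "intercept",
    unname(f$gender$terms),
    unname(f$age_group$terms),
    "married",
    unname(f$education_level$terms),
    "comorbidity",
    "asset_index",
    unname(f$service$terms),
    unname(f$region$terms),
    unname(f$facility_type$terms),
    unname(f$rurality$terms),
    unname(f$funder$terms),
    unname(f$volume_tier$terms)
  )
}

#' Patient-level term names
#'
#' The subset of [design_term_names()] describing patient (as opposed to
#' service-line or facility) characteristics, used e.g. in type-I-error
#' simulations where all patient effects are set to zero.
#'
#' @return Character vector.
#' @export
patient_terms <- function() {
  f <- equity_factors()
  c(
    unname(f$gender$terms), unname(f$age_group$terms), "married",
    unname(f$education_level$terms), "comorbidity", "asset_index"
  )
}

#' Assemble the model frame for the equity models
#'
#' Joins costed encounters to patient exit-interview covariates and
#' facility characteristics, derives age group and education level from the
#' recorded values, computes the PCA asset index from the `asset_*`
#' indicator columns (see [build_asset_index()]), and attaches the three
#' outcomes: provider-patient contact minutes, visit cost without
#' consumables, and visit cost with consumables. Rows with missing
#' covariates are dropped listwise; the number dropped is recorded in the
#' `n_excluded` attribute and reported via a message.
#'
#' @param encounter_costs Output of [cost_encounters()].
#' @param patients Patient covariates including `patient_id`, `gender`,
#'   `age`, `married`, `education_years`, `comorbidity` and `asset_*`
#'   indicator columns.
#' @param facilities Facility covariates: `facility_id`, `region`,
#'   `facility_type`, `rurality`, `funder`, `volume_tier`.
#' @param quiet Suppress the exclusion message.
#' @return Tibble with covariates and outcome columns `duration_minutes`,
#'   `cost_no_consumables_usd`, `cost_with_consumables_usd`; attribute
#'   `n_excluded`.
#' @export
build_model_frame <- function(encounter_costs, patients, facilities, quiet = FALSE) {
  patients <- tibble::as_tibble(patients)
  asset_cols <- grep("^asset_", names(patients), value = TRUE)
  if (length(asset_cols) < 2) {
    stop_invalid_input("`patients` must contain at least two `asset_*` indicator columns.")
  }
  idx <- build_asset_index(patients[asset_cols], ids = patients$patient_id)
  pat <- patients |>
    dplyr::left_join(dplyr::rename(idx, asset_index = "score"), by = "patient_id") |>
    dplyr::mutate(
      age_group = cut(age,
        breaks = c(-Inf, 30, 50, 70, Inf),
        labels = c("18-30", "31-50", "51-70", "71+"), right = TRUE
      ),
      age_group = as.character(age_group),
      education_level = cut(education_years,
        breaks = c(-Inf, 1, 3, 5, Inf),
        labels = c("0-1", "2-3", "4-5", "6+"), right = TRUE
      ),
      education_level = as.character(education_level)
    ) |>
    dplyr::select(
      patient_id, gender, age_group, married, education_level, comorbidity,
      asset_index
    )

  frame <- tibble::as_tibble(encounter_costs) |>
    dplyr::mutate(
      duration_minutes = provider_minutes,
      cost_no_consumables_usd = human_resources_usd + space_equipment_usd +
        indirects_usd,
      cost_with_consumables_usd = total_per_visit_usd
    ) |>
    dplyr::select(
      encounter_id, patient_id, facility_id, service,
      duration_minutes, cost_no_consumables_usd, cost_with_consumables_usd
    ) |>
    dplyr::left_join(pat, by = "patient_id") |>
    dplyr::left_join(
      dplyr::select(
        tibble::as_tibble(facilities),
        facility_id, region, facility_type, rurality, funder, volume_tier
      ),
      by = "facility_id"
    )

  need <- c(
    "gender", "age_group", "married", "education_level", "comorbidity",
    "asset_index", "service", "region", "facility_type", "rurality",
    "funder", "volume_tier", "duration_minutes"
  )
  ok <- stats::complete.cases(frame[need])
  n_excluded <- sum(!ok)
  if (n_excluded > 0 && !quiet) {
    message(n_excluded, " encounter(s) excluded due to missing covariate information.")
  }
  out <- frame[ok, ]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Encode the fixed-effects design matrix
#'
#' One-hot encodes each categorical covariate omitting its reference level,
#' enters the asset index as a continuous column, and prepends an intercept
#' column. Column order is deterministic (see [design_term_names()]).
#' Unknown factor levels raise a vocabulary error naming the field and
#' value. Dummy columns whose level never occurs in the data are dropped
#' with a classed warning (they would be identically zero); genuine linear
#' dependence among populated columns is reported by
#' [fit_fixed_effects_ols()] as a collinearity error.
#'
#' @param frame Model frame from [build_model_frame()] (or any tibble with
#'   the same covariate columns).
#' @param drop_empty Drop all-zero dummy columns with a warning (default
#'   `TRUE`).
#' @return Numeric matrix; attribute `dropped` lists any dropped terms.
#' @export
encode_design_matrix <- function(frame, drop_empty = TRUE) {
  frame <- tibble::as_tibble(frame)
  f <- equity_factors()
  fields <- c(
    gender = "gender", age_group = "age_group",
    education_level = "education_level", service = "service",
    region = "region", facility_type = "facility_type",
    rurality = "rurality", funder = "funder", volume_tier = "volume_tier"
  )
  for (fld in names(fields)) {
    vals <- frame[[fields[[fld]]]]
    bad <- setdiff(unique(as.character(vals)), f[[fld]]$levels)
    if (length(bad) > 0) {
      abort_tdabc(
        paste0(
          "Unknown level(s) for `", fields[[fld]], "`: ",
          paste(bad, collapse = ", ")
        ),
        "tdabcost_vocabulary"
      )
    }
  }
  n <- nrow(frame)
  cols <- list(intercept = rep(1, n))
  add_dummies <- function(cols, values, spec) {
    for (lev in names(spec$terms)) {
      cols[[spec$terms[[lev]]]] <- as.numeric(values == lev)
    }
    cols
  }
  cols <- add_dummies(cols, frame$gender, f$gender)
  cols <- add_dummies(cols, frame$age_group, f$age_group)
  cols$married <- as.numeric(as.logical(frame$married))
  cols <- add_dummies(cols, frame$education_level, f$education_level)
  cols$comorbidity <- as.numeric(as.logical(frame$comorbidity))
  cols$asset_index <- as.numeric(frame$asset_index)
  cols <- add_dummies(cols, frame$service, f$service)
  cols <- add_dummies(cols, frame$region, f$region)
  cols <- add_dummies(cols, frame$facility_type, f$facility_type)
  cols <- add_dummies(cols, frame$rurality, f$rurality)
  cols <- add_dummies(cols, frame$funder, f$funder)
  cols <- add_dummies(cols, frame$volume_tier, f$volume_tier)

  X <- do.call(cbind, cols[design_term_names()])
  colnames(X) <- design_term_names()
  dropped <- character(0)
  if (drop_empty && n > 0) {
    zero <- colnames(X)[colSums(X != 0) == 0]
    if (length(zero) > 0) {
      dropped <- zero
      rlang::warn(
        paste0(
          "Dropping design column(s) for level(s) absent from the data: ",
          paste(zero, collapse = ", ")
        ),
        class = "tdabcost_empty_level"
      )
      X <- X[, setdiff(colnames(X), zero), drop = FALSE]
    }
  }
  attr(X, "dropped") <- dropped
  X
}

#' Fit an ordinary least-squares model with fixed effects
#'
#' Fits y on a pre-built design matrix by OLS ([stats::lm()] under the
#' hood), returning estimates, standard errors, t-based confidence
#' intervals at the requested level, two-sided p-values, centered R-squared
#' and residual degrees of freedom (n minus rank). Standard errors are
#' classical (homoskedastic) by default; passing `cluster` switches to
#' cluster-robust standard errors (CR0/HC-type, via `sandwich::vcovCL`) for
#' sensitivity analysis.
#'
#' Rank-deficient design matrices are an error that names the linearly
#' dependent columns; columns are never silently dropped.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric design matrix with named columns (including an
#'   intercept column if one is wanted).
#' @param cluster Optional vector of cluster ids (e.g. facility) for
#'   cluster-robust standard errors.
#' @param conf_level Confidence level (default 0.95).
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05, two-tailed).
#' @return Object of class `tdabc_ols`: list with `coefficients` (tibble of
#'   term, estimate, se, ci_low, ci_high, p_value, significant),
#'   `r_squared`, `n`, `df_residual`, `se_type`.
#' @export
fit_fixed_effects_ols <- function(y, X, cluster = NULL, conf_level = 0.95,
                                  alpha = 0.05) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) {
    stop_invalid_input("`y` and `X` must have matching rows.")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort_tdabc(
      paste0(
        "Design matrix is rank deficient; linearly dependent column(s): ",
        paste(dep, collapse = ", ")
      ),
      "tdabcost_collinearity", columns = dep
    )
  }
  dat <- as.data.frame(X)
  dat$.y <- y
  fit <- stats::lm(.y ~ 0 + ., data = dat)
  vc <- if (is.null(cluster)) {
    stats::vcov(fit)
  } else {
    if (!requireNamespace("sandwich", quietly = TRUE)) {
      stop_invalid_parameter("Cluster-robust standard errors require the 'sandwich' package.")
    }
    sandwich::vcovCL(fit, cluster = factor(cluster))
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(vc))
  df_res <- length(y) - qrx$rank
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  out <- list(
    coefficients = tibble::tibble(
      term = colnames(X),
      estimate = unname(est),
      se = unname(se),
      ci_low = unname(est - tcrit * se),
      ci_high = unname(est + tcrit * se),
      p_value = unname(pval),
      significant = unname(pval < alpha)
    ),
    r_squared = r2,
    n = length(y),
    df_residual = df_res,
    se_type = if (is.null(cluster)) "classical" else "cluster",
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit))
  )
  class(out) <- "tdabc_ols"
  out
}

#' @export
print.tdabc_ols <- function(x, ...) {
  cat(
    "Fixed-effects OLS: n =", x$n, " R-squared =",
    formatC(x$r_squared, digits = 3, format = "f"),
    " SEs:", x$se_type, "\n"
  )
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Fit the three equity models
#'
#' Fits the three fixed-effects multivariable linear models on an identical
#' design matrix, one per outcome: provider-patient visit duration
#' (minutes), visit cost without consumables (USD) and visit cost with
#' consumables (USD). Covariates are the patient characteristics (gender,
#' age group, marital status, education level, comorbidity, asset index),
#' a service-line indicator (reference HTC), and facility fixed effects
#' (region, type, rurality, funder, volume tier). Inference uses a
#' two-tailed alpha of 0.05.
#'
#' @param encounter_costs Output of [cost_encounters()].
#' @param patients,facilities See [build_model_frame()].
#' @param se_type `"classical"` (default) or `"cluster"` (by facility).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param quiet Suppress the missing-covariate exclusion message.
#' @return Object of class `tdabc_equity`: list with `models` (named list
#'   of three `tdabc_ols` fits), `forest` (tidy table of term, estimate and
#'   CI per model, ready for forest plotting), `n`, `n_excluded`.
#' @export
run_equity_models <- function(encounter_costs, patients, facilities,
                              se_type = c("classical", "cluster"),
                              alpha = 0.05, quiet = FALSE) {
  se_type <- match.arg(se_type)
  frame <- build_model_frame(encounter_costs, patients, facilities, quiet = quiet)
  X <- encode_design_matrix(frame)
  cluster <- if (se_type == "cluster") frame$facility_id else NULL
  outcomes <- c(
    duration_minutes = "duration_minutes",
    cost_no_consumables_usd = "cost_no_consumables_usd",
    cost_with_consumables_usd = "cost_with_consumables_usd"
  )
  models <- purrr::map(outcomes, function(col) {
    fit_fixed_effects_ols(frame[[col]], X, cluster = cluster, alpha = alpha)
  })
  forest <- purrr::imap_dfr(models, function(m, nm) {
    dplyr::mutate(
      dplyr::select(m$coefficients, term, estimate, ci_low, ci_high),
      model = nm, .before = 1
    )
  })
  out <- list(
    models = models,
    forest = forest,
    n = nrow(frame),
    n_excluded = attr(frame, "n_excluded"),
    alpha = alpha,
    se_type = se_type
  )
  class(out) <- "tdabc_equity"
  out
}

#' @export
print.tdabc_equity <- function(x, ...) {
  cat(
    "Equity models (n =", x$n, ", ", x$n_excluded,
    "excluded for missing covariates):\n"
  )
  for (nm in names(x$models)) {
    cat(
      "  ", nm, ": R-squared =",
      formatC(x$models[[nm]]$r_squared, digits = 3, format = "f"), "\n"
    )
  }
  invisible(x)
}

#' Tidy coefficient table across the three equity models
#'
#' @param x A `tdabc_equity` object.
#' @return Tibble: model, term, estimate, se, ci_low, ci_high, p_value,
#'   significant, r_squared, n.
#' @export
equity_model_table <- function(x) {
  purrr::imap_dfr(x$models, function(m, nm) {
    dplyr::mutate(
      m$coefficients,
      model = nm, r_squared = m$r_squared, n = m$n, .before = 1
    )
  })
}
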