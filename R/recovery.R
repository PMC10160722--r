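# Parameter-recovery and type-I-error harnesses. The paper-scale regression
# coefficients are not reproducible without the private field data, so the
# equity layer is validated by recovery on synthetic studies with known
# ground truth instead.

#' Parameter-recovery experiment
#'
#' Runs the full pipeline (simulate, cost, fit the three equity models)
#' over a set of seeds and records, for every model term, whether the
#' estimated 95% confidence interval covers the true coefficient and
#' whether the term is significant at alpha = 0.05. Replicates whose
#' design drops an empty level (e.g. no patient aged 71+ was drawn) return
#' `NA` for that term and are excluded from that term's coverage
#' denominator.
#'
#' @param n_reps Number of replicate studies.
#' @param base_seed First seed; replicate r uses `base_seed + r - 1`.
#' @param config Configuration template; its seed is overridden per
#'   replicate.
#' @param models Which outcomes to fit (default all three).
#' @return Tibble: `rep`, `seed`, `model`, `term`, `estimate`, `ci_low`,
#'   `ci_high`, `true_value`, `covered`, `significant`.
#' @export
recovery_experiment <- function(n_reps = 100, base_seed = 1,
                                config = sim_config(),
                                models = c(
                                  "duration_minutes",
                                  "cost_no_consumables_usd",
                                  "cost_with_consumables_usd"
                                )) {
  purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(base_seed, r - 1)
    study <- simulate_study(cfg)
    costs <- cost_study(study)
    fits <- suppressWarnings(suppressMessages(
      run_equity_models(costs, study$patients, study$facilities, quiet = TRUE)
    ))
    purrr::map_dfr(models, function(m) {
      truth <- unlist(study$ground_truth$effects[[m]])
      cf <- fits$models[[m]]$coefficients
      all_terms <- design_term_names()
      cf <- dplyr::left_join(
        tibble::tibble(term = all_terms), cf,
        by = "term"
      )
      tibble::tibble(
        rep = r,
        seed = cfg$seed,
        model = m,
        term = cf$term,
        estimate = cf$estimate,
        ci_low = cf$ci_low,
        ci_high = cf$ci_high,
        true_value = unname(truth[cf$term]),
        covered = cf$ci_low <= true_value & true_value <= cf$ci_high,
        significant = cf$significant
      )
    })
  })
}

#' Summarize coverage from a recovery experiment
#'
#' @param results Output of [recovery_experiment()].
#' @return Tibble per model and term: number of informative replicates,
#'   coverage proportion, mean estimate, true value.
#' @export
coverage_summary <- function(results) {
  results |>
    dplyr::group_by(model, term) |>
    dplyr::summarise(
      n_reps = sum(!is.na(covered)),
      coverage = mean(covered, na.rm = TRUE),
      mean_estimate = mean(estimate, na.rm = TRUE),
      true_value = true_value[1],
      .groups = "drop"
    )
}

#' Type-I-error experiment
#'
#' Simulates studies in which every patient-level ground-truth effect is
#' zero (service-line and facility effects retained) and records the
#' significance of each patient-level term in the visit-duration model at
#' alpha = 0.05. In the generator the two cost outcomes are near-linear
#' transforms of duration, so their tests are not independent replicates;
#' the false-positive rate is therefore assessed on the duration model.
#'
#' @param n_reps Number of replicate studies.
#' @param base_seed First seed.
#' @param config Configuration template; patient effects are zeroed and
#'   the seed overridden per replicate.
#' @return Tibble: `rep`, `seed`, `term`, `p_value`, `significant`.
#' @export
type1_experiment <- function(n_reps = 100, base_seed = 1,
                             config = sim_config()) {
  config$effects <- zero_patient_effects(config$effects)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(base_seed, r - 1)
    study <- simulate_study(cfg)
    costs <- cost_study(study)
    fits <- suppressWarnings(suppressMessages(
      run_equity_models(costs, study$patients, study$facilities, quiet = TRUE)
    ))
    cf <- fits$models$duration_minutes$coefficients
    cf <- cf[cf$term %in% patient_terms(), ]
    tibble::tibble(
      rep = r, seed = cfg$seed,
      term = cf$term, p_value = cf$p_value, significant = cf$significant
    )
  })
}
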