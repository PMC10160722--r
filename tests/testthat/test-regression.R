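ref_frame <- function(n = 1) {
  tibble::tibble(
    gender = rep("FEMALE", n), age_group = "18-30", married = FALSE,
    education_level = "0-1", comorbidity = FALSE, asset_index = 0,
    service = "HTC", region = "DAR_ES_SALAAM", facility_type = "DISPENSARY",
    rurality = "URBAN", funder = "GOT", volume_tier = "HIGH"
  )
}

test_that("a reference-level patient encodes to all-zero dummies", {
  X <- suppressWarnings(encode_design_matrix(ref_frame(), drop_empty = FALSE))
  expect_equal(ncol(X), length(design_term_names()))
  expect_equal(unname(X[1, "intercept"]), 1)
  expect_equal(sum(X[1, setdiff(colnames(X), "intercept")]), 0)
})

test_that("factor levels encode with the documented column count and order", {
  fr <- ref_frame(6)
  fr$facility_type <- c(
    "DISPENSARY", "HEALTH_CENTRE", "HOSPITAL", "DISPENSARY",
    "HEALTH_CENTRE", "HOSPITAL"
  )
  X <- suppressWarnings(encode_design_matrix(fr, drop_empty = FALSE))
  # a 3-level factor contributes exactly 2 dummy columns
  expect_equal(sum(grepl("^type_", colnames(X))), 2)
  expect_equal(colnames(X), design_term_names())
  expect_equal(unname(colSums(X[, c("type_health_centre", "type_hospital")])), c(2, 2))
  # full design has the hand-counted term total: intercept + 1 gender +
  # 3 age + married + 3 education + comorbidity + asset + 5 service +
  # 6 region + 2 type + 1 rurality + 1 funder + 2 volume = 28
  expect_length(design_term_names(), 28)
})

test_that("unseen levels raise a vocabulary error naming the value", {
  fr <- ref_frame()
  fr$region <- "ARUSHA"
  err <- expect_error(encode_design_matrix(fr), class = "tdabcost_vocabulary")
  expect_match(conditionMessage(err), "ARUSHA")
  expect_match(conditionMessage(err), "region")
})

test_that("levels absent from the data are dropped with a classed warning", {
  fr <- ref_frame(10)
  expect_warning(
    X <- encode_design_matrix(fr),
    class = "tdabcost_empty_level"
  )
  expect_false("age_71_plus" %in% colnames(X))
  expect_true("intercept" %in% colnames(X))
})

test_that("OLS recovers noiseless coefficients exactly with R-squared 1", {
  set.seed(9)
  n <- 80
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = runif(n))
  beta <- c(2, -1.5, 4)
  y <- as.numeric(X %*% beta)
  fit <- suppressWarnings(fit_fixed_effects_ols(y, X)) # lm warns on perfect fit
  expect_equal(fit$coefficients$estimate, beta, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("an intercept-only model estimates the mean with zero R-squared", {
  set.seed(10)
  y <- rnorm(40, mean = 7)
  X <- cbind(intercept = rep(1, 40))
  fit <- fit_fixed_effects_ols(y, X)
  expect_equal(fit$coefficients$estimate, mean(y))
  expect_equal(fit$r_squared, 0, tolerance = 1e-12)
  expect_equal(fit$df_residual, 39)
})

test_that("OLS satisfies the normal equations and CI symmetry", {
  set.seed(11)
  n <- 300
  X <- cbind(intercept = 1, a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
  y <- as.numeric(X %*% c(1, 2, -3, 0.5)) + rnorm(n, sd = 2)
  fit <- fit_fixed_effects_ols(y, X)
  resid <- y - as.numeric(X %*% fit$coefficients$estimate)
  scale <- max(abs(crossprod(X, y)))
  expect_lt(max(abs(crossprod(X, resid))) / scale, 1e-6)
  expect_equal(
    fit$coefficients$estimate - fit$coefficients$ci_low,
    fit$coefficients$ci_high - fit$coefficients$estimate,
    tolerance = 1e-9
  )
})

test_that("confidence intervals attain nominal coverage on simulated data", {
  # Monte-Carlo coverage oracle: homoskedastic Gaussian errors, fixed X
  set.seed(12)
  n <- 400
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  beta <- c(1, 0.5, -0.8)
  mu <- as.numeric(X %*% beta)
  hits <- matrix(NA, 200, 3)
  for (r in 1:200) {
    y <- mu + rnorm(n, sd = 3)
    cf <- fit_fixed_effects_ols(y, X)$coefficients
    hits[r, ] <- cf$ci_low <= beta & beta <= cf$ci_high
  }
  cov <- colMeans(hits)
  expect_true(all(cov >= 0.91 & cov <= 0.99))
})

test_that("rank deficiency raises a collinearity error listing dependent columns", {
  set.seed(13)
  n <- 50
  x1 <- rnorm(n)
  X <- cbind(intercept = 1, x1 = x1, x2 = rnorm(n), x1_copy = x1)
  err <- expect_error(
    fit_fixed_effects_ols(rnorm(n), X),
    class = "tdabcost_collinearity"
  )
  expect_match(conditionMessage(err), "x1")
  # an implied facility dummy (sum of two others) must error, never drop
  d1 <- rbinom(n, 1, 0.5)
  d2 <- 1 - d1
  X2 <- cbind(intercept = 1, d1 = d1, d2 = d2, z = rnorm(n))
  expect_error(
    fit_fixed_effects_ols(rnorm(n), X2),
    class = "tdabcost_collinearity"
  )
})

test_that("cluster-robust standard errors are available and differ", {
  set.seed(14)
  n <- 200
  cl <- rep(1:20, each = 10)
  u <- rnorm(20)[cl]
  X <- cbind(intercept = 1, x = rnorm(n))
  y <- as.numeric(X %*% c(1, 2)) + u + rnorm(n)
  f1 <- fit_fixed_effects_ols(y, X)
  f2 <- fit_fixed_effects_ols(y, X, cluster = cl)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate)
  expect_false(isTRUE(all.equal(f1$coefficients$se, f2$coefficients$se)))
  expect_equal(f2$se_type, "cluster")
})

test_that("equity models are linear in the outcome: with-minus-without equals a consumables regression", {
  study <- simulate_study(small_config())
  costs <- cost_study(study)
  eq <- suppressWarnings(run_equity_models(costs, study$patients, study$facilities, quiet = TRUE))

  b_with <- eq$models$cost_with_consumables_usd$coefficients
  b_wo <- eq$models$cost_no_consumables_usd$coefficients
  frame <- suppressWarnings(build_model_frame(costs, study$patients, study$facilities, quiet = TRUE))
  X <- suppressWarnings(encode_design_matrix(frame))
  cons <- frame$cost_with_consumables_usd - frame$cost_no_consumables_usd
  b_cons <- fit_fixed_effects_ols(cons, X)$coefficients
  expect_equal(b_with$estimate - b_wo$estimate, b_cons$estimate, tolerance = 1e-8)

  # structure: three models over identical terms, tidy table exports
  expect_named(eq$models, c(
    "duration_minutes", "cost_no_consumables_usd",
    "cost_with_consumables_usd"
  ))
  expect_equal(b_with$term, b_wo$term)
  tab <- equity_model_table(eq)
  expect_true(all(c("model", "term", "estimate", "p_value", "r_squared", "n") %in% names(tab)))
  expect_equal(nrow(tab), 3 * nrow(b_with))
})
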