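#' Household asset index by principal component analysis
#'
#' The standard wealth-proxy construction: household possession and
#' dwelling-quality indicators are centered and scaled to unit variance,
#' and each household's score is its projection onto the first principal
#' component. The sign is oriented so that higher scores mean wealthier
#' households (positive correlation with the row sum of the raw
#' indicators). Scores have mean zero across the estimation sample.
#'
#' Zero-variance indicator columns carry no information under
#' standardization and are dropped before the decomposition; if every
#' column is constant the index is undefined. Missing indicator values are
#' an error — no imputation is performed.
#'
#' @param x Numeric matrix or data frame, patients in rows and asset
#'   indicators (binary or ordinal) in columns. At least 2 rows and 2
#'   columns.
#' @param ids Optional vector of patient ids (defaults to row order).
#' @return Tibble with columns `patient_id` and `score`.
#' @examples
#' set.seed(1)
#' x <- matrix(rbinom(120, 1, 0.4), nrow = 20)
#' build_asset_index(x)
#' @export
build_asset_index <- function(x, ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    stop_invalid_input("Asset indicators must be numeric (binary or ordinal).")
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop_invalid_input("Asset matrix needs at least 2 patients and 2 indicators.")
  }
  if (anyNA(x)) {
    abort_tdabc(
      "Asset indicators contain missing values; no imputation is performed.",
      "tdabcost_missingness"
    )
  }
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    abort_tdabc(
      "All asset indicator columns are constant: the first principal component is undefined.",
      "tdabcost_degenerate_variance"
    )
  }
  xk <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(xk, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  orient <- stats::cor(score, rowSums(x))
  if (!is.na(orient) && orient < 0) score <- -score
  tibble::tibble(
    patient_id = ids %||% seq_len(nrow(x)),
    score = as.numeric(score)
  )
}
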