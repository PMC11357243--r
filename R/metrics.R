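check_pairs <- function(pred, obs, min_n = 1) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (length(pred) < min_n) stop("need at least ", min_n, " pair(s)")
  if (any(!is.finite(pred)) || any(!is.finite(obs)) ||
      any(pred <= 0) || any(obs <= 0))
    stop("fold-error metrics require positive, finite values")
  invisible(TRUE)
}

#' Fold-error and percent-error metrics
#'
#' Average fold error `AFE = 10^mean(log10(pred/obs))` (geometric-mean bias;
#' 1 is unbiased), absolute average fold error
#' `AAFE = 10^mean(|log10(pred/obs)|)` (>= 1; typical fold deviation), and
#' percent prediction error `PPE = mean(|pred - obs| / obs) * 100` with a
#' normal-approximation 95% confidence interval.
#'
#' @param pred,obs Positive vectors of matched predictions and observations.
#' @return `afe`/`aafe`: scalar. `ppe`: list with `mean`, `ci` (length 2,
#'   requires n >= 2), `n`.
#' @export
afe <- function(pred, obs) {
  check_pairs(pred, obs)
  10^mean(log10(pred / obs))
}

#' @rdname afe
#' @export
aafe <- function(pred, obs) {
  check_pairs(pred, obs)
  10^mean(abs(log10(pred / obs)))
}

#' @rdname afe
#' @export
ppe <- function(pred, obs) {
  check_pairs(pred, obs)
  e <- abs(pred - obs) / obs * 100
  n <- length(e)
  ci <- if (n >= 2) mean(e) + c(-1, 1) * 1.96 * stats::sd(e) / sqrt(n)
        else c(NA_real_, NA_real_)
  list(mean = mean(e), ci = ci, n = n)
}

#' Categorical grading of fold errors
#'
#' AFE: satisfactory if `0.8 <= AFE <= 1.25`, acceptable if `0.5 <= AFE <
#' 0.8` or `1.25 < AFE <= 2`, poor if `AFE < 0.5` or `AFE > 2`. AAFE:
#' satisfactory if `<= 1.25`, acceptable if in `(1.25, 2]`, poor above 2.
#'
#' @param afe_value,aafe_value Positive metric values.
#' @return Named character vector with elements `AFE` and `AAFE`.
#' @export
categorize <- function(afe_value, aafe_value) {
  stopifnot(afe_value > 0, aafe_value > 0)
  afe_cat <- if (afe_value >= 0.8 && afe_value <= 1.25) "satisfactory"
    else if ((afe_value >= 0.5 && afe_value < 0.8) ||
             (afe_value > 1.25 && afe_value <= 2)) "acceptable"
    else "poor"
  aafe_cat <- if (aafe_value <= 1.25) "satisfactory"
    else if (aafe_value <= 2) "acceptable"
    else "poor"
  c(AFE = afe_cat, AAFE = aafe_cat)
}

#' Performance report from matched pairs
#'
#' @param pred,obs Matched positive vectors.
#' @param subgroup Label for the report row.
#' @return One-row data frame (subgroup, n_pairs, AFE, AAFE, PPE_mean,
#'   PPE_CI_low, PPE_CI_high, AFE_category, AAFE_category).
#' @export
performance_report <- function(pred, obs, subgroup = "all") {
  if (length(pred) == 0)
    return(data.frame(subgroup = subgroup, n_pairs = 0L, AFE = NA_real_,
                      AAFE = NA_real_, PPE_mean = NA_real_,
                      PPE_CI_low = NA_real_, PPE_CI_high = NA_real_,
                      AFE_category = NA_character_,
                      AAFE_category = NA_character_))
  a <- afe(pred, obs); aa <- aafe(pred, obs); p <- ppe(pred, obs)
  cats <- categorize(a, aa)
  data.frame(subgroup = subgroup, n_pairs = length(pred), AFE = a, AAFE = aa,
             PPE_mean = p$mean, PPE_CI_low = p$ci[1], PPE_CI_high = p$ci[2],
             AFE_category = cats[["AFE"]], AAFE_category = cats[["AAFE"]])
}

#' Subgroup performance report over forecast logs
#'
#' Pools prediction/observation pairs across patients within each subgroup
#' and reports the metrics per stratum: overall, ACE-inhibitor use, with and
#' without potassium supplementation, and high-ceiling diuretic use (the
#' descriptive comedication strata), plus any additional metadata flags
#' requested.
#'
#' @param logs A `forecast_set` (or list of `forecast_log`).
#' @param groupings Named list mapping subgroup labels to predicate
#'   functions of the patient metadata, or NULL for the default strata.
#' @return Data frame with one [performance_report()] row per subgroup.
#' @export
subgroup_report <- function(logs, groupings = NULL) {
  if (inherits(logs, "forecast_log")) logs <- list(logs)
  if (is.null(groupings))
    groupings <- list(
      "all" = function(m) TRUE,
      "ACE inhibitor use" = function(m) isTRUE(m$ace_i),
      "without potassium supplementation" =
        function(m) !isTRUE(m$potassium_supplementation),
      "with potassium supplementation" =
        function(m) isTRUE(m$potassium_supplementation),
      "high-ceiling diuretics" = function(m) isTRUE(m$high_ceiling_diuretic)
    )
  rows <- lapply(names(groupings), function(lab) {
    keep <- vapply(logs, function(lg) isTRUE(groupings[[lab]](lg$meta)),
                   logical(1))
    pairs <- do.call(rbind, lapply(logs[keep], `[[`, "pairs"))
    if (is.null(pairs) || nrow(pairs) == 0)
      performance_report(numeric(0), numeric(0), subgroup = lab)
    else performance_report(pairs$predicted, pairs$observed, subgroup = lab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
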