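#' Signed prediction error, normalized by the pair mean
#'
#' `PE = (predicted - observed) / ((predicted + observed) / 2) * 100`. The
#' mean-of-the-pair denominator makes the statistic antisymmetric under
#' argument swap and bounds it in (-200, 200) for positive inputs.
#'
#' @param predicted,observed Positive values; vectorized.
#' @return Signed percentage.
#' @examples
#' prediction_error(15.36, 3.60)  # 124.1
#' @export
prediction_error <- function(predicted, observed) {
  if (any(!is.finite(predicted)) || any(!is.finite(observed)) ||
      any(predicted <= 0) || any(observed <= 0))
    stop("prediction_error requires positive predicted and observed values",
         call. = FALSE)
  (predicted - observed) / ((predicted + observed) / 2) * 100
}

#' Pearson correlation by the standardized-sum formula
#'
#' `r = 1/(n-1) * sum(((x - mean(x))/sd(x)) * ((y - mean(y))/sd(y)))`, with
#' sample standard deviations. Equivalent to the covariance definition; kept
#' as the explicit summation form. Zero variance in either margin makes the
#' correlation undefined and returns `NA` with a warning rather than a
#' silent 0.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Correlation coefficient in \[-1, 1\], or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    warning("zero variance in one margin: correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (length(x) - 1)
}

#' Fold accuracy of predictions per compound
#'
#' Percentage of available tissue predictions whose predicted/observed ratio
#' falls within the closed interval \[1/fold, fold\]. Ties count as within.
#'
#' @param records Data.frame with columns `compound`, `predicted`,
#'   `observed`.
#' @param fold Fold criterion (> 1); default 3.
#' @return Named numeric vector, percent within fold per compound.
#' @export
fold_accuracy <- function(records, fold = 3) {
  if (fold <= 1) stop("fold must exceed 1", call. = FALSE)
  ratio <- records$predicted / records$observed
  within <- ratio >= 1 / fold & ratio <= fold
  100 * vapply(split(within, records$compound), mean, numeric(1))
}

#' Build predicted-versus-observed validation records
#'
#' Runs the partition model over every compound-tissue pair with an observed
#' value and pairs the prediction with the PET-derived observation.
#'
#' @param params A parameter set; default [default_parameters()].
#' @param scenario A [scenario_config()]; default [final_model_scenario()].
#' @param observed Observed table as from [observed_tbr()].
#' @return Data.frame with columns `compound`, `tissue`, `predicted`,
#'   `observed`, `pe_percent`, `within_3fold`; unavailable observations are
#'   dropped.
#' @export
validate_predictions <- function(params = default_parameters(),
                                 scenario = final_model_scenario(),
                                 observed = observed_tbr()) {
  obs <- observed[observed$available, , drop = FALSE]
  obs$predicted <- mapply(function(cn, tn)
    predict_tbr(params, cn, tn, scenario)$tbr, obs$compound, obs$tissue)
  records <- data.frame(compound = obs$compound, tissue = obs$tissue,
                        predicted = obs$predicted, observed = obs$mean)
  records$pe_percent <- prediction_error(records$predicted, records$observed)
  ratio <- records$predicted / records$observed
  records$within_3fold <- ratio >= 1 / 3 & ratio <= 3
  rownames(records) <- NULL
  records
}

#' Summarize predicted-versus-observed agreement
#'
#' Aggregates per-pair prediction errors into the validation report: mean
#' PE, a 95% interval of the PE distribution, Pearson correlation (by the
#' standardized-sum formula) with its r-squared and t-test p-value (n - 2
#' degrees of freedom), and per-compound 3-fold accuracy.
#'
#' @param records Data.frame with columns `compound`, `predicted`,
#'   `observed` (as from [validate_predictions()]).
#' @param interval_method `"percentile"` (empirical 2.5/97.5 percentiles of
#'   the PEs, default) or `"normal"` (mean +/- 1.96 sd). Neither is uniquely
#'   implied by a "CI95% of the data", so the report labels the one used.
#' @param fold Fold-accuracy criterion; default 3.
#' @return An object of class `validation_report`: list with `records`
#'   (augmented with `pe_percent`, `within_3fold`), `n`, `mean_pe`,
#'   `pe_range`, `pe_interval`, `interval_method`, `pearson_r`, `r_squared`,
#'   `p_value`, `fold`, `fold_accuracy_by_compound`.
#' @export
summarize_validation <- function(records,
                                 interval_method = c("percentile", "normal"),
                                 fold = 3) {
  interval_method <- match.arg(interval_method)
  stopifnot(nrow(records) >= 3)
  records$pe_percent <- prediction_error(records$predicted, records$observed)
  ratio <- records$predicted / records$observed
  records$within_3fold <- ratio >= 1 / fold & ratio <= fold
  pes <- records$pe_percent
  interval <- if (interval_method == "percentile") {
    unname(stats::quantile(pes, c(0.025, 0.975), type = 7))
  } else {
    mean(pes) + c(-1.96, 1.96) * stats::sd(pes)
  }
  r <- pearson_r(records$predicted, records$observed)
  n <- nrow(records)
  p_value <- if (is.na(r)) NA_real_ else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(
    list(records = records, n = n, mean_pe = mean(pes), pe_range = range(pes),
         pe_interval = interval, interval_method = interval_method,
         pearson_r = r, r_squared = r^2, p_value = p_value, fold = fold,
         fold_accuracy_by_compound = fold_accuracy(records, fold)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 4, ...) {
  cat("Validation of predicted vs observed TBR (", x$n, " pairs)\n", sep = "")
  cat("  mean PE: ", signif(x$mean_pe, digits), "%  range: [",
      signif(x$pe_range[1], digits), ", ", signif(x$pe_range[2], digits),
      "]\n", sep = "")
  cat("  95% interval (", x$interval_method, "): [",
      signif(x$pe_interval[1], digits), ", ",
      signif(x$pe_interval[2], digits), "]\n", sep = "")
  cat("  Pearson r: ", signif(x$pearson_r, digits), "  r^2: ",
      signif(x$r_squared, digits), "  p: ", signif(x$p_value, 3), "\n",
      sep = "")
  fa <- x$fold_accuracy_by_compound
  cat("  within ", x$fold, "-fold: ",
      paste(sprintf("%s %.1f%%", names(fa), fa), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Bland-Altman style agreement table
#'
#' One row per validation record: the mean of the predicted/observed pair,
#' the prediction error, and the constant PE bounds equivalent to the
#' fold criterion on the ratio scale (`+-100 * (fold - 1) / ((fold + 1)/2)`
#' ... expressed directly as the PE of a pair at exactly `fold`-fold
#' deviation: `(fold - 1)/((fold + 1)/2) * 100`, i.e. +-100 for fold = 3).
#'
#' @param records Data.frame with columns `compound`, `tissue`, `predicted`,
#'   `observed`; may be empty.
#' @param fold Fold criterion; default 3.
#' @return Data.frame with columns `compound`, `tissue`, `mean_of_pair`,
#'   `pe_percent`, `lower_bound`, `upper_bound`.
#' @export
bland_altman_table <- function(records, fold = 3) {
  bound <- (fold - 1) / ((fold + 1) / 2) * 100
  if (!nrow(records))
    return(data.frame(compound = character(), tissue = character(),
                      mean_of_pair = numeric(), pe_percent = numeric(),
                      lower_bound = numeric(), upper_bound = numeric()))
  data.frame(
    compound = records$compound, tissue = records$tissue,
    mean_of_pair = (records$predicted + records$observed) / 2,
    pe_percent = prediction_error(records$predicted, records$observed),
    lower_bound = -bound, upper_bound = bound)
}
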