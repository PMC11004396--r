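#' Regression accuracy metrics for emergence-rate validation
#'
#' Computes RMSE, MAE, and two variants of R-squared between measured and
#' estimated rates (both in percent):
#' * `r2_standard` — the coefficient of determination
#'   `1 - SSres/SStot`;
#' * `r2_printed` — the explained-sum-of-squares ratio
#'   `sum((est - mean(meas))^2) / sum((meas - mean(meas))^2)`, the form
#'   some field studies print as R^2 for validation scatter. The two agree
#'   when the estimate is an OLS fit of the measurements and differ
#'   otherwise, so both are reported; `r2_standard` is the headline value.
#'
#' With zero variance in the measured rates both R-squared variants are
#' undefined and reported as `NA`.
#'
#' @param measured numeric vector of measured rates (percent).
#' @param estimated numeric vector of estimated rates (percent), same
#'   length.
#' @return A `metric_report`: list with `n`, `r2_standard`, `r2_printed`,
#'   `rmse`, `mae`, `bias` (mean of estimated - measured).
#' @export
regression_metrics <- function(measured, estimated) {
  stopifnot(is.numeric(measured), is.numeric(estimated))
  if (length(measured) != length(estimated)) {
    stop("measured and estimated vectors differ in length", call. = FALSE)
  }
  if (length(measured) < 2L) {
    stop("need at least 2 paired samples", call. = FALSE)
  }
  if (any(!is.finite(measured)) || any(!is.finite(estimated))) {
    stop("inputs must be finite", call. = FALSE)
  }
  resid <- estimated - measured
  rmse <- sqrt(mean(resid^2))
  mae <- mean(abs(resid))
  sst <- sum((measured - mean(measured))^2)
  if (sst == 0) {
    message("regression_metrics: measured rates have zero variance; ",
            "R-squared undefined")
    r2s <- NA_real_
    r2p <- NA_real_
  } else {
    r2s <- 1 - sum(resid^2) / sst
    r2p <- sum((estimated - mean(measured))^2) / sst
  }
  structure(list(n = length(measured), r2_standard = r2s, r2_printed = r2p,
                 rmse = rmse, mae = mae, bias = mean(resid)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> n = ", x$n,
      "\n  R2 (standard) = ", format(x$r2_standard, digits = 4),
      "\n  R2 (printed)  = ", format(x$r2_printed, digits = 4),
      "\n  RMSE = ", format(x$rmse, digits = 4), "%",
      "\n  MAE  = ", format(x$mae, digits = 4), "%",
      "\n  bias = ", format(x$bias, digits = 4), "%\n", sep = "")
  invisible(x)
}

#' Compare an estimated emergence map against the truth
#'
#' Pairs per-cell rates of two emergence maps on identical grid geometry
#' (same `grid_px`, same cell set), computes the accuracy metrics and a
#' per-cell residual table, and summarizes the estimated rates
#' (mean/median).
#'
#' @param truth the reference `emergence_map` (e.g.
#'   [truth_emergence_map()]).
#' @param estimate the pipeline's `emergence_map`.
#' @return A list: `report` (a `metric_report`), `residuals` (data.frame
#'   `grid_row`, `grid_col`, `measured`, `estimated`, `residual`),
#'   `summary` (mean/median of estimated rates).
#' @export
compare_maps <- function(truth, estimate) {
  stopifnot(inherits(truth, "emergence_map"),
            inherits(estimate, "emergence_map"))
  if (!identical(attr(truth, "grid_px"), attr(estimate, "grid_px"))) {
    stop("grid mismatch: cell sizes differ (", attr(truth, "grid_px"),
         " vs ", attr(estimate, "grid_px"), " px)", call. = FALSE)
  }
  kt <- paste(truth$grid_row, truth$grid_col)
  ke <- paste(estimate$grid_row, estimate$grid_col)
  if (!setequal(kt, ke) || length(kt) != length(ke)) {
    stop("grid mismatch: the two maps score different cell sets",
         call. = FALSE)
  }
  est <- estimate$rate_pct[match(kt, ke)]
  res <- data.frame(grid_row = truth$grid_row, grid_col = truth$grid_col,
                    measured = truth$rate_pct, estimated = est,
                    residual = est - truth$rate_pct)
  list(report = regression_metrics(res$measured, res$estimated),
       residuals = res,
       summary = c(mean = mean(est), median = stats::median(est)))
}
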