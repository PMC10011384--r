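# Regression metrics and SAR correlation analysis.

#' Regression metrics for predicted vs experimental energies
#'
#' MAE, RMSE and r-squared for a set of (predicted, experimental) pairs.
#' Two r-squared conventions exist for calibration scatters; both are
#' returned: `r2` is the squared Pearson correlation (the default
#' convention here) and `r2_ss` is `1 - SS_res/SS_tot`.
#'
#' @param predicted,experimental Numeric vectors, kJ/mol.
#' @param ids Optional identifiers for the residual table.
#' @return Object of class `metrics_report`: `mae`, `rmse`, `r2`,
#'   `r2_ss`, `n` and a `residuals` data.frame.
#' @export
regression_metrics <- function(predicted, experimental, ids = NULL) {
  stopifnot(length(predicted) == length(experimental))
  n <- length(predicted)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  e <- predicted - experimental
  r2 <- if (stats::sd(predicted) > 0 && stats::sd(experimental) > 0) {
    stats::cor(predicted, experimental)^2
  } else NA_real_
  structure(list(
    mae = mean(abs(e)),
    rmse = sqrt(mean(e^2)),
    r2 = r2,
    r2_ss = 1 - sum(e^2) / sum((experimental - mean(experimental))^2),
    n = n,
    residuals = data.frame(
      id = if (is.null(ids)) seq_len(n) else ids,
      predicted = predicted, experimental = experimental, error = e)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("  MAE = %.2f kJ/mol, RMSE = %.2f kJ/mol, r2 = %.2f (ss: %.2f)\n",
              x$mae, x$rmse, x$r2, x$r2_ss))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both with non-zero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Correlate activities with per-molecule features
#'
#' Pearson r between pIC50s and each feature column over the intersection
#' of identifiers, as in structure-activity tables for congeneric series.
#' A feature constant across molecules yields `NA` for that feature (with
#' a warning); other features are unaffected.
#'
#' @param activities Named numeric vector (or 2-column data.frame of id,
#'   pIC50).
#' @param strengths data.frame with an `id`-like first column and one
#'   numeric column per feature.
#' @return data.frame with columns `feature`, `r`, `n`; attribute
#'   `missing_ids` lists identifiers present on only one side.
#' @export
sar_correlate <- function(activities, strengths) {
  if (is.data.frame(activities)) {
    activities <- stats::setNames(activities[[2]],
                                  as.character(activities[[1]]))
  }
  sid <- as.character(strengths[[1]])
  shared <- intersect(names(activities), sid)
  if (length(shared) < 3) {
    stop("need at least 3 shared identifiers", call. = FALSE)
  }
  act <- activities[shared]
  feat <- strengths[match(shared, sid), -1, drop = FALSE]
  rows <- lapply(names(feat), function(nm) {
    r <- tryCatch(pearson_r(act, feat[[nm]]), error = function(e) {
      warning("feature '", nm, "': ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
    data.frame(feature = nm, r = r, n = length(shared),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "missing_ids") <-
    setdiff(union(names(activities), sid), shared)
  out
}
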