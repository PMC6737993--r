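#' Model evaluation statistics for observed vs predicted yields
#'
#' The four agreement statistics used to judge yield predictions:
#' root mean square error, coefficient of determination (squared Pearson
#' correlation), Willmott's index of agreement, and percent bias.
#'
#' Percent bias follows the hydrological sign convention:
#' `100 * sum(obs - pred) / sum(obs)`, so positive values mean the model
#' underestimates and negative values mean it overestimates.
#'
#' Willmott's index is `1 - sum((obs - pred)^2) /
#' sum((|pred - mean(obs)| + |obs - mean(obs)|)^2)`; it equals 1 for
#' perfect agreement and approaches 0 for useless predictions.
#'
#' @param obs,pred numeric vectors of equal length.
#' @return A single numeric value.
#' @name validation_metrics
NULL

.check_op <- function(obs, pred, nmin = 1L) {
  if (length(obs) != length(pred)) stop("'obs' and 'pred' lengths differ")
  if (length(obs) < nmin) stop("need at least ", nmin, " observations")
  if (anyNA(obs) || anyNA(pred)) stop("missing values in 'obs' or 'pred'")
  invisible(TRUE)
}

#' @rdname validation_metrics
#' @export
rmse <- function(obs, pred) {
  .check_op(obs, pred)
  sqrt(mean((obs - pred)^2))
}

#' @rdname validation_metrics
#' @export
r_squared <- function(obs, pred) {
  .check_op(obs, pred, 2L)
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    stop("R2 undefined for a constant series")
  stats::cor(obs, pred)^2
}

#' @rdname validation_metrics
#' @export
willmott_d <- function(obs, pred) {
  .check_op(obs, pred, 2L)
  den <- sum((abs(pred - mean(obs)) + abs(obs - mean(obs)))^2)
  if (den == 0) stop("index of agreement undefined: no dispersion about mean(obs)")
  1 - sum((obs - pred)^2) / den
}

#' @rdname validation_metrics
#' @export
pbias <- function(obs, pred) {
  .check_op(obs, pred)
  if (sum(obs) == 0) stop("percent bias undefined: observed values sum to zero")
  100 * sum(obs - pred) / sum(obs)
}

#' Validation report for observed vs predicted yields
#'
#' Bundles the four evaluation statistics into a one-row report.
#'
#' @param obs,pred observed and predicted grain yields (kg/ha).
#' @param zone optional zone label.
#' @return An object of class `"quefts_validation"`: a list with `n`,
#'   `RMSE` (kg/ha), `R2`, `d`, `PBIAS` (percent) and `zone`.
#' @export
validation_report <- function(obs, pred, zone = NA_character_) {
  .check_op(obs, pred, 2L)
  structure(list(n = length(obs), RMSE = rmse(obs, pred),
                 R2 = r_squared(obs, pred), d = willmott_d(obs, pred),
                 PBIAS = pbias(obs, pred), zone = zone),
            class = "quefts_validation")
}

#' @export
print.quefts_validation <- function(x, ...) {
  cat("Yield validation", if (!is.na(x$zone)) paste0("(", x$zone, ")"), "\n")
  cat(sprintf("  n = %d\n  RMSE  = %.2f t/ha\n  R2    = %.2f\n  d     = %.2f\n  PBIAS = %+.1f%%\n",
              x$n, x$RMSE / 1000, x$R2, x$d, x$PBIAS))
  invisible(x)
}
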