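#' @export
print.quefts <- function(x, ...) {
  cat("QUEFTS model fit\n")
  cat("Records: ", x$report$n_input, " in; ",
      x$report$n_outliers_removed, " outliers and ",
      x$report$n_ghi_removed, " low-GHI plots removed; ",
      x$report$n_calibration, " calibration / ",
      x$report$n_validation, " validation\n", sep = "")
  print(x$coef)
  invisible(x)
}

#' @export
summary.quefts <- function(object, ...) {
  cat("Call: "); print(object$call)
  print(object)
  cat("\nIndigenous supply equations:\n")
  for (eq in object$supply_eqs) print(eq)
  v <- try(validate(object), silent = TRUE)
  if (!inherits(v, "try-error")) { cat("\nValidation partition:\n"); print(v) }
  invisible(object)
}

#' Extract fitted QUEFTS coefficients
#'
#' @param object a fitted [quefts] model.
#' @param ... unused.
#' @return The fitted [quefts_coef] object.
#' @export
coef.quefts <- function(object, ...) object$coef

#' Predict grain yield for new plots
#'
#' Runs the forward chain (supply equations, recovery fractions, uptake,
#' yield combination) on new plot records.
#'
#' @param object a fitted [quefts] model.
#' @param newdata plot-record data.frame; defaults to the validation
#'   partition.
#' @param type `"yield"` (kg/ha vector) or `"all"` (list with `yield`,
#'   `uptake`, `supply`).
#' @param ... unused.
#' @export
predict.quefts <- function(object, newdata = NULL,
                           type = c("yield", "all"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$validation
  Fz <- as.matrix(newdata[, c("applied_N", "applied_P", "applied_K")])
  S <- total_supply(newdata, object$supply_eqs, Fz, object$coef)
  res <- quefts_yield(S, object$coef, object$uptake_combine)
  if (type == "yield") res$yield else c(res, list(supply = S))
}

#' Observed-minus-predicted yield residuals
#'
#' @inheritParams predict.quefts
#' @param ... unused.
#' @return kg/ha residuals on the validation partition (or `newdata`).
#' @export
residuals.quefts <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$validation
  newdata$grain_yield - predict(object, newdata)
}

#' Validate a fitted QUEFTS model
#'
#' Predicts grain yield for the validation partition (or any other plot
#' table) and reports the agreement statistics.
#'
#' @param object a fitted [quefts] model.
#' @param newdata optional plot-record data.frame.
#' @param zone optional label for the report.
#' @return A [validation_report] object.
#' @export
validate <- function(object, newdata = NULL, zone = NULL) {
  stopifnot(inherits(object, "quefts"))
  if (is.null(newdata)) newdata <- object$validation
  if (nrow(newdata) < 2) stop("validation set has fewer than 2 plots")
  if (is.null(zone)) zone <- object$coef$zone
  validation_report(newdata$grain_yield, predict(object, newdata), zone)
}

#' Simulate trials from a fitted model
#'
#' Draws new synthetic omission-trial tables whose true coefficients and
#' supply equations are the fitted ones.
#'
#' @param object a fitted [quefts] model.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param n_fields fields per table.
#' @param zone zone whose soil distribution and rates to use; must be
#'   `"NGS"`, `"SS"` or `"All"` (defaults to the fit's zone).
#' @param ... passed to [quefts_generator()].
#' @return A list of plot-record data.frames (a single data.frame if
#'   `nsim = 1`).
#' @export
simulate.quefts <- function(object, nsim = 1, seed = NULL, n_fields = 100,
                            zone = NULL, ...) {
  if (is.null(zone)) zone <- object$coef$zone
  if (!zone %in% c("NGS", "SS", "All")) zone <- "All"
  gen <- quefts_generator(zone, n_fields = n_fields, coef = object$coef,
                          eqs = object$supply_eqs, ...)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(k) generate_trials(gen))
  if (nsim == 1) out[[1]] else out
}

#' Diagnostic plots for a fitted QUEFTS model
#'
#' `which = 1`: observed vs predicted yield on the validation partition;
#' `which = 2`: per-nutrient yield-uptake clouds of the calibration
#' partition with the fitted boundary lines.
#'
#' @param x a fitted [quefts] model.
#' @param which plot selection.
#' @param ... graphical parameters passed on.
#' @export
plot.quefts <- function(x, which = 1, ...) {
  if (1 %in% which && nrow(x$validation) >= 2) {
    obs <- x$validation$grain_yield / 1000
    prd <- predict(x, x$validation) / 1000
    lim <- range(0, obs, prd)
    plot(prd, obs, xlim = lim, ylim = lim,
         xlab = "Predicted yield (t/ha)", ylab = "Observed yield (t/ha)",
         main = "QUEFTS validation", ...)
    abline(0, 1, lty = 2)
  }
  if (2 %in% which) {
    op <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(op))
    U <- plot_uptake(x$calibration)
    for (i in c("N", "P", "K")) {
      plot(U[, i], x$calibration$grain_yield / 1000,
           xlab = paste0("Uptake of ", i, " (kg/ha)"),
           ylab = "Grain yield (t/ha)", main = paste("Nutrient", i), ...)
      abline(-x$coef$a[[i]] * x$coef$r[[i]] / 1000, x$coef$a[[i]] / 1000,
             col = "grey40")
      abline(-x$coef$d[[i]] * x$coef$r[[i]] / 1000, x$coef$d[[i]] / 1000,
             col = "grey40")
    }
  }
  invisible(x)
}
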