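#' Indigenous soil nutrient supply equations
#'
#' A supply equation maps topsoil properties to the indigenous supply of
#' one nutrient (kg/ha): what the unfertilized soil can deliver to a
#' maize crop over a season, as estimated from nutrient uptake in plots
#' where that nutrient was omitted. Equations are stored as an intercept
#' plus a list of terms, each a coefficient applied to a transformed
#' predictor, so that both the zone-calibrated forms and the classic
#' QUEFTS default forms can be represented, evaluated, serialized and
#' re-fitted uniformly.
#'
#' Soil property columns and units: `pH` (1:1 water), `OC_tot` (g/kg),
#' `N_tot` (g/kg), `P_av` (mg/kg, Mehlich-3), `K_exch` (cmol_c/kg).
#'
#' @param nutrient one of `"N"`, `"P"`, `"K"`.
#' @param intercept numeric intercept (kg/ha).
#' @param terms a list of terms, each `list(var =, coef =, power = 1)`
#'   (power applies to the predictor before the coefficient) or, for the
#'   non-polynomial families, `trans = "log"` / `"exp"` (with `scale`),
#'   or `trans = "cauchy"` with `loc` and `scale`.
#' @param family label of the functional family (`"linear"`,
#'   `"polynomial"`, `"logarithmic"`, `"exponential"`, `"cauchy"`).
#' @param R2,BIC optional fit diagnostics carried with the equation.
#' @param zone,source provenance labels.
#' @return An object of class `"supply_eq"`.
#' @examples
#' eq <- supply_equation("K", 26.35, list(list(var = "K_exch", coef = 247.97)))
#' predict(eq, data.frame(K_exch = 0.22))
#' @export
supply_equation <- function(nutrient, intercept, terms, family = "linear",
                            R2 = NA_real_, BIC = NA_real_,
                            zone = NA_character_, source = NA_character_) {
  nutrient <- match.arg(nutrient, c("N", "P", "K"))
  terms <- lapply(terms, function(tm) {
    stopifnot(!is.null(tm$var), !is.null(tm$coef))
    if (is.null(tm$power)) tm$power <- 1
    tm
  })
  structure(list(nutrient = nutrient, intercept = intercept, terms = terms,
                 family = family, R2 = R2, BIC = BIC, zone = zone,
                 source = source),
            class = "supply_eq")
}

.eval_term <- function(tm, soil) {
  if (!tm$var %in% names(soil))
    stop("missing predictor '", tm$var, "' required by supply equation")
  x <- soil[[tm$var]]
  v <- if (!is.null(tm$trans)) {
    switch(tm$trans,
           log = log(x),
           exp = exp(x / tm$scale),
           cauchy = 1 / (1 + ((x - tm$loc) / tm$scale)^2),
           stop("unknown term transform: ", tm$trans))
  } else x^tm$power
  tm$coef * v
}

#' Evaluate a supply equation on soil data
#'
#' Evaluates the stored functional form at each row of a soil table and
#' floors the result at zero: a negative fitted supply (possible at low
#' pH or very low nutrient status with some intercepts) is physically
#' meaningless and is reported as zero.
#'
#' @param object a [supply_equation] object.
#' @param newdata data.frame of soil properties (one row per field).
#' @param ... unused.
#' @return Numeric vector of indigenous supplies (kg/ha), floored at 0.
#' @export
predict.supply_eq <- function(object, newdata, ...) {
  v <- rep(object$intercept, nrow(newdata))
  for (tm in object$terms) v <- v + .eval_term(tm, newdata)
  pmax(v, 0)
}

#' @export
print.supply_eq <- function(x, ...) {
  tt <- vapply(x$terms, function(tm) {
    rhs <- if (!is.null(tm$trans)) paste0(tm$trans, "(", tm$var, ")")
           else if (tm$power != 1) paste0(tm$var, "^", tm$power)
           else tm$var
    sprintf("%+g %s", tm$coef, rhs)
  }, "")
  cat(sprintf("S_%s = %g %s", x$nutrient, x$intercept, paste(tt, collapse = " ")))
  if (!is.na(x$R2)) cat(sprintf("   (R2 = %.2f)", x$R2))
  cat("\n")
  invisible(x)
}

.t3 <- function(nutrient, intercept, terms, R2, zone, source, family = "linear")
  supply_equation(nutrient, intercept, terms, family, R2 = R2,
                  zone = zone, source = source)

# Zone-calibrated and QUEFTS-default indigenous supply equations.
.supply_registry <- list(
  parameterized = list(
    NGS = list(
      N = .t3("N", -20.54, list(list(var = "OC_tot", coef = 0.60),
                                list(var = "N_tot", coef = 130.92)), 0.57,
               "NGS", "parameterized"),
      P = .t3("P", -12.16, list(list(var = "pH", coef = 2.71),
                                list(var = "P_av", coef = 0.71)), 0.61,
               "NGS", "parameterized"),
      K = .t3("K", 27.10, list(list(var = "K_exch", coef = 246.22)), 0.55,
               "NGS", "parameterized")),
    SS = list(
      N = .t3("N", 11.64, list(list(var = "N_tot", coef = 155.41, power = 3)),
               0.52, "SS", "parameterized", family = "polynomial"),
      P = .t3("P", -4.11, list(list(var = "pH", coef = 1.40),
                               list(var = "P_av", coef = 0.0005, power = 3)),
               0.66, "SS", "parameterized", family = "polynomial"),
      K = .t3("K", 228.73, list(list(var = "pH", coef = -35.30),
                                list(var = "K_exch", coef = 275.30)), 0.60,
               "SS", "parameterized")),
    All = list(
      N = .t3("N", 9.56, list(list(var = "N_tot", coef = 147.28, power = 2)),
               0.56, "All", "parameterized", family = "polynomial"),
      P = .t3("P", -8.35, list(list(var = "pH", coef = 2.20),
                               list(var = "P_av", coef = 0.43)), 0.50,
               "All", "parameterized"),
      K = .t3("K", 26.35, list(list(var = "K_exch", coef = 247.97)), 0.52,
               "All", "parameterized"))),
  janssen_default = list(
    NGS = list(
      N = .t3("N", 22.80, list(list(var = "OC_tot", coef = 2.54)), 0.11,
               "NGS", "janssen_default"),
      P = .t3("P", 5.46, list(list(var = "OC_tot", coef = -0.22),
                              list(var = "P_av", coef = 0.72)), 0.57,
               "NGS", "janssen_default"),
      K = .t3("K", 37.53, list(list(var = "OC_tot", coef = -1.60),
                               list(var = "K_exch", coef = 248.05)), 0.46,
               "NGS", "janssen_default")),
    SS = list(
      N = .t3("N", 24.87, list(list(var = "OC_tot", coef = 0.61)), 0.03,
               "SS", "janssen_default"),
      P = .t3("P", 3.29, list(list(var = "OC_tot", coef = -0.11),
                              list(var = "P_av", coef = 0.31)), 0.56,
               "SS", "janssen_default"),
      K = .t3("K", 39.13, list(list(var = "OC_tot", coef = -2.50),
                               list(var = "K_exch", coef = 237.21)), 0.36,
               "SS", "janssen_default")),
    All = list(
      N = .t3("N", 22.06, list(list(var = "OC_tot", coef = 2.36)), 0.10,
               "All", "janssen_default"),
      P = .t3("P", 4.74, list(list(var = "OC_tot", coef = 0.01),
                              list(var = "P_av", coef = 0.42)), 0.35,
               "All", "janssen_default"),
      K = .t3("K", 36.23, list(list(var = "OC_tot", coef = -1.53),
                               list(var = "K_exch", coef = 248.42)), 0.43,
               "All", "janssen_default"))))

#' Bundled indigenous supply equations
#'
#' Returns the bundled set of per-nutrient indigenous supply equations for
#' an agro-ecological zone, either the zone-calibrated forms or the
#' classic QUEFTS default forms.
#'
#' @inheritParams quefts_coefficients
#' @return Named list with `supply_eq` elements `N`, `P`, `K`.
#' @examples
#' eqs <- supply_equations("NGS")
#' predict(eqs$N, data.frame(OC_tot = 7.25, N_tot = 0.47))
#' @export
supply_equations <- function(zone = c("All", "NGS", "SS"),
                             source = c("parameterized", "janssen_default")) {
  zone <- match.arg(zone)
  source <- match.arg(source)
  .supply_registry[[source]][[zone]]
}

#' Indigenous soil nutrient supply
#'
#' Evaluates one nutrient's supply equation on a soil table.
#'
#' @param soil data.frame of soil properties.
#' @param eq a [supply_equation] object.
#' @return kg/ha of indigenous supply per field, floored at 0.
#' @export
indigenous_supply <- function(soil, eq) {
  stopifnot(inherits(eq, "supply_eq"))
  predict(eq, soil)
}

#' Fertilizer recovery fraction
#'
#' The fraction of an applied nutrient recovered in above-ground biomass:
#' `(U - U0) / F`, where `U` is uptake in the fully fertilized (NPK) plot,
#' `U0` uptake in the plot where the nutrient was omitted, and `F` the
#' applied rate. Plot-level values can be negative under field noise;
#' they are retained and averaged at zone level.
#'
#' @param U_npk uptake in the NPK plot (kg/ha).
#' @param U_omission uptake in the matching omission plot (kg/ha).
#' @param F_applied applied rate of the nutrient (kg/ha), must be > 0.
#' @return Recovery fraction (unitless), vectorised over plot pairs.
#' @export
recovery_fraction <- function(U_npk, U_omission, F_applied) {
  if (any(F_applied <= 0))
    stop("recovery fraction undefined when the applied rate is zero")
  (U_npk - U_omission) / F_applied
}

#' Total potential nutrient supply
#'
#' Step 1 of the QUEFTS chain: indigenous soil supply (from the bundled or
#' fitted equations) plus applied fertilizer times its average recovery
#' fraction.
#'
#' @param soil data.frame of soil properties, one row per field/plot.
#' @param eqs named list of [supply_equation] objects (`N`, `P`, `K`).
#' @param fertilizer applied rates: length-3 vector or n-by-3 matrix
#'   (kg/ha, N-P-K order); defaults to none.
#' @param coef a [quefts_coef] object supplying the recovery fractions.
#' @return n-by-3 matrix of potential supplies (kg/ha).
#' @examples
#' cf <- quefts_coefficients("NGS")
#' total_supply(data.frame(pH = 5.8, OC_tot = 7.25, N_tot = 0.47,
#'                         P_av = 8.43, K_exch = 0.22),
#'              supply_equations("NGS"), c(140, 50, 50), cf)
#' @export
total_supply <- function(soil, eqs, fertilizer = c(0, 0, 0), coef) {
  coef <- .check_coef(coef)
  stopifnot(all(c("N", "P", "K") %in% names(eqs)))
  n <- nrow(soil)
  if (is.null(dim(fertilizer)))
    fertilizer <- matrix(fertilizer, n, 3, byrow = TRUE)
  if (any(fertilizer < 0)) stop("applied rates must be non-negative")
  ind <- vapply(c("N", "P", "K"),
                function(i) indigenous_supply(soil, eqs[[i]]), numeric(n))
  ind <- matrix(ind, nrow = n, dimnames = list(NULL, c("N", "P", "K")))
  ind + sweep(fertilizer, 2, coef$recovery, `*`)
}
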