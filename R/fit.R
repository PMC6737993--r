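#' Multivariate outlier screening by Mahalanobis distance
#'
#' Flags records whose vector of soil properties, yields and uptakes is
#' an outlier of the multivariate cloud: the squared Mahalanobis distance
#' from the column means exceeds the chi-square quantile at `1 - alpha`
#' with as many degrees of freedom as screened variables. Location and
#' scatter are classical by default; `robust = TRUE` uses the minimum
#' covariance determinant estimate instead.
#'
#' @param records plot-record data.frame.
#' @param alpha significance level of the chi-square cutoff (default 0.05).
#' @param vars columns to screen; defaults to the numeric soil
#'   properties plus grain yield, total dry matter and the three derived
#'   uptakes.
#' @param robust use MCD location/scatter instead of classical.
#' @return List with `retained` and `removed` data.frames and the logical
#'   flag vector `is_outlier`.
#' @export
screen_outliers <- function(records, alpha = 0.05, vars = NULL,
                            robust = FALSE) {
  if (is.null(vars)) {
    U <- plot_uptake(records)
    X <- cbind(records[, intersect(c("pH", "OC_tot", "N_tot", "P_av", "K_exch"),
                                   names(records)), drop = FALSE],
               grain_yield = records$grain_yield,
               total_dm = records$grain_yield * 0.85 + records$stover_yield,
               U_N = U[, "N"], U_P = U[, "P"], U_K = U[, "K"])
  } else {
    X <- records[, vars, drop = FALSE]
  }
  X <- as.matrix(X)
  p <- ncol(X)
  if (nrow(X) < p + 2) stop("need at least p + 2 records to screen")

  if (robust) {
    est <- MASS::cov.rob(X, method = "mcd")
    ctr <- est$center; S <- est$cov
  } else {
    ctr <- colMeans(X); S <- stats::cov(X)
  }
  d2 <- tryCatch(stats::mahalanobis(X, ctr, S),
                 error = function(e) {
                   warning("singular covariance; using pseudo-inverse")
                   stats::mahalanobis(X, ctr, MASS::ginv(S), inverted = TRUE)
                 })
  cut <- stats::qchisq(1 - alpha, df = p)
  bad <- d2 > cut
  list(retained = records[!bad, , drop = FALSE],
       removed = records[bad, , drop = FALSE],
       is_outlier = bad)
}

#' Grain harvest index filter
#'
#' Drops plots with a grain harvest index below 0.40; such plots are
#' taken to have suffered stresses other than nutrients. A GHI of exactly
#' 0.40 is retained.
#'
#' @param records plot-record data.frame with a `ghi` column.
#' @param threshold exclusion threshold (plots with `ghi < threshold` are
#'   dropped; the boundary value is kept).
#' @return The retained records; the number removed is in attribute
#'   `"n_removed"`.
#' @export
filter_ghi <- function(records, threshold = 0.40) {
  keep <- records$ghi >= threshold
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Physiological efficiency from tissue composition
#'
#' The grain produced per kg of nutrient in the above-ground biomass,
#' computed from the grain harvest index and the nutrient mass fractions
#' of grain and stover: `1000 * GHI / (GHI * X_g + (1 - GHI) * X_s)`.
#'
#' @param ghi grain harvest index in (0, 1].
#' @param X_g,X_s nutrient mass fractions (g/kg) of grain and stover.
#' @return kg grain per kg nutrient, vectorised.
#' @export
physiological_efficiency <- function(ghi, X_g, X_s) {
  den <- ghi * X_g + (1 - ghi) * X_s
  if (any(den <= 0)) stop("zero denominator: grain and stover fractions both zero")
  1000 * ghi / den
}

#' Minimum uptake to produce any grain
#'
#' The minimum uptake of a nutrient among control plots with non-zero
#' grain yield.
#'
#' @param records plot-record data.frame.
#' @param nutrient `"N"`, `"P"` or `"K"`.
#' @return r (kg/ha).
#' @export
fit_minimum_uptake <- function(records, nutrient) {
  nutrient <- match.arg(nutrient, c("N", "P", "K"))
  ctl <- records[records$treatment == "control" & records$grain_yield > 0, ,
                 drop = FALSE]
  if (nrow(ctl) == 0) stop("no control plots with non-zero grain yield")
  min(plot_uptake(ctl)[, nutrient])
}

#' Boundary-line physiological efficiency envelope
#'
#' Estimates the envelope slopes of the yield-versus-uptake cloud for one
#' nutrient: each plot contributes the slope of the line through the
#' minimum-uptake point `(r, 0)`, `s = grain_yield / (U - r)`, and the
#' envelope at maximum accumulation (`a`) and maximum dilution (`d`) is
#' read off as lower and upper quantiles of those slopes.
#'
#' @param records plot-record data.frame (after the GHI filter).
#' @param r minimum uptake for the nutrient (kg/ha), see
#'   [fit_minimum_uptake()].
#' @param nutrient `"N"`, `"P"` or `"K"`.
#' @param q_low,q_high slope quantiles defining the envelope
#'   (defaults 0.025 and 0.975).
#' @param min_n minimum number of usable plots.
#' @param min_gap ill-conditioning guard: plots whose net uptake `U - r`
#'   is below this fraction of the median net uptake are excluded, since
#'   their slope `yield / (U - r)` amplifies measurement noise
#'   hyperbolically as `U` approaches `r`.
#' @return Named numeric vector `c(a =, d =)`.
#' @export
fit_boundary_lines <- function(records, r, nutrient, q_low = 0.025,
                               q_high = 0.975, min_n = 30, min_gap = 0.1) {
  nutrient <- match.arg(nutrient, c("N", "P", "K"))
  U <- plot_uptake(records)[, nutrient]
  keep <- U > r & records$grain_yield > 0
  gap <- min_gap * stats::median(U[keep] - r)
  keep <- keep & (U - r) > gap
  if (sum(keep) < min_n)
    stop("insufficient data for boundary lines: ", sum(keep), " usable plots")
  s <- records$grain_yield[keep] / (U[keep] - r)
  q <- stats::quantile(s, c(q_low, q_high), names = FALSE, type = 7)
  c(a = q[1], d = q[2])
}

# candidate basis sets per family for one predictor
.family_terms <- function(family, var, x) {
  switch(family,
    linear = list(list(var = var, coef = NA_real_, power = 1)),
    polynomial = list(list(var = var, coef = NA_real_, power = 1),
                      list(var = var, coef = NA_real_, power = 2),
                      list(var = var, coef = NA_real_, power = 3)),
    logarithmic = list(list(var = var, coef = NA_real_, trans = "log")),
    exponential = list(list(var = var, coef = NA_real_, trans = "exp",
                            scale = max(abs(x), 1e-9))),
    stop("unknown family: ", family))
}

.design_col <- function(tm, soil) {
  x <- soil[[tm$var]]
  if (!is.null(tm$trans)) {
    switch(tm$trans,
           log = log(x),
           exp = exp(x / tm$scale))
  } else x^tm$power
}

#' Best-subset supply equation fit
#'
#' Fits the indigenous supply of one nutrient (its uptake in the plots
#' where it was omitted) against topsoil properties, over all predictor
#' subsets and functional families (linear, polynomial with single power
#' terms of degree 2 or 3, logarithmic, exponential, and a one-predictor
#' Cauchy peak fitted by nonlinear least squares). The equation with the
#' smallest Bayesian information criterion wins; ties go to fewer terms,
#' then to the family order just given.
#'
#' @param soils soil table (one row per observation, same order as
#'   `uptake`).
#' @param uptake observed uptake of the nutrient in its omission plots
#'   (kg/ha).
#' @param nutrient `"N"`, `"P"` or `"K"`.
#' @param predictors candidate soil property columns.
#' @param families candidate functional families.
#' @param max_terms largest predictor subset size.
#' @return A [supply_equation] with `R2` and `BIC` filled in.
#' @export
fit_supply_equation <- function(soils, uptake, nutrient,
                                predictors = c("pH", "OC_tot", "N_tot",
                                               "P_av", "K_exch"),
                                families = c("linear", "polynomial",
                                             "logarithmic", "exponential",
                                             "cauchy"),
                                max_terms = 3) {
  nutrient <- match.arg(nutrient, c("N", "P", "K"))
  if (length(uptake) < 10) stop("need at least 10 observations")
  n <- length(uptake)
  bic_of <- function(rss, k) n * log(max(rss, 1e-10) / n) + k * log(n)

  best <- NULL
  consider <- function(cand) {
    if (is.null(best) ||
        cand$BIC < best$BIC - 1e-9 ||
        (abs(cand$BIC - best$BIC) <= 1e-9 && cand$k < best$k))
      best <<- cand
  }

  # intercept-only baseline
  rss0 <- sum((uptake - mean(uptake))^2)
  consider(list(BIC = bic_of(rss0, 2), k = 0, R2 = 0, family = "linear",
                intercept = mean(uptake), terms = list()))

  subsets <- unlist(lapply(seq_len(min(max_terms, length(predictors))),
                           function(k) utils::combn(predictors, k,
                                                    simplify = FALSE)),
                    recursive = FALSE)
  for (family in setdiff(families, "cauchy")) {
    for (vars in subsets) {
      # one basis choice per predictor; polynomial tries power 2 and 3
      choices <- lapply(vars, function(v) .family_terms(family, v, soils[[v]]))
      grid <- expand.grid(lapply(choices, seq_along))
      for (g in seq_len(nrow(grid))) {
        terms <- lapply(seq_along(vars), function(j)
          choices[[j]][[grid[g, j]]])
        X <- vapply(terms, .design_col, numeric(n), soil = soils)
        X <- matrix(X, nrow = n)
        if (any(!is.finite(X))) next
        fit <- stats::lm.fit(cbind(1, X), uptake)
        if (fit$rank < ncol(X) + 1) next           # collinear: skip subset
        rss <- sum(fit$residuals^2)
        cand <- list(BIC = bic_of(rss, length(terms) + 2), k = length(terms),
                     R2 = 1 - rss / rss0, family = family,
                     intercept = fit$coefficients[1],
                     terms = lapply(seq_along(terms), function(j) {
                       tm <- terms[[j]]
                       tm$coef <- unname(fit$coefficients[j + 1])
                       tm
                     }))
        consider(cand)
      }
    }
  }

  if ("cauchy" %in% families) {
    for (v in predictors) {
      x <- soils[[v]]
      st <- list(c0 = min(uptake), c1 = diff(range(uptake)),
                 loc = stats::median(x),
                 scale = max(stats::IQR(x), 1e-3))
      fit <- tryCatch(
        suppressWarnings(
          stats::nls(uptake ~ c0 + c1 / (1 + ((x - loc) / scale)^2),
                     start = st,
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE))),
        error = function(e) NULL)
      if (is.null(fit)) next
      co <- stats::coef(fit)
      if (!all(is.finite(co)) || co[["scale"]] <= 0) next
      rss <- sum(stats::residuals(fit)^2)
      consider(list(BIC = bic_of(rss, 6), k = 1,
                    R2 = 1 - rss / rss0, family = "cauchy",
                    intercept = co[["c0"]],
                    terms = list(list(var = v, coef = co[["c1"]],
                                      trans = "cauchy", loc = co[["loc"]],
                                      scale = co[["scale"]]))))
    }
  }

  supply_equation(nutrient, unname(best$intercept), best$terms,
                  family = best$family, R2 = best$R2, BIC = best$BIC,
                  source = "fitted")
}

#' Field-level calibration/validation split
#'
#' Randomly assigns whole fields (all their plots together) to the
#' calibration or validation partition.
#'
#' @param records plot-record data.frame with a `field_id` column.
#' @param fraction calibration share of fields (default 0.8).
#' @param seed optional integer seed.
#' @return List with `calibration` and `validation` data.frames.
#' @export
split_calibration_validation <- function(records, fraction = 0.8,
                                         seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(records$field_id)
  n_cal <- round(fraction * length(ids))
  cal_ids <- sample(ids, n_cal)
  list(calibration = records[records$field_id %in% cal_ids, , drop = FALSE],
       validation = records[!records$field_id %in% cal_ids, , drop = FALSE])
}

#' Fit the QUEFTS model to nutrient omission trial data
#'
#' The full parameterization pipeline: multivariate outlier screening,
#' grain-harvest-index filtering, a field-level calibration/validation
#' split, then estimation of all model components on the calibration
#' partition: minimum uptakes from control plots, boundary-line
#' physiological efficiencies, indigenous supply equations from the
#' omission plots, and average fertilizer recovery fractions from
#' NPK/omission plot pairs.
#'
#' @param data plot-record data.frame (see [read_plot_table()] for the
#'   column layout).
#' @param zone zone label carried into the fitted coefficients.
#' @param ymax maximum potential yield (kg/ha).
#' @param alpha outlier-screening significance level.
#' @param split_fraction calibration share of fields.
#' @param seed integer seed controlling the random split.
#' @param q_low,q_high boundary-line slope quantiles.
#' @param uptake_combine passed to [quefts_yield()] at prediction time.
#' @return An object of class `"quefts"` with components `coef`
#'   (a [quefts_coef]), `supply_eqs`, `report` (record counts), the two
#'   data partitions, and the call.
#' @examples
#' gen <- quefts_generator("NGS", n_fields = 60)
#' trials <- generate_trials(gen, seed = 1)
#' fit <- quefts(trials, zone = "NGS", seed = 1)
#' coef(fit)
#' @export
quefts <- function(data, zone = "All", ymax = 10000, alpha = 0.05,
                   split_fraction = 0.8, seed = NULL,
                   q_low = 0.025, q_high = 0.975,
                   uptake_combine = c("min", "mean")) {
  uptake_combine <- match.arg(uptake_combine)
  cl <- match.call()
  n_input <- nrow(data)

  sc <- screen_outliers(data, alpha = alpha)
  clean <- sc$retained
  n_outliers <- nrow(sc$removed)

  clean <- filter_ghi(clean)
  n_ghi <- attr(clean, "n_removed")

  parts <- split_calibration_validation(clean, split_fraction, seed = seed)
  cal <- parts$calibration

  nm <- c("N", "P", "K")
  r <- vapply(nm, function(i) fit_minimum_uptake(cal, i), 0)
  ad <- vapply(nm, function(i) fit_boundary_lines(cal, r[[i]], i,
                                                  q_low, q_high), numeric(2))

  # supply equations from the matching omission plots
  omis <- c(N = "minusN", P = "minusP", K = "minusK")
  Ucal <- plot_uptake(cal)
  eqs <- lapply(nm, function(i) {
    rows <- cal$treatment == omis[[i]]
    fit_supply_equation(cal[rows, , drop = FALSE], Ucal[rows, i], i)
  })
  names(eqs) <- nm

  # recovery fractions over NPK/omission pairs matched by field
  rec <- vapply(nm, function(i) {
    npk <- cal[cal$treatment == "NPK", c("field_id", "applied_N", "applied_P",
                                         "applied_K")]
    om <- cal[cal$treatment == omis[[i]], "field_id"]
    common <- intersect(npk$field_id, om)
    if (length(common) == 0) return(NA_real_)
    u1 <- Ucal[cal$treatment == "NPK", i][match(common, npk$field_id)]
    u0 <- Ucal[cal$treatment == omis[[i]], i][match(common, om)]
    Fi <- cal[cal$treatment == "NPK",
              paste0("applied_", i)][match(common, npk$field_id)]
    mean(recovery_fraction(u1, u0, Fi))
  }, 0)

  coef <- quefts_coef(a = ad["a", ], d = ad["d", ], r = r, recovery = rec,
                      ymax = ymax, zone = zone, source = "fitted")

  structure(list(
    coef = coef, supply_eqs = eqs,
    report = list(n_input = n_input, n_outliers_removed = n_outliers,
                  n_ghi_removed = n_ghi,
                  n_calibration = nrow(cal),
                  n_validation = nrow(parts$validation),
                  seed = seed),
    calibration = cal, validation = parts$validation,
    uptake_combine = uptake_combine, call = cl),
    class = "quefts")
}
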