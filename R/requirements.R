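#' Balanced nutrient uptake for a target yield
#'
#' Finds the uptake triple at which a target yield is produced with all
#' three nutrients simultaneously balanced, by scaling a supply triple
#' along a fixed ratio: the scale is solved by 1-D root finding so that
#' the ultimate yield estimate equals the target, the ratio is then
#' updated to the resulting uptake ratio, and the two steps are iterated
#' (with damping) to a fixed point.
#'
#' @param target_yield target grain yield (kg/ha), in (0, ymax].
#' @param coef a [quefts_coef] object.
#' @param uptake_combine passed to [quefts_yield()].
#' @param tol relative convergence tolerance on the uptake ratio.
#' @param max_iter maximum ratio updates (the damped iteration contracts
#'   slowly, so the default is generous).
#' @return List with `uptake` (kg/ha, named), `supply` (kg/ha, named),
#'   `yield` (achieved, kg/ha) and `iterations`.
#' @examples
#' balanced_uptake(4000, quefts_coefficients("NGS"))$uptake
#' @export
balanced_uptake <- function(target_yield, coef,
                            uptake_combine = c("min", "mean"),
                            tol = 1e-6, max_iter = 400) {
  coef <- .check_coef(coef)
  uptake_combine <- match.arg(uptake_combine)
  if (target_yield <= 0) stop("target yield must be positive")
  if (target_yield > coef$ymax)
    stop("infeasible target: exceeds the potential yield ymax")

  ratio <- coef$r + target_yield / ((coef$a + coef$d) / 2)
  ratio <- ratio / sum(ratio)
  res <- NULL
  for (it in seq_len(max_iter)) {
    f <- function(l) quefts_yield(l * ratio, coef, uptake_combine)$yield -
      target_yield
    hi <- 10
    while (f(hi) < 0 && hi < 1e8) hi <- hi * 2
    if (f(hi) < 0)
      stop("infeasible target: yield ", target_yield,
           " not attainable along the supply ray")
    lam <- stats::uniroot(f, c(1e-9, hi), tol = 1e-10)$root
    res <- quefts_yield(lam * ratio, coef, uptake_combine)
    newr <- res$uptake[1, ] / sum(res$uptake[1, ])
    newr <- 0.5 * newr + 0.5 * ratio
    delta <- max(abs(newr - ratio) / pmax(ratio, 1e-12))
    ratio <- newr
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("balanced-uptake ratio iteration did not fully converge (",
            signif(delta, 3), " relative)")
  list(uptake = res$uptake[1, ], supply = lam * ratio,
       yield = res$yield, iterations = it)
}

#' Balanced uptake requirement curve
#'
#' Tabulates, per target yield, the balanced N, P and K uptake and its
#' per-tonne expression (the reciprocal physiological efficiency, RPhE,
#' kg nutrient per tonne grain).
#'
#' Two procedures are available. `method = "population"` reproduces the
#' requirement table the way it is derived for a trial region: the
#' forward model is run over a (simulated) population of fields of the
#' zone at the recommended NPK rates, and a saturating uptake-yield curve
#' with plateau at `ymax` is fitted per nutrient,
#' `U = beta * (-ymax * log(1 - Y/ymax))`; requirements are read off that
#' curve. `method = "search"` instead runs the coefficient-only balanced
#' search of [balanced_uptake()] at each target.
#'
#' @param coef a [quefts_coef] object.
#' @param targets target yields (kg/ha), sorted increasing.
#' @param method `"population"` or `"search"` (see Details).
#' @param zone zone whose field population to simulate (defaults to
#'   `coef$zone`); used by the population method only.
#' @param n_fields number of simulated fields for the population method.
#' @param seed integer seed for the simulated field population.
#' @param eqs supply equations for the population method (defaults to the
#'   bundled parameterized set of `zone`).
#' @param ... passed to [balanced_uptake()] for the search method.
#' @return data.frame of class `"quefts_requirements"` with columns
#'   `target_yield`, `U_N`, `U_P`, `U_K` (kg/ha), `RPhE_N`, `RPhE_P`,
#'   `RPhE_K` (kg/t, rounded to 0.1), and `PhE_N`, `PhE_P`, `PhE_K`
#'   (kg grain per kg nutrient).
#' @examples
#' requirement_curve(quefts_coefficients("NGS"), targets = c(2, 4, 6) * 1000,
#'                   n_fields = 200, seed = 1)
#' @export
requirement_curve <- function(coef, targets = seq(1000, 9000, by = 1000),
                              method = c("population", "search"),
                              zone = NULL, n_fields = 2000, seed = 1,
                              eqs = NULL, ...) {
  coef <- .check_coef(coef)
  method <- match.arg(method)
  if (is.unsorted(targets) || any(targets <= 0) || any(targets > coef$ymax))
    stop("targets must be increasing and within (0, ymax]")

  if (method == "population") {
    if (is.null(zone)) zone <- coef$zone
    if (!zone %in% c("NGS", "SS", "All"))
      stop("population method needs a study zone ('NGS', 'SS' or 'All')")
    U <- .population_requirements(coef, targets, zone, n_fields, seed, eqs)
  } else {
    U <- t(vapply(targets, function(y)
      balanced_uptake(y, coef, ...)$uptake, numeric(3)))
  }

  rphe <- round(U * 1000 / targets, 1)
  out <- data.frame(target_yield = targets,
                    U_N = U[, 1], U_P = U[, 2], U_K = U[, 3],
                    RPhE_N = rphe[, 1], RPhE_P = rphe[, 2], RPhE_K = rphe[, 3],
                    PhE_N = 1000 / rphe[, 1], PhE_P = 1000 / rphe[, 2],
                    PhE_K = 1000 / rphe[, 3])
  attr(out, "zone") <- coef$zone
  attr(out, "method") <- method
  class(out) <- c("quefts_requirements", "data.frame")
  out
}

# population procedure: simulate the zone's fields, run the forward model
# at recommended rates, fit U = beta * z(Y) with z = -ymax*log(1 - Y/ymax)
.population_requirements <- function(coef, targets, zone, n_fields, seed,
                                     eqs = NULL) {
  gen <- quefts_generator(zone, n_fields = n_fields, coef = coef,
                          eqs = if (is.null(eqs)) supply_equations(zone)
                                else eqs)
  soils <- generate_soils(gen, seed = seed)
  rates <- list(NGS = c(140, 50, 50), SS = c(120, 40, 40))
  Fz <- t(vapply(soils$zone, function(z)
    if (!is.null(gen$rates)) gen$rates else rates[[z]], numeric(3)))
  S <- total_supply(soils, gen$eqs, Fz, coef)
  res <- quefts_yield(S, coef)

  keep <- res$yield > 100 & res$yield < 0.99 * coef$ymax
  z <- -log(1 - res$yield[keep] / coef$ymax) * coef$ymax
  zt <- -log(1 - targets / coef$ymax) * coef$ymax
  U <- vapply(c("N", "P", "K"), function(i) {
    u <- res$uptake[keep, i]
    beta <- sum(u^2) / sum(u * z)     # slope of z ~ u through the origin
    beta * zt
  }, numeric(length(targets)))
  matrix(U, ncol = 3, dimnames = list(NULL, c("N", "P", "K")))
}

#' @export
print.quefts_requirements <- function(x, ...) {
  cat("Balanced uptake requirements (", attr(x, "zone"), ", method: ",
      attr(x, "method"), ")\n", sep = "")
  print.data.frame(cbind(`yield (t/ha)` = x$target_yield / 1000,
                         round(x[, c("RPhE_N", "RPhE_P", "RPhE_K")], 1)),
                   row.names = FALSE)
  invisible(x)
}
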