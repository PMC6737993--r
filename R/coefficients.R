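#' Crop coefficient sets for the QUEFTS maize model
#'
#' Constructs the set of crop coefficients that drive the QUEFTS engine:
#' per-nutrient physiological efficiency at maximum accumulation (`a`, kg
#' grain per kg nutrient), at maximum dilution (`d`, kg grain per kg
#' nutrient), minimum uptake required to produce any grain (`r`, kg/ha),
#' average fertilizer recovery fractions (`recovery`, unitless), and the
#' maximum attainable (potential) yield `ymax` (kg/ha).
#'
#' `quefts_coef()` builds a coefficient set from explicit values;
#' `quefts_coefficients()` returns one of the bundled sets: maize
#' coefficients calibrated for the Northern Guinea Savanna (`"NGS"`), the
#' Sudan Savanna (`"SS"`), the two zones combined (`"All"`), or the
#' original QUEFTS defaults of Janssen and co-workers
#' (`source = "janssen_default"`).
#'
#' @param a,d,r numeric length-3 vectors, in N, P, K order.
#' @param recovery numeric length-3 vector of fertilizer recovery
#'   fractions in N, P, K order.
#' @param ymax maximum potential grain yield in kg/ha.
#' @param zone optional label carried along for reporting.
#' @param source label of the coefficient provenance.
#'
#' @return An object of class `"quefts_coef"`: a list with elements
#'   `a`, `d`, `r` (named numeric vectors over `c("N","P","K")`),
#'   `recovery`, `ymax`, `zone`, `source`.
#' @examples
#' cf <- quefts_coefficients("NGS")
#' cf$a
#' @export
quefts_coef <- function(a, d, r, recovery = c(N = 0.5, P = 0.1, K = 0.5),
                        ymax = 10000, zone = "custom", source = "user") {
  nm <- c("N", "P", "K")
  a <- stats::setNames(as.numeric(a), nm)
  d <- stats::setNames(as.numeric(d), nm)
  r <- stats::setNames(as.numeric(r), nm)
  recovery <- stats::setNames(as.numeric(recovery), nm)
  if (any(!is.finite(a)) || any(!is.finite(d)) || any(!is.finite(r)))
    stop("coefficients must be finite")
  if (any(a <= 0) || any(d <= 0))
    stop("physiological efficiencies 'a' and 'd' must be positive")
  if (any(a >= d))
    stop("invalid coefficients: 'a' (maximum accumulation) must be ",
         "strictly smaller than 'd' (maximum dilution) for every nutrient")
  if (any(r < 0)) stop("minimum uptake 'r' must be non-negative")
  if (!is.numeric(ymax) || length(ymax) != 1L || ymax <= 0)
    stop("'ymax' must be a single positive number (kg/ha)")
  structure(
    list(a = a, d = d, r = r, recovery = recovery, ymax = ymax,
         zone = zone, source = source),
    class = "quefts_coef"
  )
}

# Calibrated maize coefficients for the Northern Nigerian savanna zones and
# the original QUEFTS defaults. Units: a, d kg grain / kg nutrient;
# r kg/ha; recovery unitless.
.quefts_coef_registry <- list(
  NGS = list(a = c(35, 200, 25), d = c(79, 527, 117), r = c(4.0, 0.5, 4.5),
             recovery = c(0.42, 0.16, 0.54)),
  SS = list(a = c(32, 164, 24), d = c(79, 528, 136), r = c(6.1, 0.8, 7.3),
            recovery = c(0.32, 0.08, 0.37)),
  All = list(a = c(35, 199, 24), d = c(79, 528, 124), r = c(4.0, 0.5, 4.5),
             recovery = c(0.40, 0.15, 0.52)),
  janssen_default = list(a = c(30, 200, 30), d = c(70, 600, 120),
                         r = c(5.0, 0.4, 2.0), recovery = c(0.50, 0.10, 0.50))
)

#' @rdname quefts_coef
#' @param ... passed on to `quefts_coef()` (e.g. `ymax`).
#' @export
quefts_coefficients <- function(zone = c("All", "NGS", "SS"),
                                source = c("parameterized", "janssen_default"),
                                ...) {
  zone <- match.arg(zone)
  source <- match.arg(source)
  key <- if (source == "janssen_default") "janssen_default" else zone
  p <- .quefts_coef_registry[[key]]
  quefts_coef(a = p$a, d = p$d, r = p$r, recovery = p$recovery,
              zone = zone, source = source, ...)
}

#' @export
print.quefts_coef <- function(x, ...) {
  cat("QUEFTS crop coefficients (", x$zone, ", ", x$source, ")\n", sep = "")
  m <- rbind(a = x$a, d = x$d, r = x$r, recovery = x$recovery)
  print(round(m, 3))
  cat("ymax:", x$ymax, "kg/ha\n")
  invisible(x)
}

.check_coef <- function(coef) {
  if (!inherits(coef, "quefts_coef"))
    stop("'coef' must be a 'quefts_coef' object; see quefts_coefficients()")
  coef
}
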