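#' Read and write plot-level trial tables
#'
#' Plot tables are plain CSV, one row per treatment plot, with columns:
#' `field_id`, `zone` (`NGS`/`SS`), `season`, `variety_group`
#' (`OPV`/`hybrid`), `treatment` (`control`, `minusN`, `minusP`, `minusK`,
#' `NPK`, `NPKplus`), soil properties `pH` (1:1 water), `OC_tot` (g/kg),
#' `N_tot` (g/kg), `P_av` (mg/kg Mehlich-3), `K_exch` (cmol_c/kg), applied
#' rates `applied_N/P/K` (kg/ha), `grain_yield` (kg/ha at 15% moisture),
#' `stover_yield` (kg/ha oven-dry), `ghi` (grain harvest index), and
#' tissue mass fractions `grain_N/P/K`, `stover_N/P/K` (g/kg dry matter).
#'
#' Reading validates the schema and flags likely unit mistakes (e.g.
#' `P_av` above 1000 mg/kg, `ghi` outside \code{[0, 1]}).
#'
#' @param path file path.
#' @param records plot-record data.frame.
#' @return `read_plot_table()` returns the validated data.frame;
#'   `write_plot_table()` returns `path` invisibly.
#' @export
read_plot_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("field_id", "zone", "season", "variety_group", "treatment",
            "pH", "OC_tot", "N_tot", "P_av", "K_exch",
            "applied_N", "applied_P", "applied_K",
            "grain_yield", "stover_yield", "ghi",
            "grain_N", "grain_P", "grain_K",
            "stover_N", "stover_P", "stover_K")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("plot table is missing columns: ", paste(miss, collapse = ", "))
  ok_tr <- c("control", "minusN", "minusP", "minusK", "NPK", "NPKplus")
  bad <- which(!x$treatment %in% ok_tr)
  if (length(bad))
    stop("unknown treatment code '", x$treatment[bad[1]], "' in row ", bad[1])
  if (any(x$ghi < 0 | x$ghi > 1))
    stop("ghi outside [0, 1] in row ", which(x$ghi < 0 | x$ghi > 1)[1])
  if (any(x$P_av > 1000))
    warning("P_av above 1000 mg/kg: check units (expected mg/kg Mehlich-3)")
  if (any(x$grain_yield < 0 | x$stover_yield < 0))
    stop("negative yields in plot table")
  x
}

#' @rdname read_plot_table
#' @export
write_plot_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

.coef_to_list <- function(coef) {
  list(zone = coef$zone, source = coef$source, ymax = coef$ymax,
       a = as.list(coef$a), d = as.list(coef$d), r = as.list(coef$r),
       recovery = as.list(coef$recovery))
}

.eq_to_list <- function(eq) {
  list(nutrient = eq$nutrient, family = eq$family,
       intercept = eq$intercept, R2 = eq$R2,
       terms = lapply(eq$terms, function(tm) tm[!vapply(tm, is.null, TRUE)]))
}

#' Write and read coefficient files
#'
#' Serializes a crop coefficient set, its supply equations and recovery
#' fractions to a structured YAML file, and reads them back. The round
#' trip is exact to full double precision (numbers are written with 17
#' significant digits).
#'
#' @param coef a [quefts_coef] object.
#' @param eqs named list of [supply_equation] objects (`N`, `P`, `K`),
#'   optional.
#' @param path file path (`.yaml`).
#' @return `read_coefficients()` returns `list(coef =, eqs =)`;
#'   `write_coefficients()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_coefficients(quefts_coefficients("NGS"), supply_equations("NGS"), f)
#' cs <- read_coefficients(f)
#' cs$coef$a
#' @export
write_coefficients <- function(coef, eqs = NULL, path) {
  coef <- .check_coef(coef)
  obj <- list(format = "quefts_coefficients", version = 1L,
              coefficients = .coef_to_list(coef))
  if (!is.null(eqs))
    obj$supply_equations <- lapply(eqs, .eq_to_list)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_coefficients
#' @param zone for bundle files holding several zones, which one to
#'   return.
#' @export
read_coefficients <- function(path, zone = NULL) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "quefts_coefficients"))
    stop("not a coefficient file: ", path)
  if (!identical(as.integer(obj$version), 1L))
    warning("coefficient file version ", obj$version,
            " differs from the supported version 1")
  if (!is.null(obj$sets)) {
    zones <- vapply(obj$sets, function(s) s$coefficients$zone, "")
    if (is.null(zone)) {
      out <- lapply(obj$sets, .parse_coef_set)
      names(out) <- zones
      return(out)
    }
    k <- match(zone, zones)
    if (is.na(k)) stop("zone '", zone, "' not in file (has: ",
                       paste(zones, collapse = ", "), ")")
    return(.parse_coef_set(obj$sets[[k]]))
  }
  .parse_coef_set(obj)
}

.parse_coef_set <- function(obj) {
  co <- obj$coefficients
  coef <- quefts_coef(a = unlist(co$a), d = unlist(co$d), r = unlist(co$r),
                      recovery = unlist(co$recovery), ymax = co$ymax,
                      zone = co$zone, source = co$source)
  eqs <- NULL
  if (!is.null(obj$supply_equations)) {
    eqs <- lapply(obj$supply_equations, function(e)
      supply_equation(e$nutrient, e$intercept, e$terms, family = e$family,
                      R2 = if (is.null(e$R2)) NA_real_ else e$R2,
                      zone = co$zone, source = co$source))
    names(eqs) <- vapply(eqs, `[[`, "", "nutrient")
  }
  list(coef = coef, eqs = eqs)
}

#' Path to a bundled coefficient file
#'
#' The package ships two coefficient bundles: the zone-calibrated maize
#' set (`"parameterized"`) and the classic QUEFTS default set
#' (`"janssen_default"`), each holding the NGS, SS and combined-zone
#' entries with their supply equations.
#'
#' @param source which bundle.
#' @return File path inside the installed package.
#' @examples
#' cs <- read_coefficients(bundled_coefficients("parameterized"), "NGS")
#' cs$coef$a
#' @export
bundled_coefficients <- function(source = c("parameterized",
                                            "janssen_default")) {
  source <- match.arg(source)
  system.file("extdata", paste0("coefficients_", source, ".yaml"),
              package = "queftsr", mustWork = TRUE)
}
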