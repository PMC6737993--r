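#' Synthetic nutrient-omission-trial generator
#'
#' Builds the configuration for simulating on-farm nutrient omission
#' trials with the statistical structure the analysis pipeline assumes:
#' per-zone topsoil property distributions (right-skewed, truncated to the
#' observed ranges, with organic carbon and total N correlated), the
#' six-treatment omission design (control, -N, -P, -K, NPK, NPK+ at the
#' zone's recommended rates), deterministic QUEFTS yields from true
#' coefficients and supply equations, multiplicative lognormal field
#' noise, and tissue concentrations back-computed so that derived uptakes
#' are exactly consistent with the recorded yields.
#'
#' Zone soil distributions default to the observed topsoil summary of the
#' Northern Guinea Savanna (NGS) and Sudan Savanna (SS) trial fields
#' (mean, CV%, range): each property is drawn from a lognormal matched to
#' the mean and CV and rejected outside the range. For `zone = "All"`,
#' half the fields follow each zone's distribution and rates.
#'
#' @param zone `"NGS"`, `"SS"` or `"All"`.
#' @param n_fields number of experimental fields.
#' @param coef true crop coefficients, a [quefts_coef] object.
#' @param eqs true supply equations, as from [supply_equations()].
#' @param rates applied N-P-K rates (kg/ha) in fully fertilized plots;
#'   defaults to 140/50/50 in the NGS and 120/40/40 in the SS.
#' @param yield_cv multiplicative lognormal noise sd on grain yield.
#' @param uptake_cv multiplicative lognormal noise sd on each uptake.
#' @param ghi_mean,ghi_sd,ghi_range truncated-normal grain harvest index.
#' @param outlier_frac fraction of plot records inflated into gross
#'   multivariate outliers (yields and uptakes multiplied by
#'   `outlier_scale`).
#' @param outlier_scale multiplier applied to planted outliers.
#' @param rho_oc_n latent Gaussian correlation between OC_tot and N_tot.
#' @param soil_dist optional replacement soil-property distributions: a
#'   named list with entries `pH`, `OC_tot`, `N_tot`, `P_av`, `K_exch`,
#'   each `c(mean, cv, min, max)`; defaults to the observed zone summary.
#' @return An object of class `"quefts_generator"` (a list of settings).
#' @seealso [generate_soils()], [generate_trials()]
#' @export
quefts_generator <- function(zone = c("NGS", "SS", "All"), n_fields = 100,
                             coef = NULL, eqs = NULL, rates = NULL,
                             yield_cv = 0.15, uptake_cv = 0.10,
                             ghi_mean = 0.46, ghi_sd = 0.05,
                             ghi_range = c(0.25, 0.65),
                             outlier_frac = 0, outlier_scale = 10,
                             rho_oc_n = 0.8, soil_dist = NULL) {
  zone <- match.arg(zone)
  if (is.null(coef)) coef <- quefts_coefficients(zone)
  if (is.null(eqs)) eqs <- supply_equations(zone)
  if (is.null(rates))
    rates <- list(NGS = c(140, 50, 50), SS = c(120, 40, 40),
                  All = NULL)[[zone]]
  stopifnot(n_fields >= 1, yield_cv >= 0, uptake_cv >= 0,
            outlier_frac >= 0, outlier_frac < 1)
  structure(list(zone = zone, n_fields = n_fields, coef = coef, eqs = eqs,
                 rates = rates, yield_cv = yield_cv, uptake_cv = uptake_cv,
                 ghi_mean = ghi_mean, ghi_sd = ghi_sd, ghi_range = ghi_range,
                 outlier_frac = outlier_frac, outlier_scale = outlier_scale,
                 rho_oc_n = rho_oc_n, soil_dist = soil_dist),
            class = "quefts_generator")
}

# observed topsoil summaries per zone: mean, CV (fraction), min, max
.soil_dist <- list(
  NGS = list(pH = c(5.80, 0.08, 4.80, 7.20),
             OC_tot = c(7.25, 0.36, 2.44, 15.45),
             N_tot = c(0.47, 0.30, 0.25, 0.98),
             P_av = c(8.43, 0.82, 0.64, 31.77),
             K_exch = c(0.22, 0.78, 0.06, 1.35)),
  SS = list(pH = c(6.20, 0.09, 5.20, 7.20),
            OC_tot = c(5.01, 0.36, 2.04, 10.12),
            N_tot = c(0.36, 0.36, 0.17, 0.66),
            P_av = c(16.54, 0.71, 1.44, 50.00),
            K_exch = c(0.24, 0.43, 0.07, 0.50)))

.lnorm_pars <- function(m, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# truncated lognormal through a standard-normal latent value
.q_trunc_lnorm <- function(z, m, cv, lo, hi) {
  p <- .lnorm_pars(m, cv)
  if (cv == 0) return(rep(m, length(z)))
  plo <- stats::plnorm(lo, p[1], p[2]); phi <- stats::plnorm(hi, p[1], p[2])
  stats::qlnorm(plo + (phi - plo) * stats::pnorm(z), p[1], p[2])
}

.gen_soils_one <- function(zone, n, rho, dist = NULL) {
  d <- if (is.null(dist)) .soil_dist[[zone]] else dist
  z_oc <- stats::rnorm(n)
  z_nt <- rho * z_oc + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(
    zone = zone,
    pH = .q_trunc_lnorm(stats::rnorm(n), d$pH[1], d$pH[2], d$pH[3], d$pH[4]),
    OC_tot = .q_trunc_lnorm(z_oc, d$OC_tot[1], d$OC_tot[2], d$OC_tot[3], d$OC_tot[4]),
    N_tot = .q_trunc_lnorm(z_nt, d$N_tot[1], d$N_tot[2], d$N_tot[3], d$N_tot[4]),
    P_av = .q_trunc_lnorm(stats::rnorm(n), d$P_av[1], d$P_av[2], d$P_av[3], d$P_av[4]),
    K_exch = .q_trunc_lnorm(stats::rnorm(n), d$K_exch[1], d$K_exch[2],
                            d$K_exch[3], d$K_exch[4]),
    stringsAsFactors = FALSE)
}

#' Simulate field topsoil properties
#'
#' Draws one row of topsoil properties per field from the generator's
#' zone distributions (truncated lognormal matched to mean and CV, with
#' OC_tot and N_tot coupled through a latent Gaussian factor).
#'
#' @param config a [quefts_generator] object.
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns `field_id`, `zone`, `pH`, `OC_tot`,
#'   `N_tot`, `P_av`, `K_exch`.
#' @export
generate_soils <- function(config, seed = NULL) {
  stopifnot(inherits(config, "quefts_generator"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_fields
  s <- if (config$zone == "All" && is.null(config$soil_dist)) {
    n1 <- n %/% 2
    rbind(.gen_soils_one("NGS", n1, config$rho_oc_n),
          .gen_soils_one("SS", n - n1, config$rho_oc_n))
  } else {
    .gen_soils_one(config$zone, n, config$rho_oc_n, config$soil_dist)
  }
  cbind(field_id = sprintf("F%04d", seq_len(n)), s,
        stringsAsFactors = FALSE)
}

.treatment_design <- function(rates) {
  rbind(control = c(0, 0, 0),
        minusN = c(0, rates[2], rates[3]),
        minusP = c(rates[1], 0, rates[3]),
        minusK = c(rates[1], rates[2], 0),
        NPK = rates,
        NPKplus = rates)
}

# grain-to-stover concentration ratios used to split uptake into tissues
.conc_ratio <- c(N = 2.0, P = 4.0, K = 0.25)

#' Simulate nutrient omission trials
#'
#' Generates the full plot-level trial table: for each field and
#' treatment, the potential supplies follow from the field's soil and the
#' treatment's applied rates; yield and uptakes follow from the forward
#' QUEFTS chain; multiplicative lognormal noise is applied; the grain
#' harvest index is drawn and stover yield, grain and stover nutrient
#' mass fractions are back-computed so that the derived uptakes are
#' exactly consistent with the recorded values. Optionally a fraction of
#' records is inflated into gross outliers for screening studies.
#'
#' Grain yield is expressed at 15% moisture (multiply by 0.85 for dry
#' matter); stover is oven-dry; tissue mass fractions are g/kg on the dry
#' basis.
#'
#' @inheritParams generate_soils
#' @param soils optional pre-generated soil table from [generate_soils()];
#'   generated from `config` when omitted.
#' @return data.frame of plot records, one row per field x treatment,
#'   with the column layout documented in [read_plot_table()].
#' @export
generate_trials <- function(config, seed = NULL, soils = NULL) {
  stopifnot(inherits(config, "quefts_generator"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(soils)) soils <- generate_soils(config)
  nf <- nrow(soils)
  rates_for <- function(zone)
    if (!is.null(config$rates)) config$rates
    else list(NGS = c(140, 50, 50), SS = c(120, 40, 40))[[zone]]

  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    des <- .treatment_design(rates_for(soils$zone[f]))
    S <- total_supply(soils[rep(f, nrow(des)), ], config$eqs, des, config$coef)
    res <- quefts_yield(S, config$coef)
    rows[[f]] <- data.frame(
      field_id = soils$field_id[f], zone = soils$zone[f],
      treatment = rownames(des),
      applied_N = des[, 1], applied_P = des[, 2], applied_K = des[, 3],
      true_yield = res$yield,
      U_N = res$uptake[, "N"], U_P = res$uptake[, "P"], U_K = res$uptake[, "K"],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tr <- do.call(rbind, rows)
  np <- nrow(tr)

  # field noise (lognormal, mean-one) and grain harvest index
  yn <- if (config$yield_cv > 0)
    stats::rlnorm(np, -config$yield_cv^2 / 2, config$yield_cv) else rep(1, np)
  grain15 <- tr$true_yield * yn                    # grain at 15% moisture
  ghi <- .r_trunc_norm(np, config$ghi_mean, config$ghi_sd, config$ghi_range)
  for (i in c("N", "P", "K")) {
    un <- if (config$uptake_cv > 0)
      stats::rlnorm(np, -config$uptake_cv^2 / 2, config$uptake_cv) else rep(1, np)
    tr[[paste0("U_", i)]] <- pmax(tr[[paste0("U_", i)]] * un, 0.01)
  }

  # planted gross outliers
  n_out <- round(config$outlier_frac * np)
  out_idx <- if (n_out > 0) sample.int(np, n_out) else integer(0)
  if (n_out > 0) {
    grain15[out_idx] <- grain15[out_idx] * config$outlier_scale
    for (i in c("N", "P", "K"))
      tr[[paste0("U_", i)]][out_idx] <-
        tr[[paste0("U_", i)]][out_idx] * config$outlier_scale
  }

  grain_dry0 <- 0.85 * grain15                     # dry-matter grain
  stover <- ifelse(grain_dry0 > 0, grain_dry0 * (1 - ghi) / ghi, 1000)
  ghi <- ifelse(grain_dry0 > 0, ghi, 0)
  tot_dm <- grain_dry0 + stover

  out <- data.frame(
    field_id = tr$field_id, zone = tr$zone,
    season = sample(c(2015L, 2016L), np, replace = TRUE),
    variety_group = sample(c("OPV", "hybrid"), np, replace = TRUE),
    treatment = tr$treatment,
    stringsAsFactors = FALSE)
  soil_cols <- c("pH", "OC_tot", "N_tot", "P_av", "K_exch")
  out <- cbind(out, soils[match(tr$field_id, soils$field_id), soil_cols],
               row.names = NULL)
  out$applied_N <- tr$applied_N; out$applied_P <- tr$applied_P
  out$applied_K <- tr$applied_K
  out$grain_yield <- grain15                       # stored at 15% moisture
  out$stover_yield <- stover
  out$ghi <- ghi

  # tissue mass fractions consistent with uptakes: U*1000 = gd*Xg + st*Xs
  for (i in c("N", "P", "K")) {
    U <- tr[[paste0("U_", i)]]
    k <- .conc_ratio[[i]]
    Xs <- 1000 * U / (grain_dry0 * k + stover)
    out[[paste0("stover_", i)]] <- Xs
    out[[paste0("grain_", i)]] <- k * Xs
  }
  attr(out, "outlier_rows") <- out_idx
  attr(out, "total_dm") <- tot_dm
  out
}

.r_trunc_norm <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(range[1], mean, sd); phi <- stats::pnorm(range[2], mean, sd)
  stats::qnorm(plo + (phi - plo) * stats::runif(n), mean, sd)
}

#' Derived nutrient uptake of a plot record
#'
#' Total above-ground uptake (kg/ha) from yields and tissue mass
#' fractions: `(grain_dry * X_g + stover * X_s) / 1000`, with grain
#' converted from 15% moisture to dry matter.
#'
#' @param records plot-record data.frame (see [read_plot_table()]).
#' @param moisture grain moisture fraction assumed in `grain_yield`
#'   (default 0.15).
#' @return n-by-3 matrix of uptakes (kg/ha) with columns `N`, `P`, `K`.
#' @export
plot_uptake <- function(records, moisture = 0.15) {
  gd <- records$grain_yield * (1 - moisture)
  u <- vapply(c("N", "P", "K"), function(i)
    (gd * records[[paste0("grain_", i)]] +
       records$stover_yield * records[[paste0("stover_", i)]]) / 1000,
    numeric(nrow(records)))
  matrix(u, nrow = nrow(records), dimnames = list(NULL, c("N", "P", "K")))
}
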