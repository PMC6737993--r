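# Shared fixtures: the fertility-gradient generator used for parameter
# recovery studies. Supplies cross the minimum-uptake region (zero
# intercepts, heavy-tailed soil distributions) and each true supply
# equation has a single predictor so the planted form is identifiable.

recovery_generator <- function(n_fields, yield_cv = 0.15, uptake_cv = 0.10,
                               outlier_frac = 0) {
  eqs <- list(
    N = supply_equation("N", 0, list(list(var = "N_tot", coef = 130))),
    P = supply_equation("P", 0, list(list(var = "P_av", coef = 0.6))),
    K = supply_equation("K", 0, list(list(var = "K_exch", coef = 260))))
  dist <- list(pH = c(5.8, 0.08, 4.8, 7.2),
               OC_tot = c(7.25, 0.36, 2.44, 15.45),
               N_tot = c(0.30, 1.5, 0.005, 1.0),
               P_av = c(12, 1.2, 0.05, 35),
               K_exch = c(0.28, 1.5, 0.005, 1.2))
  quefts_generator("NGS", n_fields = n_fields,
                   coef = quefts_coefficients("NGS"),
                   eqs = eqs, soil_dist = dist,
                   yield_cv = yield_cv, uptake_cv = uptake_cv,
                   outlier_frac = outlier_frac)
}
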