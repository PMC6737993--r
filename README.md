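# queftsr

Parameterization and application of the QUEFTS model (QUantitative
Evaluation of the Fertility of Tropical Soils) for maize in the Northern
Nigerian savanna, covering the Northern Guinea Savanna (NGS) and Sudan
Savanna (SS) agro-ecological zones.

## The problem

Blanket fertilizer recommendations perform poorly on the heterogeneous,
low-organic-matter soils of the West African savanna. Site-specific
nutrient management instead asks: given a field's soil test values and a
target yield, how much N, P and K must the crop actually take up — and
how much of each will the soil supply on its own? QUEFTS answers both
questions with a four-step empirical model:

1. **Potential supply** `S_i` of each nutrient: an indigenous soil supply
   predicted from topsoil properties (pH, total organic carbon, total N,
   Mehlich-3 P, exchangeable K) plus applied fertilizer times an average
   recovery fraction `R_i`.
2. **Actual uptake** `U_i(j)`: a piecewise function of the nutrient's own
   supply and each partner nutrient's supply — all of a scarce supply is
   taken up; an abundant supply is capped at what the partner-limited
   yield can use.
3. **Yield ranges**: from each uptake, the yield at maximum accumulation
   `Y_ia = a_i (U_i - r_i)` and maximum dilution `Y_id = d_i (U_i - r_i)`,
   where `a_i < d_i` are the envelope physiological efficiencies (kg grain
   per kg nutrient) and `r_i` is the minimum uptake needed to produce any
   grain.
4. **Ultimate yield** `YU`: the six ordered nutrient-pair estimates
   (a parabola from the partner's accumulation yield up to a cap set by
   the other nutrients' dilution yields and the potential yield `ymax`)
   are averaged.

The package provides this engine together with everything needed to
*fit* it from nutrient omission trials (control, -N, -P, -K, NPK, NPK+
treatments): Mahalanobis outlier screening, grain-harvest-index
filtering, minimum-uptake and boundary-line estimation, best-subset
(minimum-BIC) indigenous supply regressions, fertilizer recovery
fractions, balanced N-P-K uptake requirement curves, validation
statistics (RMSE, R², Willmott's d, PBIAS), and a synthetic trial
generator so the whole pipeline can be exercised and tested without the
original field data.

Bundled coefficient sets (zone-calibrated and the classic QUEFTS
defaults) are shipped as plain YAML under `inst/extdata/`.

## Worked example

Forward run on the average NGS field at the recommended rates
(140/50/50 kg N/P/K per ha):

```r
library(queftsr)
cf   <- quefts_coefficients("NGS")        # a, d, r, recovery, ymax
soil <- data.frame(pH = 5.8, OC_tot = 7.25, N_tot = 0.47,
                   P_av = 8.43, K_exch = 0.22)
S <- total_supply(soil, supply_equations("NGS"), c(140, 50, 50), cf)
S
#>          N    P     K
#> [1,] 104.1 17.5 108.3        # kg/ha potential supplies
quefts_yield(S, cf)$yield
#> [1] 5470                     # kg/ha grain (15% moisture)
```

The supply of P (17.5 kg/ha) limits this field: the crop takes up
100.3 kg N, 16.7 kg P and 103.5 kg K and reaches 5.5 t/ha of a 10 t/ha
potential.

Fitting the model to (here: simulated) omission-trial data and
validating on held-out fields:

```r
gen    <- quefts_generator("NGS", n_fields = 100)
trials <- generate_trials(gen, seed = 42)
fit    <- quefts(trials, zone = "NGS", seed = 42)
fit
#> QUEFTS model fit
#> Records: 600 in; 55 outliers and 52 low-GHI plots removed;
#>   394 calibration / 99 validation
validate(fit)
#>   n = 99
#>   RMSE  = 0.76 t/ha
#>   R2    = 0.79
#>   d     = 0.93
#>   PBIAS = -8.0%
```

Balanced uptake requirements (kg nutrient per tonne of grain) for the
NGS, derived by running the model over the zone's field population:

```r
requirement_curve(cf, targets = seq(1000, 9000, 2000),
                  zone = "NGS", n_fields = 2000, seed = 1)
#>  yield (t/ha) RPhE_N RPhE_P RPhE_K
#>             1   13.9    2.3   15.2
#>             3   15.7    2.6   17.2
#>             5   18.3    3.0   20.0
#>             7   22.7    3.8   24.8
#>             9   33.8    5.6   36.9
```

Per-tonne requirements rise with the target because internal efficiency
falls as yields approach the potential. `method = "search"` gives the
coefficient-only balanced-supply search instead; see the methods
vignette (`vignettes/quefts-methods.Rmd`) for when each is appropriate.

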