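---
title: "QUEFTS for savanna maize: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QUEFTS for savanna maize: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(queftsr)
```

## The model

QUEFTS maps the soil's capacity to supply nitrogen, phosphorus and
potassium into a grain yield estimate, accounting for the interactions
among the three macronutrients. It is an empirical, season-scale model:
no weather, water, pest or management terms — everything except N, P and
K is assumed non-limiting. Four steps:

**Step 1 — potential supply.** For each nutrient,
`S_i = indigenous supply + R_i * F_i`, where the indigenous supply is a
regression on topsoil properties (pH in water 1:1, total organic carbon
and total N in g/kg, Mehlich-3 available P in mg/kg, exchangeable K in
cmol~c~/kg) fitted to nutrient uptake in omission plots, `F_i` is the
applied rate (kg/ha) and `R_i` an average recovery fraction. The package
ships two equation registries — the zone-calibrated forms for the
Northern Guinea Savanna (NGS), Sudan Savanna (SS) and both combined, and
the classic QUEFTS default forms — selectable without code changes
(`supply_equations()`, `bundled_coefficients()`). Negative evaluations
(possible at low pH with some intercepts) are floored at zero, since a
negative supply is physically meaningless.

**Step 2 — actual uptake.** Uptake of nutrient `i` relative to partner
`j` is piecewise in `S_i`: full uptake while `S_i` is below what the
partner-limited crop can dilute; capped at
`r_i + (S_j - r_j) d_j / a_i` when `i` is abundant; a parabola joining
the two regimes in between. When a partner is at or below its minimum
uptake `r_j`, the net partner supply is treated as zero, which forces
uptake of `i` to `min(S_i, r_i)` and yield to zero downstream. The two
partner-relative uptakes are combined with the minimum by default (the
more limiting partner governs); `uptake_combine = "mean"` is available
as a sensitivity switch, since the source formulation leaves the
combination rule implicit.

**Steps 3 and 4 — yield ranges and their combination.** Each uptake
brackets yield between maximum accumulation `a_i (U_i - r_i)` and
maximum dilution `d_i (U_i - r_i)` (zero below `r_i`; yields cannot be
negative). For each ordered pair the estimate runs along the
maximum-dilution line of `i` up to the partner's accumulation yield,
then follows a parabola to its apex at the cap
`m = min(Y_jd, Y_kd, ymax)`, staying at the cap for luxury uptake
beyond the apex. If the cap does not exceed the partner's accumulation
yield the range collapses and the estimate equals the cap — this
(rather than the accumulation yield itself) keeps every estimate within
the cap and guarantees zero yield when any nutrient sits at its
minimum. The six ordered pair estimates are averaged.

All internal yields are kg/ha of grain **at 15% moisture** — the basis
on which the crop coefficients and the 10,000 kg/ha potential yield are
defined. Tonnes appear only in printing. Uptake computations convert
grain to dry matter (× 0.85) before applying tissue mass fractions,
because mass fractions are determined on dry material; whether the
original laboratory fractions referred to dry or 15%-moisture grain is
not documented, so the moisture factor is exposed as the `moisture`
argument of `plot_uptake()`.

## Crop coefficients

`quefts_coefficients(zone, source)` returns the bundled sets.
Calibrated maize values (kg grain per kg nutrient; kg/ha for `r`):

| zone | a (N,P,K) | d (N,P,K) | r (N,P,K) | R (N,P,K) |
|------|-----------|-----------|-----------|-----------|
| NGS  | 35, 200, 25 | 79, 527, 117 | 4.0, 0.5, 4.5 | 0.42, 0.16, 0.54 |
| SS   | 32, 164, 24 | 79, 528, 136 | 6.1, 0.8, 7.3 | 0.32, 0.08, 0.37 |
| All  | 35, 199, 24 | 79, 528, 124 | 4.0, 0.5, 4.5 | 0.40, 0.15, 0.52 |
| default | 30, 200, 30 | 70, 600, 120 | 5.0, 0.4, 2.0 | 0.50, 0.10, 0.50 |

`ymax` defaults to 10,000 kg/ha, the potential used for these zones.

## Fitting the model from omission trials

`quefts(data, zone, seed)` runs the full pipeline on a plot table
(schema in `?read_plot_table`):

1. **Multivariate screening.** Squared Mahalanobis distances of each
   plot's (soil, yield, total dry matter, uptake) vector from the
   classical mean/covariance, cut at the chi-square `1 - alpha` quantile
   with `p` degrees of freedom (`alpha = 0.05`). This is the classical
   test (as in common point-and-click implementations); a robust MCD
   option exists for heavily contaminated data. A singular covariance
   falls back to a pseudo-inverse with a warning.
2. **Harvest-index filter.** Plots with GHI < 0.40 are removed (crop
   likely stressed by factors other than nutrients); the boundary value
   0.40 is kept, reading the exclusion strictly.
3. **Field-level 80/20 split** into calibration and validation, whole
   fields together, seeded.
4. **Minimum uptake** `r_i`: the minimum uptake among control plots with
   non-zero grain yield. This estimator only works if the data contain
   fields poor enough to approach zero yield — true of the original
   trials (zero-yield control plots had to be discarded) and of the
   recovery experiment design below.
5. **Boundary lines** `a_i`, `d_i`: quantiles (defaults 0.025 and 0.975)
   of the per-plot slopes through `(r_i, 0)`,
   `s = grain_yield / (U_i - r_i)`. Plots with net uptake below 10% of
   the median net uptake are excluded (`min_gap`): the slope is
   ill-conditioned as `U → r` and measurement noise there is amplified
   hyperbolically. The quantile pair is configurable because the source
   describes the envelopes only graphically.
6. **Supply equations**: for each nutrient, best-subset least squares of
   its omission-plot uptake on the five soil properties over five
   functional families — linear, polynomial (single power terms of
   degree 1–3 per predictor, so forms mixing a linear and a cubic term
   are reachable), logarithmic, exponential (predictor scaled by its
   maximum to avoid overflow), and a one-predictor Cauchy peak
   `c0 + c1 / (1 + ((x - c2)/c3)^2)` fitted by `nls` (the "Cauchy"
   family is not specified anywhere authoritative; this is our
   assumption). Selection is by minimum BIC with residual sums of
   squares floored at 1e-10 (a perfect fit otherwise gives an infinite
   likelihood); ties go to fewer terms, then to the family order above.
   Collinear subsets are skipped.
7. **Recovery fractions**: `R_i = mean((U_NPK - U_omission) / F_i)` over
   plot pairs matched by field; plot-level values may be negative under
   noise and are retained in the average.

`predict()`, `residuals()`, `validate()` then run the forward chain on
new plots; `validate()` reports RMSE, R², Willmott's `d` (in its
standard `1 - …` form; the ratio form without the leading one would
score 0 for perfect agreement) and percent bias
(`100 * sum(obs - pred) / sum(obs)`; positive = model underestimates).

### What parameter recovery can and cannot achieve

The test suite recovers planted parameters from synthetic trials
generated by this package's own generator. Two estimator properties are
worth stating plainly, because they bound what any such study can show:

- **Quantile envelopes are biased under multiplicative noise.** With
  lognormal noise of combined sd ≈ 0.18 on the slopes, the fitted
  `a` (lower quantile) is pulled below and `d` (upper quantile) above
  the planted values by a factor of roughly `exp(±0.18 z)`, where `z`
  depends on how much of the data sits on the envelope. In our recovery
  experiments this bias is of the order of ±20% — the envelopes are
  recovered *as quantile estimates*, near-exactly on noise-free data but
  systematically widened on noisy data. Consumers of fitted `a`/`d`
  should treat them as envelope estimates at the stated quantiles, not
  unbiased physiological constants.
- **`r` needs coverage.** The minimum-uptake estimator converges to the
  true `r` only if control plots approach it; with supplies bounded well
  away from `r` the estimate reflects the population floor instead.

The recovery experiment design used in the tests therefore spans a wide
fertility gradient: zero-intercept single-predictor true supply
equations and heavy-tailed soil distributions whose supplies cross the
minimum-uptake region, with the P range kept mostly below its
partner-imposed uptake cap so omission-plot uptakes track supplies.

## Balanced uptake requirements

`requirement_curve()` tabulates, per target yield, the balanced N-P-K
uptake and its per-tonne form (reciprocal physiological efficiency,
RPhE, kg nutrient per tonne grain, reported to 0.1 kg/t). Two
procedures:

- **`method = "population"` (default).** The forward model is run over a
  simulated field population of the zone (soil summaries below) at the
  recommended rates (NGS 140/50/50, SS 120/40/40 kg N/P/K per ha), and a
  saturating curve with plateau at `ymax`,
  `U = beta * (-ymax * log(1 - Y/ymax))`, is fitted per nutrient by
  least squares on the linearized yield; requirements are read off the
  curve. This reproduces how requirement tables are derived for a trial
  region: they summarize model behaviour *across that region's soils*,
  which is why zones with abundant soil P or K show higher "balanced" P
  or K per tonne (luxury uptake on those soils is part of the zone's
  uptake-yield relation). The curve is near-linear below roughly half
  the potential and steepens toward it. Defaults: 2000 fields, seeded;
  results change by well under 1% between seeds at that size.
- **`method = "search"`.** A coefficient-only construction: supplies are
  scaled along a fixed ratio (1-D root-finding on the scale so the
  ultimate yield equals the target), the ratio is updated to the
  resulting uptake ratio, and the two steps are iterated with 0.5
  damping to a fixed point (tolerance 1e-6 relative on the ratio, up to
  400 iterations — the damped map contracts slowly). This yields the
  least total uptake consistent with mutual balance at the given
  coefficients, independent of any soil population. Its per-tonne curve
  is convex: it *falls* at small targets (the minimum-uptake overhead
  `r/Y` dominates) and rises near the potential, so it is not monotone
  from zero the way population curves are.

The two methods answer different questions — "what does balanced
nutrition look like across this zone's fields" versus "what is the
minimal balanced uptake implied by the coefficients alone" — and their
values at mid-range targets differ by 10–20%. Targets at exactly `ymax`
are accepted but sit on the asymptote of the saturating curve and are
tolerance-sensitive; avoid resting decisions on that row.

## The synthetic trial generator

`quefts_generator()` + `generate_trials()` emulate the two-zone
omission-trial structure: per-zone topsoil distributions (truncated
lognormal matched to the observed mean and CV, clipped to the observed
range, with OC and total N coupled at latent correlation 0.8 — between-
property correlations were not reported, so this is an assumption, and
it is configurable), the six-treatment design at the recommended rates,
deterministic QUEFTS yields from true coefficients and equations,
multiplicative lognormal noise (yield sd 0.15, uptake sd 0.10 —
field-scale CVs in this system are large and right-skewed; no error
model is documented, so these are stated defaults), GHI drawn from a
truncated normal (0.46 ± 0.05 on [0.25, 0.65]), and tissue mass
fractions back-computed from the uptakes (grain:stover concentration
ratios N 2.0, P 4.0, K 0.25) so that the uptake identity
`U = (0.85 * grain * X_g + stover * X_s)/1000` holds exactly. An
optional fraction of records is inflated tenfold into gross outliers
for screening studies. NPK+ is generated identically to NPK (secondary
and micronutrients are treated as non-limiting).

What the generator does **not** emulate: season and variety effects
(labels are generated but carry none, matching the pooled analysis),
spatial autocorrelation between fields, weather, correlated
yield/uptake noise, and measurement structure beyond the multiplicative
model. Tests that pass on these synthetic trials demonstrate the
pipeline's correctness and its estimator properties under the stated
noise model — not that the model fits any particular real dataset.

## Numerical choices and degenerate inputs

- Supplies, rates, uptakes validated non-negative; `a >= d` rejected at
  construction (the uptake parabola needs `d_j/a_i - a_j/d_i > 0`).
- Partner supply at or below its minimum: net supply treated as zero
  (avoids negative thresholds); uptake then `min(S_i, r_i)`.
- Collapsed pairwise range (`m <= Y_ja`): the estimate equals the cap,
  keeping it within bounds and preserving zero yield at minimum uptake.
- Perfect regression fits: RSS floored at 1e-10 in the BIC; ties broken
  toward fewer terms, then family order.
- Boundary slopes: `min_gap` guard above; quantile type 7.
- Balanced search: bisection bracket grown geometrically; an infeasible
  target (ultimate yield cannot reach it along the ray) is an error.
- Coefficient YAML files are written with 17 significant digits so the
  write-read-write cycle is byte-identical.

## Zone soil summaries used by the generator

Mean (CV%, range): NGS — pH 5.8 (8, 4.8–7.2), OC 7.25 g/kg (36,
2.44–15.45), N 0.47 g/kg (30, 0.25–0.98), P 8.43 mg/kg (82, 0.64–31.77),
K 0.22 cmol~c~/kg (78, 0.06–1.35). SS — pH 6.2 (9, 5.2–7.2), OC 5.01
(36, 2.04–10.12), N 0.36 (36, 0.17–0.66), P 16.54 (71, 1.44–50.00),
K 0.24 (43, 0.07–0.50). The combined zone draws half its fields from
each.

## Known limitations

- The model assumes nutrients are the only limiting factor; bias against
  observed yields absorbs water, pest and management effects.
- Fitted recovery fractions are mildly attenuated relative to the true
  values whenever uptake is capped by partner supplies (the uptake
  increment understates the supply increment).
- Fitted `a`/`d` carry the quantile-envelope noise bias described above.
- The SS balanced-requirement column is sensitive to the upper tail of
  the soil P distribution (supply is cubic in available P there);
  population-method results for SS should be read with that in mind.
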