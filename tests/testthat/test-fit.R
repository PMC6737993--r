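test_that("mahalanobis screening finds a planted far outlier and only it", {
  set.seed(8)
  n <- 100
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  X[1, ] <- c(10, 10, 10)                      # planted 10-sigma point
  sc <- screen_outliers(X, alpha = 0.05, vars = c("x1", "x2", "x3"))
  expect_true(sc$is_outlier[1])
  # false removals on the clean remainder stay near the nominal rate
  expect_lte(mean(sc$is_outlier[-1]), 0.07)
})

test_that("screening respects the alpha limits", {
  set.seed(9)
  X <- data.frame(x = rnorm(50), y = rnorm(50))
  none <- screen_outliers(X, alpha = 1e-12, vars = c("x", "y"))
  expect_equal(nrow(none$removed), 0)
  # identical records: zero distances, nothing removed
  Z <- data.frame(x = rep(1, 30), y = rep(2, 30))
  expect_warning(sc <- screen_outliers(Z, vars = c("x", "y")), "singular")
  expect_equal(nrow(sc$removed), 0)
})

test_that("the harvest-index filter drops strictly sub-threshold plots", {
  rec <- data.frame(ghi = c(0.35, 0.40, 0.45))
  out <- filter_ghi(rec)
  expect_equal(out$ghi, c(0.40, 0.45))        # boundary value kept
  expect_equal(attr(out, "n_removed"), 1)
  all_ok <- data.frame(ghi = c(0.41, 0.52))
  expect_equal(nrow(filter_ghi(all_ok)), 2)

  set.seed(10)
  ghi <- c(runif(200, 0.25, 0.399), runif(800, 0.40, 0.65))
  out <- filter_ghi(data.frame(ghi = sample(ghi)))
  expect_equal(attr(out, "n_removed"), 200)   # exactly the planted 20%
})

test_that("physiological efficiency follows its closed forms", {
  expect_equal(physiological_efficiency(1, 15, 8), 1000 / 15)
  # equal grain and stover fractions reduce to 1000*GHI/X
  expect_equal(physiological_efficiency(0.45, 12, 12), 1000 * 0.45 / 12)
  expect_equal(physiological_efficiency(0.5, 15, 8), 500 / 11.5)
  expect_error(physiological_efficiency(0.5, 0, 0), "zero denominator")
})

test_that("minimum uptake comes from yielding control plots only", {
  mk <- function(U, yield) {
    gd <- pmax(yield, 0) * 0.85
    ghi <- ifelse(gd > 0, 0.46, 0)
    st <- ifelse(gd > 0, gd * (1 - ghi) / ghi, 1000)
    Xs <- 1000 * U / (gd * 2 + st)
    data.frame(treatment = "control", grain_yield = yield, stover_yield = st,
               ghi = ghi, grain_N = 2 * Xs, stover_N = Xs,
               grain_P = 0, stover_P = 0, grain_K = 0, stover_K = 0)
  }
  rec <- rbind(mk(6.1, 900), mk(9.0, 1500), mk(7.2, 1100))
  expect_equal(fit_minimum_uptake(rec, "N"), 6.1, tolerance = 1e-9)
  # a zero-yield control plot is discarded before taking the minimum
  rec2 <- rbind(mk(2.0, 0), mk(4.0, 700), mk(5.5, 950))
  expect_equal(fit_minimum_uptake(rec2, "N"), 4.0, tolerance = 1e-9)
  expect_error(fit_minimum_uptake(mk(2.0, 0), "N"), "control")
})

test_that("boundary lines recover quantiles of a known slope distribution", {
  # plots constructed so the slope through (r, 0) is exactly uniform(30, 80)
  set.seed(11)
  n <- 2000
  r <- 4
  s_true <- runif(n, 30, 80)
  net <- runif(n, 5, 120)
  gy <- s_true * net                           # grain at 15% moisture
  gd <- 0.85 * gy
  ghi <- 0.5
  rec <- data.frame(grain_yield = gy, stover_yield = gd,
                    ghi = ghi,
                    grain_N = 1000 * (net + r) / (2 * gd),
                    stover_N = 1000 * (net + r) / (2 * gd),
                    grain_P = 0, stover_P = 0, grain_K = 0, stover_K = 0)
  ad <- fit_boundary_lines(rec, r, "N", min_gap = 0)
  expect_equal(unname(ad["a"]), 31.25, tolerance = 0.03)
  expect_equal(unname(ad["d"]), 78.75, tolerance = 0.03)
  # permutation invariance
  ad2 <- fit_boundary_lines(rec[sample(n), ], r, "N", min_gap = 0)
  expect_equal(ad, ad2)
  # collapsed envelope: every point on one line through (r, 0)
  gy55 <- 55 * net
  gd55 <- 0.85 * gy55
  rec55 <- data.frame(grain_yield = gy55, stover_yield = gd55,
                      ghi = ghi,
                      grain_N = 1000 * (net + r) / (2 * gd55),
                      stover_N = 1000 * (net + r) / (2 * gd55),
                      grain_P = 0, stover_P = 0, grain_K = 0, stover_K = 0)
  ad3 <- fit_boundary_lines(rec55, r, "N", min_gap = 0)
  expect_equal(unname(ad3["a"]), 55, tolerance = 1e-9)
  expect_equal(unname(ad3["d"]), 55, tolerance = 1e-9)
})

test_that("best-subset fit recovers a planted linear law", {
  set.seed(12)
  n <- 300
  soils <- data.frame(pH = runif(n, 4.8, 7.2), OC_tot = runif(n, 2, 16),
                      N_tot = runif(n, 0.1, 1), P_av = runif(n, 0.6, 45),
                      K_exch = runif(n, 0.06, 1.3))
  y <- 10 + 150 * soils$N_tot + rnorm(n, 0, 0.5)
  eq <- fit_supply_equation(soils, y, "N")
  expect_equal(eq$family, "linear")
  expect_equal(length(eq$terms), 1)
  expect_equal(eq$terms[[1]]$var, "N_tot")
  expect_equal(eq$intercept, 10, tolerance = 0.05)
  expect_equal(eq$terms[[1]]$coef, 150, tolerance = 0.05)

  # pure-noise response: intercept-only wins, R2 essentially zero
  y0 <- rnorm(n, 50, 5)
  eq0 <- fit_supply_equation(soils, y0, "N")
  expect_equal(length(eq0$terms), 0)
  expect_lt(eq0$R2, 0.05)
})

test_that("field-level split is exact, seeded and disjoint", {
  gen <- quefts_generator("NGS", n_fields = 10)
  tr <- generate_trials(gen, seed = 13)
  sp <- split_calibration_validation(tr, 0.8, seed = 14)
  expect_equal(length(unique(sp$calibration$field_id)), 8)
  expect_equal(length(unique(sp$validation$field_id)), 2)
  expect_length(intersect(sp$calibration$field_id, sp$validation$field_id), 0)
  sp2 <- split_calibration_validation(tr, 0.8, seed = 14)
  expect_identical(sp$calibration$field_id, sp2$calibration$field_id)
  sp3 <- split_calibration_validation(tr, 0.8, seed = 15)
  expect_false(identical(sort(unique(sp$validation$field_id)),
                         sort(unique(sp3$validation$field_id))))
})

test_that("record counts are conserved through the pipeline", {
  gen <- recovery_generator(50)
  tr <- generate_trials(gen, seed = 16)
  fit <- quefts(tr, zone = "NGS", seed = 16)
  rep <- fit$report
  expect_equal(rep$n_input, nrow(tr))
  expect_equal(rep$n_input - rep$n_outliers_removed - rep$n_ghi_removed,
               rep$n_calibration + rep$n_validation)
})
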