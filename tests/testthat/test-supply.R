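test_that("bundled supply equations evaluate to their printed arithmetic", {
  eqs_all <- supply_equations("All")
  # combined-zone K equation at zero exchangeable K returns the intercept
  expect_equal(predict(eqs_all$K, data.frame(K_exch = 0)), 26.35)

  # NGS N equation at the zone mean soil
  eqs_ngs <- supply_equations("NGS")
  expect_equal(predict(eqs_ngs$N, data.frame(OC_tot = 7.25, N_tot = 0.47)),
               -20.54 + 0.60 * 7.25 + 130.92 * 0.47)

  # SS K equation (hand calculator check)
  eqs_ss <- supply_equations("SS")
  expect_equal(predict(eqs_ss$K, data.frame(pH = 6.2, K_exch = 0.24)),
               228.73 - 35.30 * 6.2 + 275.30 * 0.24)

  # cubic SS forms evaluate the stored power
  expect_equal(predict(eqs_ss$N, data.frame(N_tot = 0.4)),
               11.64 + 155.41 * 0.4^3)
  expect_equal(predict(eqs_all$N, data.frame(N_tot = 0.4)),
               9.56 + 147.28 * 0.4^2)
})

test_that("negative fitted supplies are floored at zero", {
  eqs <- supply_equations("NGS")
  # low pH, negligible P: the P form goes negative and is reported as 0
  expect_equal(predict(eqs$P, data.frame(pH = 3.5, P_av = 0.1)), 0)
})

test_that("missing predictors are reported by name", {
  eqs <- supply_equations("NGS")
  expect_error(predict(eqs$N, data.frame(OC_tot = 7)), "N_tot")
})

test_that("recovery fraction follows its defining ratio", {
  expect_equal(recovery_fraction(42, 42, 140), 0)
  expect_equal(recovery_fraction(100.8, 42.0, 140), 0.42)
  # plot-level values may be negative (noise); sign is retained
  expect_lt(recovery_fraction(30, 40, 100), 0)
  expect_error(recovery_fraction(10, 5, 0), "zero")
})

test_that("total supply adds recovered fertilizer to indigenous supply", {
  cf <- quefts_coefficients("NGS")
  eqs <- supply_equations("NGS")
  soil <- data.frame(pH = 5.8, OC_tot = 7.25, N_tot = 0.47,
                     P_av = 8.43, K_exch = 0.22)
  ind <- total_supply(soil, eqs, c(0, 0, 0), cf)
  fert <- total_supply(soil, eqs, c(140, 50, 50), cf)
  expect_equal(unname(fert - ind),
               matrix(c(0.42 * 140, 0.16 * 50, 0.54 * 50), 1))
  # linearity in the applied rates
  fert2 <- total_supply(soil, eqs, c(280, 100, 100), cf)
  expect_equal(unname(fert2 - ind), 2 * unname(fert - ind))
})

test_that("registry forms refit exactly from noise-free data", {
  set.seed(42)
  soils <- data.frame(pH = runif(200, 4.8, 7.2),
                      OC_tot = runif(200, 2.4, 15),
                      N_tot = runif(200, 0.1, 1.0),
                      P_av = runif(200, 0.6, 45),
                      K_exch = runif(200, 0.06, 1.3))
  for (zone in c("NGS", "SS", "All")) {
    for (i in c("N", "P", "K")) {
      eq <- supply_equations(zone)[[i]]
      y <- eq$intercept +
        rowSums(vapply(eq$terms, function(tm)
          tm$coef * soils[[tm$var]]^tm$power, numeric(200)))
      refit <- fit_supply_equation(soils, y, i,
                                   families = c("linear", "polynomial"))
      expect_equal(refit$intercept, eq$intercept, tolerance = 1e-6)
      expect_equal(length(refit$terms), length(eq$terms))
      got <- vapply(refit$terms, `[[`, 0, "coef")
      names(got) <- vapply(refit$terms, function(tm)
        paste0(tm$var, "^", tm$power), "")
      want <- vapply(eq$terms, `[[`, 0, "coef")
      names(want) <- vapply(eq$terms, function(tm)
        paste0(tm$var, "^", tm$power), "")
      expect_equal(got[sort(names(got))], want[sort(names(want))],
                   tolerance = 1e-6)
      expect_gt(refit$R2, 1 - 1e-9)
    }
  }
})

test_that("parameterized and default registries are interchangeable", {
  cfp <- quefts_coefficients("SS", "parameterized")
  cfd <- quefts_coefficients("SS", "janssen_default")
  soil <- data.frame(pH = 6.2, OC_tot = 5.01, N_tot = 0.36,
                     P_av = 16.54, K_exch = 0.24)
  for (src in c("parameterized", "janssen_default")) {
    s <- total_supply(soil, supply_equations("SS", src), c(120, 40, 40),
                      if (src == "parameterized") cfp else cfd)
    expect_true(all(is.finite(s)) && all(s >= 0))
  }
  expect_equal(cfd$recovery, c(N = 0.50, P = 0.10, K = 0.50))
})
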