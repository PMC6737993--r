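cf_ngs <- quefts_coefficients("NGS")
cf_all <- quefts_coefficients("All")

test_that("uptake follows the piecewise supply relation", {
  # supply at the minimum with an ample partner is taken up entirely
  expect_equal(nutrient_uptake(4.0, 500, cf_ngs, "N", "P"), 4.0)

  # continuity at both branch switch points
  ri <- cf_ngs$r[["N"]]; rj <- cf_ngs$r[["P"]]
  aj <- cf_ngs$a[["P"]]; dj <- cf_ngs$d[["P"]]
  ai <- cf_ngs$a[["N"]]; di <- cf_ngs$d[["N"]]
  Sj <- 30
  b1 <- ri + (Sj - rj) * aj / di
  b2 <- ri + (Sj - rj) * (2 * dj / ai - aj / di)
  for (b in c(b1, b2)) {
    lo <- nutrient_uptake(b - 1e-7, Sj, cf_ngs, "N", "P")
    hi <- nutrient_uptake(b + 1e-7, Sj, cf_ngs, "N", "P")
    expect_lt(abs(hi - lo) / b, 1e-6)
  }

  # selected branch matches the piecewise minimum-envelope construction
  # on a fine supply grid (grid-evaluation oracle)
  S_N <- seq(0.5, 400, by = 0.5)
  got <- nutrient_uptake(S_N, 30, cf_ngs, "N", "P")
  want <- vapply(S_N, oracle_uptake_ij, 0, Sj = 30,
                 ai = ai, di = di, ri = ri, aj = aj, dj = dj, rj = rj)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got <= S_N + 1e-12))
})

test_that("uptake is continuous and monotone in both supplies", {
  for (pair in list(c("N", "P"), c("P", "K"), c("K", "N"))) {
    Si <- seq(0.5, 300, by = 0.25)
    for (Sj in c(5, 20, 80, 250)) {
      u <- nutrient_uptake(Si, Sj, cf_all, pair[1], pair[2])
      expect_true(all(diff(u) >= -1e-9))
      jump <- abs(nutrient_uptake(Si + 1e-7, Sj, cf_all, pair[1], pair[2]) -
                    nutrient_uptake(Si - 1e-7, Sj, cf_all, pair[1], pair[2]))
      expect_true(all(jump < 1e-6 * Si))
    }
    u2 <- vapply(c(5, 20, 80, 250),
                 function(sj) nutrient_uptake(150, sj, cf_all,
                                              pair[1], pair[2]), 0)
    expect_true(all(diff(u2) >= -1e-9))
  }
})

test_that("degenerate partner supply forces minimal uptake and zero yield", {
  # partner at or below its minimum: net partner supply treated as zero
  expect_equal(nutrient_uptake(3.0, cf_ngs$r[["P"]], cf_ngs, "N", "P"), 3.0)
  expect_equal(nutrient_uptake(50, cf_ngs$r[["P"]] / 2, cf_ngs, "N", "P"),
               cf_ngs$r[["N"]])
  res <- quefts_yield(c(N = cf_ngs$r[["N"]], P = 500, K = 500), cf_ngs)
  expect_equal(res$yield, 0)
})

test_that("invalid coefficients are rejected", {
  expect_error(quefts_coef(a = c(80, 200, 25), d = c(79, 527, 117),
                           r = c(4, 0.5, 4.5)), "invalid coefficients")
  expect_error(quefts_coef(a = c(35, 200, 25), d = c(79, 527, 117),
                           r = c(-1, 0.5, 4.5)), "non-negative")
  expect_error(nutrient_uptake(10, 10, cf_ngs, "N", "N"), "differ")
})

test_that("yield ranges follow the accumulation and dilution slopes", {
  yr <- yield_range(54, cf_ngs, "N")
  expect_equal(unname(yr[1, "Ya"]), 35 * 50)
  expect_equal(unname(yr[1, "Yd"]), 79 * 50)
  # uptake at the minimum gives a zero range; below it is floored at zero
  expect_equal(unname(yield_range(cf_ngs$r[["N"]], cf_ngs, "N")[1, ]), c(0, 0))
  expect_equal(unname(yield_range(1, cf_ngs, "N")[1, ]), c(0, 0))
  # the range ratio is d/a independent of uptake
  for (u in c(10, 50, 200)) {
    yr <- yield_range(u, cf_ngs, "K")
    expect_equal(unname(yr[1, "Yd"] / yr[1, "Ya"]),
                 cf_ngs$d[["K"]] / cf_ngs$a[["K"]])
  }
})

test_that("pairwise yield hits its analytic endpoints", {
  U <- c(N = 100, P = 15, K = 90)
  ranges <- lapply(setNames(c("N", "P", "K"), c("N", "P", "K")),
                   function(i) yield_range(U[[i]], cf_ngs, i))
  Yja <- ranges$P[1, "Ya"]
  m <- min(ranges$P[1, "Yd"], ranges$K[1, "Yd"], cf_ngs$ymax)
  ri <- cf_ngs$r[["N"]]; ai <- cf_ngs$a[["N"]]; di <- cf_ngs$d[["N"]]
  # uptake exactly supporting the partner's accumulation yield
  expect_equal(pairwise_yield(ri + Yja / di, ranges, cf_ngs, "N", "P", "K"),
               unname(Yja))
  # apex: uptake converting the cap at maximum accumulation
  expect_equal(pairwise_yield(ri + m / ai, ranges, cf_ngs, "N", "P", "K"),
               unname(m))
  # luxury uptake beyond the apex stays at the cap
  expect_equal(pairwise_yield(ri + m / ai + 50, ranges, cf_ngs, "N", "P", "K"),
               unname(m))
})

test_that("all six pairwise estimates match an independent transcription", {
  U <- c(N = 100, P = 15, K = 90)
  ranges <- lapply(setNames(c("N", "P", "K"), c("N", "P", "K")),
                   function(i) yield_range(U[[i]], cf_ngs, i))
  pairs <- list(c("N", "P", "K"), c("N", "K", "P"), c("P", "N", "K"),
                c("P", "K", "N"), c("K", "N", "P"), c("K", "P", "N"))
  for (p in pairs) {
    got <- pairwise_yield(U[[p[1]]], ranges, cf_ngs, p[1], p[2], p[3])
    Ya <- vapply(c("N", "P", "K"), function(i) ranges[[i]][1, "Ya"], 0)
    Yd <- vapply(c("N", "P", "K"), function(i) ranges[[i]][1, "Yd"], 0)
    m <- min(Yd[[p[2]]], Yd[[p[3]]], cf_ngs$ymax)
    t <- U[[p[1]]] - cf_ngs$r[[p[1]]] - Ya[[p[2]]] / cf_ngs$d[[p[1]]]
    D <- m / cf_ngs$a[[p[1]]] - Ya[[p[2]]] / cf_ngs$d[[p[1]]]
    t2 <- min(max(t, 0), D)
    want <- Ya[[p[2]]] + 2 * (m - Ya[[p[2]]]) * t2 / D -
      (m - Ya[[p[2]]]) * (t2 / D)^2
    expect_equal(got, unname(want), tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, m + 1e-9)
  }
})

test_that("ultimate yield matches the independent oracle on a supply grid", {
  g <- expand.grid(N = seq(5, 300, length.out = 20),
                   P = seq(1, 80, length.out = 20),
                   K = seq(5, 300, length.out = 20))
  res <- quefts_yield(as.matrix(g), cf_all)
  want <- vapply(seq_len(nrow(g)), function(k)
    oracle_yield(as.list(g[k, ]), cf_all)$yield, 0)
  expect_equal(res$yield, want, tolerance = 1e-9)
  expect_true(all(res$yield >= 0 & res$yield <= cf_all$ymax))
  expect_true(all(res$uptake <= as.matrix(g) + 1e-9))
})

test_that("ultimate yield is monotone in each supply and capped by ymax", {
  base <- c(N = 60, P = 10, K = 50)
  for (i in c("N", "P", "K")) {
    s <- seq(1, 400, by = 1)
    S <- matrix(rep(base, each = length(s)), ncol = 3,
                dimnames = list(NULL, names(base)))
    S[, i] <- s
    y <- quefts_yield(S, cf_ngs)$yield
    expect_true(all(diff(y) >= -1e-8))
  }
  big <- quefts_yield(c(5000, 5000, 5000), cf_ngs)
  expect_lte(big$yield, cf_ngs$ymax)

  # raising the potential yield never decreases the estimate
  cf2 <- quefts_coefficients("NGS", ymax = 20000)
  for (k in 1:20) {
    set.seed(k)
    S <- runif(3, 5, 400)
    expect_gte(quefts_yield(S, cf2)$yield, quefts_yield(S, cf_ngs)$yield - 1e-8)
  }
})

test_that("a frozen trace through the full chain is reproduced", {
  # hand-stepped trace, combined-zone coefficients, supplies (60, 10, 50)
  res <- quefts_yield(c(N = 60, P = 10, K = 50), cf_all)
  want <- oracle_yield(list(N = 60, P = 10, K = 50), cf_all)
  expect_equal(res$yield, want$yield, tolerance = 1e-12)
  expect_equal(res$uptake[1, ], want$uptake, tolerance = 1e-12)
  # frozen regression value (computed once from the scalar trace)
  expect_equal(res$yield, 2910.091794, tolerance = 1e-6)
})
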