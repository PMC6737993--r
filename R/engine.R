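#' Actual nutrient uptake from paired supplies
#'
#' Step 2 of the QUEFTS calculation: the actual uptake of nutrient `i`
#' given its own supply and the supply of a second nutrient `j`. Uptake
#' follows the piecewise Janssen form: when the supply of `i` is small
#' relative to what `j` can support, all of it is taken up (`U = S_i`);
#' when `i` is abundant, uptake is capped at the amount needed to convert
#' the yield that `j` can sustain at maximum dilution of `j` and maximum
#' accumulation of `i`; in between the two regimes uptake follows a
#' parabola that joins them with continuous value and slope.
#'
#' When the supply of the partner nutrient is at or below its minimum
#' uptake (`S_j <= r_j`) the net partner supply is treated as zero, so
#' uptake of `i` is `min(S_i, r_i)`: any grain yield downstream is zero.
#'
#' @param S_i,S_j supplies of nutrients `i` and `j` (kg/ha); vectors are
#'   recycled to common length.
#' @param coef a [quefts_coef] object.
#' @param i,j nutrient labels, distinct elements of `c("N","P","K")`.
#' @return Uptake of nutrient `i` (kg/ha), never exceeding `S_i`.
#' @seealso [quefts_yield()] for the full supply-to-yield chain.
#' @export
nutrient_uptake <- function(S_i, S_j, coef, i, j) {
  coef <- .check_coef(coef)
  .check_pair(i, j)
  if (any(S_i < 0, na.rm = TRUE) || any(S_j < 0, na.rm = TRUE))
    stop("supplies must be non-negative")
  n <- max(length(S_i), length(S_j))
  S_i <- rep_len(S_i, n); S_j <- rep_len(S_j, n)

  ai <- coef$a[[i]]; di <- coef$d[[i]]; ri <- coef$r[[i]]
  aj <- coef$a[[j]]; dj <- coef$d[[j]]; rj <- coef$r[[j]]

  net_j <- pmax(S_j - rj, 0)           # partner supply beyond its minimum
  lo <- ri + net_j * aj / di           # below: full uptake
  hi <- ri + net_j * (2 * dj / ai - aj / di)  # above: dilution-capped

  u <- numeric(n)
  b1 <- S_i < lo
  b2 <- !b1 & S_i > hi
  b3 <- !b1 & !b2
  u[b1] <- S_i[b1]
  u[b2] <- ri + net_j[b2] * dj / ai
  if (any(b3)) {
    denom <- net_j[b3] * (dj / ai - aj / di)
    num <- (S_i[b3] - ri - net_j[b3] * aj / di)^2
    # net_j == 0 collapses lo == hi == ri; there S_i == ri and uptake is ri
    u[b3] <- ifelse(denom > 0, S_i[b3] - 0.25 * num / denom, pmin(S_i[b3], ri))
  }
  pmin(u, S_i)
}

#' Yield range from actual uptake
#'
#' Step 3 of the QUEFTS calculation: the yield attainable from an actual
#' uptake `U_i`, bracketed between the yield at maximum accumulation
#' (`Ya = a_i (U_i - r_i)`, nutrient held in luxury amounts) and at
#' maximum dilution (`Yd = d_i (U_i - r_i)`, nutrient used with maximal
#' internal efficiency). Uptake at or below the minimum `r_i` yields zero.
#'
#' @param U uptake of nutrient `i` (kg/ha), vectorised.
#' @param coef a [quefts_coef] object.
#' @param i nutrient label.
#' @return A two-column matrix with columns `Ya`, `Yd` (kg grain/ha).
#' @export
yield_range <- function(U, coef, i) {
  coef <- .check_coef(coef)
  i <- match.arg(i, c("N", "P", "K"))
  net <- pmax(U - coef$r[[i]], 0)
  cbind(Ya = coef$a[[i]] * net, Yd = coef$d[[i]] * net)
}

#' Yield estimate for an ordered nutrient pair
#'
#' Step 4 (first half) of the QUEFTS calculation: combines the uptake of
#' nutrient `i` with the yield range of partner `j`, capped by the
#' dilution yields of the other two nutrients and by the potential yield,
#' through the Janssen parabola. Writing `m = min(Yd_j, Yd_k, ymax)`:
#' the estimate runs along the maximum-dilution line of `i` up to the
#' accumulation yield `Ya_j` of the partner, then follows a parabola from
#' `(r_i + Ya_j/d_i, Ya_j)` to its apex `(r_i + m/a_i, m)`, and stays at
#' the cap `m` for larger uptake (luxury consumption). When the cap does
#' not exceed `Ya_j` the range collapses and the estimate equals the cap.
#'
#' @param U_i uptake of nutrient `i` (kg/ha), vectorised.
#' @param ranges list with named elements `N`, `P`, `K`, each a two-column
#'   `Ya`/`Yd` matrix as returned by [yield_range()] for the same records.
#' @param coef a [quefts_coef] object.
#' @param i,j,k distinct nutrient labels (`k` is the nutrient outside the
#'   pair).
#' @return Yield estimate for the ordered pair (kg grain/ha).
#' @export
pairwise_yield <- function(U_i, ranges, coef, i, j, k) {
  coef <- .check_coef(coef)
  .check_pair(i, j); .check_pair(j, k); .check_pair(i, k)
  ai <- coef$a[[i]]; di <- coef$d[[i]]; ri <- coef$r[[i]]
  Yja <- ranges[[j]][, "Ya"]
  m <- pmin(ranges[[j]][, "Yd"], ranges[[k]][, "Yd"], coef$ymax)

  net <- pmax(U_i - ri, 0)
  t <- net - Yja / di
  D <- m / ai - Yja / di                # > 0 whenever m > Yja since a < d

  y <- numeric(length(U_i))
  collapsed <- m <= Yja                 # cap at/below partner accumulation
  y[collapsed] <- m[collapsed]
  dil <- !collapsed & t <= 0            # i limiting: maximum-dilution line
  y[dil] <- di * net[dil]
  par <- !collapsed & t > 0
  if (any(par)) {
    tt <- pmin(t[par], D[par])          # beyond the apex: luxury uptake of i
    mm <- m[par] - Yja[par]
    y[par] <- Yja[par] + 2 * mm * tt / D[par] - mm * (tt / D[par])^2
  }
  y
}

#' QUEFTS yield from nutrient supplies
#'
#' The full forward QUEFTS chain: from the potential supplies of N, P and
#' K to actual uptakes (step 2), per-nutrient yield ranges (step 3), the
#' six ordered pairwise yield estimates and their mean, the ultimate yield
#' estimate (step 4). Uptake of each nutrient is computed relative to both
#' partners and combined (by default the minimum, i.e. the more limiting
#' partner governs).
#'
#' @param supplies numeric vector of length 3 (N, P, K in kg/ha) or an
#'   n-by-3 matrix/data.frame with columns `N`, `P`, `K` for many records.
#' @param coef a [quefts_coef] object.
#' @param uptake_combine how the two partner-relative uptakes of a
#'   nutrient are merged: `"min"` (default) or `"mean"`.
#' @return A list with elements `yield` (ultimate yield estimate, kg/ha),
#'   `uptake` (n-by-3 matrix of actual uptakes, kg/ha), and `pairwise`
#'   (n-by-6 matrix of the ordered pair estimates `Y_NP`, `Y_NK`, `Y_PN`,
#'   `Y_PK`, `Y_KN`, `Y_KP`).
#' @examples
#' cf <- quefts_coefficients("NGS")
#' quefts_yield(c(N = 60, P = 10, K = 50), cf)$yield
#' @export
quefts_yield <- function(supplies, coef, uptake_combine = c("min", "mean")) {
  coef <- .check_coef(coef)
  uptake_combine <- match.arg(uptake_combine)
  S <- .as_supply_matrix(supplies)
  nm <- c("N", "P", "K")

  # step 2: uptake of i relative to each partner j, then combine
  U <- matrix(NA_real_, nrow(S), 3, dimnames = list(NULL, nm))
  for (i in nm) {
    others <- setdiff(nm, i)
    u2 <- vapply(others, function(j) nutrient_uptake(S[, i], S[, j], coef, i, j),
                 numeric(nrow(S)))
    u2 <- matrix(u2, nrow = nrow(S))
    U[, i] <- if (uptake_combine == "min") pmin(u2[, 1], u2[, 2])
              else rowMeans(u2)
  }

  # step 3: yield ranges per nutrient
  ranges <- lapply(stats::setNames(nm, nm), function(i) yield_range(U[, i], coef, i))

  # step 4: six ordered pairs, averaged
  pairs <- list(c("N", "P", "K"), c("N", "K", "P"), c("P", "N", "K"),
                c("P", "K", "N"), c("K", "N", "P"), c("K", "P", "N"))
  YP <- vapply(pairs, function(p)
    pairwise_yield(U[, p[1]], ranges, coef, p[1], p[2], p[3]),
    numeric(nrow(S)))
  YP <- matrix(YP, nrow = nrow(S),
               dimnames = list(NULL, vapply(pairs, function(p)
                 paste0("Y_", p[1], p[2]), "")))

  yu <- pmin(pmax(rowMeans(YP), 0), coef$ymax)
  # a nutrient at or below its minimum uptake produces no grain
  yu[U[, "N"] <= coef$r[["N"]] | U[, "P"] <= coef$r[["P"]] |
       U[, "K"] <= coef$r[["K"]]] <- 0
  list(yield = yu, uptake = U, pairwise = YP)
}

.check_pair <- function(i, j) {
  nm <- c("N", "P", "K")
  if (!(i %in% nm) || !(j %in% nm)) stop("nutrient labels must be N, P or K")
  if (i == j) stop("nutrient indices must differ")
  invisible(TRUE)
}

.as_supply_matrix <- function(supplies) {
  nm <- c("N", "P", "K")
  if (is.data.frame(supplies)) supplies <- as.matrix(supplies)
  if (is.null(dim(supplies))) {
    if (length(supplies) != 3L) stop("'supplies' must have N, P and K entries")
    supplies <- matrix(supplies, 1, 3, dimnames = list(NULL, nm))
  }
  if (ncol(supplies) != 3L) stop("'supplies' must have 3 columns (N, P, K)")
  if (!is.null(colnames(supplies)) && all(nm %in% colnames(supplies)))
    supplies <- supplies[, nm, drop = FALSE]
  colnames(supplies) <- nm
  if (any(supplies < 0, na.rm = TRUE)) stop("supplies must be non-negative")
  supplies
}
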