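# Independent scalar transcription of the supply-to-yield chain, written
# without reference to the package internals: plain loops, one nutrient
# pair at a time. Used as the cross-check for the vectorized engine.

oracle_uptake_ij <- function(Si, Sj, ai, di, ri, aj, dj, rj) {
  nj <- max(Sj - rj, 0)
  if (Si < ri + nj * aj / di) return(Si)
  if (Si > ri + nj * (2 * dj / ai - aj / di)) return(ri + nj * dj / ai)
  den <- nj * (dj / ai - aj / di)
  if (den <= 0) return(min(Si, ri))
  min(Si, Si - 0.25 * (Si - ri - nj * aj / di)^2 / den)
}

oracle_yield <- function(S, cf) {
  nm <- c("N", "P", "K")
  U <- numeric(3); names(U) <- nm
  for (i in nm) {
    vals <- c()
    for (j in setdiff(nm, i))
      vals <- c(vals, oracle_uptake_ij(S[[i]], S[[j]],
                                       cf$a[[i]], cf$d[[i]], cf$r[[i]],
                                       cf$a[[j]], cf$d[[j]], cf$r[[j]]))
    U[i] <- min(vals)
  }
  Ya <- Yd <- numeric(3); names(Ya) <- names(Yd) <- nm
  for (i in nm) {
    net <- max(U[[i]] - cf$r[[i]], 0)
    Ya[i] <- cf$a[[i]] * net
    Yd[i] <- cf$d[[i]] * net
  }
  tot <- 0
  for (i in nm) for (j in setdiff(nm, i)) {
    k <- setdiff(nm, c(i, j))
    m <- min(Yd[[j]], Yd[[k]], cf$ymax)
    yij <- if (m <= Ya[[j]]) {
      m
    } else {
      t <- U[[i]] - cf$r[[i]] - Ya[[j]] / cf$d[[i]]
      if (t <= 0) {
        cf$d[[i]] * max(U[[i]] - cf$r[[i]], 0)
      } else {
        D <- m / cf$a[[i]] - Ya[[j]] / cf$d[[i]]
        t <- min(t, D)
        Ya[[j]] + 2 * (m - Ya[[j]]) * t / D - (m - Ya[[j]]) * (t / D)^2
      }
    }
    tot <- tot + yij
  }
  yu <- min(max(tot / 6, 0), cf$ymax)
  if (any(U <= cf$r)) yu <- 0
  list(yield = yu, uptake = U)
}
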