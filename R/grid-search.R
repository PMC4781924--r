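#' @include utils.R
NULL

# Exhaustive argmin of the Beer's-law RMS objective over a Cartesian mesh.
#
# The objective M * eps^2 = c'Gc - 2h'c + k is quadratic in the
# concentrations, with G = A A', h = A y, k = y'y precomputed once per fit
# (so cost per mesh point is O(N^2), independent of the number of
# wavenumbers M). For fixed values of the first N-1 components the objective
# is an exact parabola in the last component, so along that axis only the
# two mesh points bracketing the parabola vertex can attain the minimum;
# they are evaluated directly instead of sweeping the whole axis. This is an
# algebraic identity, not an approximation: the returned argmin is the same
# point full enumeration would return (tests cross-check a naive
# implementation).
#
# Ties are broken toward the lexicographically smallest concentration vector
# in component order: prefixes are enumerated with component 1 varying
# slowest, strict comparisons keep the earliest (smallest) candidate, and
# along the last axis the lower of two equal-valued points wins.
#
# grids: list of N ascending, equally spaced mesh vectors (length-1 allowed).
# Returns list(best, value = eps_RMS, nEval = mesh cardinality).
.gridSearch <- function(grids, G, h, k, M, chunkSize = 2^20) {
  N <- length(grids)
  lens <- vapply(grids, length, integer(1))
  nEval <- prod(as.numeric(lens))
  if (N == 1L) {
    g <- grids[[1L]]
    v <- G[1L, 1L] * g * g - 2 * h[1L] * g + k
    i <- which.min(v)
    return(list(best = g[i], value = sqrt(max(v[i], 0) / M), nEval = nEval))
  }
  gN <- grids[[N]]
  LN <- length(gN)
  a <- G[N, N]
  Gp <- G[-N, -N, drop = FALSE]
  gcol <- G[-N, N]
  hp <- h[-N]
  hN <- h[N]
  lensP <- lens[-N]
  nPrefix <- prod(as.numeric(lensP))
  # inner[j] = number of prefixes sharing a fixed value of components 1..j
  inner <- rev(cumprod(rev(c(as.numeric(lensP[-1L]), 1))))
  bestVal <- Inf
  bestC <- NULL
  start <- 0
  while (start < nPrefix) {
    nb <- as.integer(min(chunkSize, nPrefix - start))
    idx <- start + seq_len(nb) - 1
    P <- matrix(0, nb, N - 1L)
    for (j in seq_len(N - 1L))
      P[, j] <- grids[[j]][(idx %/% inner[j]) %% lensP[j] + 1]
    d <- rowSums((P %*% Gp) * P) - 2 * drop(P %*% hp) + k
    b <- 2 * (drop(P %*% gcol) - hN)
    if (LN == 1L) {
      x <- rep.int(gN, nb)
      v <- a * x * x + b * x + d
    } else if (a > 0) {
      stepN <- gN[2L] - gN[1L]
      t <- (-b / (2 * a) - gN[1L]) / stepN
      lo <- pmin(pmax(floor(t), 0), LN - 1)
      hi <- pmin(lo + 1, LN - 1)
      xlo <- gN[lo + 1]
      xhi <- gN[hi + 1]
      vlo <- a * xlo * xlo + b * xlo + d
      vhi <- a * xhi * xhi + b * xhi + d
      takeHi <- which(vhi < vlo)
      x <- xlo
      x[takeHi] <- xhi[takeHi]
      v <- vlo
      v[takeHi] <- vhi[takeHi]
    } else {
      # degenerate axis (all-zero component on this grid): sweep it
      v <- rep.int(Inf, nb)
      x <- rep.int(gN[1L], nb)
      for (xx in gN) {
        vv <- a * xx * xx + b * xx + d
        upd <- vv < v
        x[upd] <- xx
        v[upd] <- vv
      }
    }
    i <- which.min(v)
    if (v[i] < bestVal) {
      bestVal <- v[i]
      bestC <- c(P[i, ], x[i])
    }
    start <- start + nb
  }
  list(best = bestC, value = sqrt(max(bestVal, 0) / M), nEval = nEval)
}

# Shared fit preparation: common grid, unit-normalised reference matrix and
# the Gram-form pieces of the objective.
.prepareFit <- function(mixture, library, select = NULL) {
  stopifnot(is(mixture, "Spectrum"), is(library, "ComponentLibrary"))
  grid <- commonGrid(mixture, library)
  y <- mixture@absorbances[match(grid, mixture@wavenumbers)]
  A <- libraryMatrix(library, grid, select = select)
  N <- nrow(A)
  M <- length(grid)
  if (M < 10L * N)
    warning("only ", M, " shared wavenumbers for ", N,
            " components; the fit is weakly over-determined", call. = FALSE)
  list(grid = grid, y = y, A = A, N = N, M = M,
       G = A %*% t(A), h = drop(A %*% y), k = sum(y * y))
}
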