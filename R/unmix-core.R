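#' @include grid-search.R
NULL

#' Beer's-law forward model for a mixture spectrum
#'
#' Under Beer's law the absorbance of a dilute mixture is, at every
#' wavenumber, the concentration-weighted linear sum of the unit-concentration
#' component absorbances: A_m = sum_n C_n * A_{n,m}.
#'
#' @param concentrations numeric vector, percent, one value per library
#'   component (in library order).
#' @param library a [ComponentLibrary-class]; all selected reference spectra
#'   must share one wavenumber grid (or supply `grid`).
#' @param grid optional wavenumber grid to resample onto; defaults to the
#'   shared grid of the selected references.
#' @param select reference selection, see [libraryMatrix()].
#' @return a [Spectrum-class] of the modelled mixture.
#' @examples
#' g <- seq(1000, 1100, by = 1)
#' lib <- ComponentLibrary(list(
#'   ComponentRecord("a", Spectrum(g, dnorm(g, 1030, 8) / 50)),
#'   ComponentRecord("b", Spectrum(g, dnorm(g, 1070, 10) / 50))))
#' mix <- beerLawMixture(c(2, 3), lib)
#' @export
beerLawMixture <- function(concentrations, library, grid = NULL,
                           select = NULL) {
  stopifnot(is(library, "ComponentLibrary"))
  N <- length(library)
  if (length(concentrations) != N)
    .inputError("expected ", N, " concentrations, got ",
                length(concentrations))
  if (is.null(grid)) {
    grids <- lapply(library@components,
                    function(r) r@spectra[[1L]]@wavenumbers)
    grid <- grids[[1L]]
    same <- all(vapply(grids, function(g)
      length(g) == length(grid) && all(g == grid), logical(1)))
    if (!same)
      .inputError("library spectra are not on one grid; pass `grid` or ",
                  "resample first")
  }
  A <- libraryMatrix(library, grid, select = select)
  Spectrum(grid, drop(crossprod(A, as.numeric(concentrations))),
           label = "modelled mixture")
}

#' @describeIn rmsError evaluate the objective for a concentration vector:
#'   sqrt((1/M) * sum_m (A_m^mix - sum_n C_n A_{n,m})^2), computed directly
#'   on the common grid of `mixture` and `library`.
#' @param library a [ComponentLibrary-class].
#' @param mixture a [Spectrum-class].
#' @param select reference selection, see [libraryMatrix()].
#' @export
setMethod("rmsError", "numeric", function(x, library, mixture, select = NULL) {
  prep <- .prepareFit(mixture, library, select = select)
  if (length(x) != prep$N)
    .inputError("expected ", prep$N, " concentrations, got ", length(x))
  r <- prep$y - drop(crossprod(prep$A, x))
  sqrt(mean(r * r))
})

.passRecord <- function(pass, grids, step, frozen, res) {
  list(pass = pass,
       lower = vapply(grids, min, numeric(1)),
       upper = vapply(grids, max, numeric(1)),
       step = step,
       frozen = frozen,
       best = res$best,
       rmsError = res$value,
       nEvaluations = res$nEval)
}

.finishFit <- function(prep, best, passes, converged, library,
                       refit = NA) {
  names(best) <- rownames(prep$A)
  # final rmsError recomputed directly (not via the Gram form) for accuracy
  r <- prep$y - drop(crossprod(prep$A, best))
  new("FitResult", concentrations = best, rmsError = sqrt(mean(r * r)),
      passes = passes, convergedComponents = converged,
      refitOccurred = as.logical(refit))
}

#' Single mesh method: exhaustive concentration-mesh search
#'
#' Evaluates the RMS residual for every combination of mesh concentrations
#' and returns the minimising point. Exact within the mesh resolution and
#' immune to local minima, but the mesh cardinality grows as
#' points^N; a safety cap refuses runs above `maxEvaluations` and points to
#' [mplmFit()].
#'
#' Ties at equal residual are broken toward the lexicographically smallest
#' concentration vector in component order.
#'
#' @param mixture measured [Spectrum-class].
#' @param library [ComponentLibrary-class] of references.
#' @param mesh a [MeshSpec-class] (scalars recycled across components).
#' @param select reference selection, see [libraryMatrix()].
#' @param maxEvaluations safety cap on mesh cardinality (default 1e8).
#' @param chunkSize mesh points evaluated per block.
#' @return a [FitResult-class] with a single pass record whose
#'   `nEvaluations` is the full mesh cardinality.
#' @seealso [mplmFit()]
#' @export
smmFit <- function(mixture, library, mesh, select = NULL,
                   maxEvaluations = 1e8, chunkSize = 2^20) {
  stopifnot(is(mesh, "MeshSpec"))
  prep <- .prepareFit(mixture, library, select = select)
  N <- prep$N
  lo <- rep_len(mesh@lower, N)
  up <- rep_len(mesh@upper, N)
  st <- rep_len(mesh@step, N)
  grids <- lapply(seq_len(N), function(n) .meshPoints(lo[n], up[n], st[n]))
  size <- prod(vapply(grids, length, integer(1)))
  if (size > maxEvaluations)
    .fitError("mesh has ", format(size, big.mark = ","), " points, above the ",
              "cap of ", format(maxEvaluations, big.mark = ","),
              "; use mplmFit() for fine precision on many components")
  res <- .gridSearch(grids, prep$G, prep$h, prep$k, prep$M, chunkSize)
  passes <- list(.passRecord(1L, grids, st, rep(FALSE, N), res))
  .finishFit(prep, res$best, passes, rep(FALSE, N), library)
}

#' Multi-pass local adaptive mesh refinement (MPLM) fit
#'
#' Pass 1 is an exhaustive coarse-mesh search (the single mesh method) at
#' step s1 over the first-pass bounds. Each subsequent pass centres a finer
#' mesh on the previous best point: the new mesh spans `backoff` previous
#' steps in each direction and its step is s[i+1] = s[i] * backoff /
#' reduction (a fivefold shrink with the defaults B = 0.8, r = 4). Meshes
#' are clipped to the global concentration bounds; the previous best point
#' is always a point of the next mesh, so the best residual can never
#' increase from pass to pass. A component whose next step would drop below
#' `freezeStep` is frozen at its best value and excluded from further
#' looping; the fit stops after `maxPasses` passes or when every component
#' is frozen.
#'
#' @param mixture measured [Spectrum-class].
#' @param library [ComponentLibrary-class] of references.
#' @param config an [MPLMConfig-class]; `firstStep`, `lowerBound` and
#'   `upperBound` may be per-component vectors.
#' @param select reference selection, see [libraryMatrix()].
#' @return a [FitResult-class] with the full pass history.
#' @examples
#' g <- seq(1000, 1400, by = 2)
#' lib <- ComponentLibrary(list(
#'   ComponentRecord("a", Spectrum(g, 0.02 * exp(-(g - 1100)^2 / 800))),
#'   ComponentRecord("b", Spectrum(g, 0.05 * exp(-(g - 1300)^2 / 1500)))))
#' mix <- beerLawMixture(c(12.5, 3.75), lib)
#' fit <- mplmFit(mix, lib)
#' concentrations(fit)
#' @export
mplmFit <- function(mixture, library, config = MPLMConfig(), select = NULL) {
  stopifnot(is(config, "MPLMConfig"))
  validObject(config)
  prep <- .prepareFit(mixture, library, select = select)
  N <- prep$N
  gLo <- rep_len(config@lowerBound, N)
  gUp <- rep_len(config@upperBound, N)
  if (!is.null(config@firstPassBounds)) {
    fp <- config@firstPassBounds
    lo1 <- rep_len(fp@lower, N)
    up1 <- rep_len(fp@upper, N)
    s <- rep_len(fp@step, N)
  } else {
    lo1 <- gLo
    up1 <- gUp
    s <- rep_len(config@firstStep, N)
  }
  B <- config@backoff
  r <- config@reduction
  frozen <- rep(FALSE, N)
  passes <- vector("list", config@maxPasses)
  best <- NULL
  nPass <- 0L
  for (pass in seq_len(config@maxPasses)) {
    if (pass == 1L) {
      grids <- lapply(seq_len(N), function(n) .meshPoints(lo1[n], up1[n], s[n]))
    } else {
      sNew <- s * B / r
      frozen <- frozen | (sNew < config@freezeStep)
      if (all(frozen)) break
      grids <- vector("list", N)
      for (n in seq_len(N)) {
        if (frozen[n]) {
          grids[[n]] <- best[n]
        } else {
          half <- floor(B * s[n] / sNew[n] + 1e-9)  # = floor(r)
          pts <- best[n] + sNew[n] * (-half:half)
          pts <- pts[pts >= gLo[n] - 1e-9 & pts <= gUp[n] + 1e-9]
          if (!length(pts))
            .fitError("empty mesh for component ", n, " after clipping to [",
                      gLo[n], ", ", gUp[n], "]")
          grids[[n]] <- pts
          s[n] <- sNew[n]
        }
      }
    }
    res <- .gridSearch(grids, prep$G, prep$h, prep$k, prep$M, config@chunkSize)
    best <- res$best
    nPass <- pass
    passes[[pass]] <- .passRecord(pass, grids, s, frozen, res)
  }
  converged <- (s * B / r) < config@freezeStep
  .finishFit(prep, best, passes[seq_len(nPass)], converged, library)
}

#' Fit with concentration-matched references and automatic re-fit
#'
#' For samples where Beer's law holds only approximately (aqueous solutions:
#' water-solute interaction, detector saturation), references measured at a
#' concentration close to the actual one unmix more accurately. Each
#' component's reference nearest the initial guess is selected (normalised to
#' unit concentration) and [mplmFit()] is run. If any fitted concentration
#' deviates from its guess by more than `threshold` (relative, default 15 %),
#' references are re-selected nearest the fitted values and the fit is run
#' once more.
#'
#' @param mixture measured [Spectrum-class].
#' @param library [ComponentLibrary-class]; components may carry several
#'   reference concentrations.
#' @param config an [MPLMConfig-class].
#' @param initialGuess numeric, expected concentration per component
#'   (percent).
#' @param threshold relative deviation that triggers the re-fit
#'   (default 0.15).
#' @return a [FitResult-class]; `refitOccurred(x)` reports whether the
#'   second fit ran.
#' @export
matchedReferenceRefit <- function(mixture, library, config = MPLMConfig(),
                                  initialGuess, threshold = 0.15) {
  stopifnot(is(library, "ComponentLibrary"))
  N <- length(library)
  if (length(initialGuess) != N)
    .inputError("initialGuess must have one value per component")
  multi <- any(vapply(library@components,
                      function(r) length(r@refConcs) > 1L, logical(1)))
  fit <- mplmFit(mixture, library, config, select = initialGuess)
  if (!multi) {
    fit@refitOccurred <- FALSE
    return(fit)
  }
  c1 <- concentrations(fit)
  dev <- abs(c1 - initialGuess) / pmax(abs(initialGuess),
                                       .Machine$double.eps)
  if (any(dev > threshold)) {
    fit <- mplmFit(mixture, library, config, select = c1)
    fit@refitOccurred <- TRUE
  } else {
    fit@refitOccurred <- FALSE
  }
  fit
}

#' Goodness-of-fit statistics for a modelled spectrum
#'
#' Regresses the measured absorbances (y) on the computed ones (x) by
#' ordinary least squares, y = a x + b, and reports the slope a, intercept
#' b, squared correlation R^2 and the RMS residual of measured minus
#' computed. A perfect model gives a = 1, b = 0, R^2 = 1, rmsError = 0;
#' deviations flag missing or spurious components.
#'
#' @param mixture measured [Spectrum-class].
#' @param fittedModel computed [Spectrum-class] on the same grid (e.g. from
#'   [beerLawMixture()] with fitted concentrations).
#' @return a [FitStatistics-class].
#' @seealso [formatFitStatistics()]
#' @export
fitStatistics <- function(mixture, fittedModel) {
  stopifnot(is(mixture, "Spectrum"), is(fittedModel, "Spectrum"))
  if (length(mixture) != length(fittedModel) ||
      any(abs(mixture@wavenumbers - fittedModel@wavenumbers) > 1e-6))
    .inputError("mixture and fitted model must share one wavenumber grid")
  y <- mixture@absorbances
  x <- fittedModel@absorbances
  if (stats::var(x) <= 0)
    .fitError("computed spectrum is constant; measured-vs-computed ",
              "regression is degenerate")
  co <- stats::coef(stats::lm(y ~ x))
  r2 <- stats::cor(x, y)^2
  new("FitStatistics", rmsError = sqrt(mean((y - x)^2)),
      slope = unname(co[2L]), intercept = unname(co[1L]), rSquared = r2)
}

#' Render fit statistics in compact diagnostic form
#'
#' Reports the four indicators on scales where smaller uniformly means a
#' better fit: RMS residual as a percentage (x 100), 1 - R^2 and 1 - slope
#' multiplied by 1e4, and the intercept multiplied by 1e5.
#'
#' @param stats a [FitStatistics-class].
#' @return named numeric vector with elements `rmsError_pct`,
#'   `one_minus_R2_1e4`, `one_minus_slope_1e4`, `intercept_1e5`.
#' @export
formatFitStatistics <- function(stats) {
  stopifnot(is(stats, "FitStatistics"))
  c(rmsError_pct = 100 * stats@rmsError,
    one_minus_R2_1e4 = 1e4 * (1 - stats@rSquared),
    one_minus_slope_1e4 = 1e4 * (1 - stats@slope),
    intercept_1e5 = 1e5 * stats@intercept)
}

#' Operation-count reduction of MPLM relative to SMM
#'
#' For N components refined to a final precision p (percent) over the full
#' 0-100 % range, an exhaustive single mesh needs (100/p)^N residual
#' evaluations, while the multi-pass search needs about passes *
#' pointsPerDim^N. The ratio
#' \deqn{\eta = \frac{(100/p)^N}{\mathrm{passes} \times
#'   \mathrm{pointsPerDim}^N}}
#' estimates the speed-up at equal final precision. Defaults mirror the
#' reference schedule: p = 0.01, 9 passes, 10 points per dimension.
#'
#' @param nComponents N, number of components.
#' @param precision final mesh precision, percent (default 0.01).
#' @param passes number of refinement passes (default 9).
#' @param pointsPerDim mesh points per component per pass (default 10).
#' @return the dimensionless evaluation-count ratio.
#' @examples
#' speedupEstimate(1) # about 111
#' speedupEstimate(9) # about 1.1e26
#' @export
speedupEstimate <- function(nComponents, precision = 0.01, passes = 9,
                            pointsPerDim = 10) {
  stopifnot(nComponents > 0, precision > 0, passes > 0, pointsPerDim > 0)
  (100 / precision)^nComponents / (passes * pointsPerDim^nComponents)
}
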