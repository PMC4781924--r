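# Shared fixtures and independent oracles for the test suite.

# small, fast wavenumber grid for most tests (401 points)
testGrid <- function() seq(1000, 1800, by = 2)

# low-overlap synthetic library on the small grid
testLibrary <- function(n = 3, seed = 11, grid = testGrid()) {
  generateLibrary(n, grid = grid, seed = seed)
}

# Independent exhaustive-search oracle: direct objective evaluation with
# plain loops, no Gram form, no axis shortcut. Only for tiny meshes.
naiveGridArgmin <- function(mixture, library, grids) {
  grid <- commonGrid(mixture, library)
  A <- libraryMatrix(library, grid)
  y <- absorbances(resampleToGrid(mixture, grid))
  # enumerate with component 1 varying slowest (lexicographic order)
  combos <- as.matrix(expand.grid(rev(grids)))
  combos <- combos[, rev(seq_len(ncol(combos))), drop = FALSE]
  eps <- apply(combos, 1L, function(cc)
    sqrt(mean((y - drop(crossprod(A, cc)))^2)))
  i <- which.min(eps)
  list(best = unname(combos[i, ]), value = eps[i])
}

# last executed (unfrozen) mesh step of a fit, per component
finalStep <- function(fit) {
  ph <- passHistory(fit)
  ph[[length(ph)]]$step
}

# two clearly distinct synthetic endpoint spectra for titration tests
titrationEndpoints <- function(grid = testGrid()) {
  list(protonated = generateComponentSpectrum(
         peakModel(c(1280, 1710), c(15, 20), c(0.03, 0.05)), grid,
         label = "protonated"),
       deprotonated = generateComponentSpectrum(
         peakModel(c(1415, 1560), c(15, 18), c(0.04, 0.045)), grid,
         label = "deprotonated"))
}

# exact two-endpoint blend
blendSpectrum <- function(fp, fd, ends) {
  Spectrum(wavenumbers(ends$protonated),
           fp * absorbances(ends$protonated) +
             fd * absorbances(ends$deprotonated))
}

# two-chamber equilibration curves from the symmetric model
diffusionSeries <- function(k, times) {
  e <- exp(-k * times)
  list(times = times, source = 0.5 * (1 + e), sink = 0.5 * (1 - e))
}
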