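test_that("the Beer's-law forward model is an exact weighted sum", {
  w <- c(1000, 1001)
  lib <- ComponentLibrary(list(
    ComponentRecord("a", Spectrum(w, c(0.01, 0.02))),
    ComponentRecord("b", Spectrum(w, c(0.03, 0.01)))))
  suppressWarnings({
    # C = (2, 3): elementwise 2*A1 + 3*A2
    expect_equal(absorbances(beerLawMixture(c(2, 3), lib)), c(0.11, 0.07))
    # all-zero concentrations give the zero spectrum
    expect_equal(absorbances(beerLawMixture(c(0, 0), lib)), c(0, 0))
  })
  # N = 1, C = 1 reproduces the component spectrum
  lib1 <- testLibrary(1, seed = 3)
  suppressWarnings(
    expect_equal(absorbances(beerLawMixture(1, lib1)),
                 absorbances(referenceSpectra(lib1[[1]])[[1]])))
  suppressWarnings(expect_error(beerLawMixture(c(1, 2, 3), lib), "expected 2"))
})

test_that("the RMS objective matches its closed form and scales linearly", {
  lib <- testLibrary(2, seed = 7)
  truth <- c(4, 1.5)
  mix <- synthesizeMixture(lib, truth)
  # perfect model gives zero residual
  expect_equal(rmsError(truth, lib, mix), 0)

  # M = 3 residuals (0.01, -0.01, 0.02): sqrt(0.0006/3) = sqrt(0.0002)
  w <- c(1, 2, 3)
  libz <- ComponentLibrary(list(ComponentRecord("z", Spectrum(w, c(0, 0, 0)))))
  mixr <- Spectrum(w, c(0.01, -0.01, 0.02))
  suppressWarnings({
    expect_equal(rmsError(0, libz, mixr), sqrt(2e-4))
    expect_equal(round(rmsError(0, libz, mixr), 6), 0.014142)
    # doubling all residuals doubles the RMS error
    mixr2 <- Spectrum(w, 2 * absorbances(mixr))
    expect_equal(rmsError(0, libz, mixr2), 2 * rmsError(0, libz, mixr))
  })

  # objective identity: M * eps^2 equals the sum of squared residuals
  set.seed(1)
  for (i in 1:5) {
    cc <- runif(2, 0, 10)
    model <- beerLawMixture(cc, lib)
    ssr <- sum((absorbances(mix) - absorbances(model))^2)
    expect_equal(rmsError(cc, lib, mix)^2 * length(mix), ssr,
                 tolerance = 1e-12)
  }
})

test_that("the Gram-form evaluation agrees with the direct objective", {
  lib <- testLibrary(3, seed = 9)
  mix <- synthesizeMixture(lib, c(5, 2, 8), NoiseSpec(0.005, seed = 2))
  prep <- mplmfit:::.prepareFit(mix, lib)
  set.seed(4)
  for (i in 1:20) {
    cc <- runif(3, 0, 12)
    gram <- sqrt(max(drop(cc %*% prep$G %*% cc) - 2 * sum(prep$h * cc) +
                       prep$k, 0) / prep$M)
    expect_equal(gram, rmsError(cc, lib, mix), tolerance = 1e-10)
  }
})

test_that("exhaustive SMM recovers on-mesh truths exactly", {
  lib1 <- testLibrary(1, seed = 21)
  mix1 <- synthesizeMixture(lib1, 30)
  fit1 <- smmFit(mix1, lib1, MeshSpec(0, 50, 10))
  expect_equal(unname(concentrations(fit1)), 30)
  expect_equal(rmsError(fit1), 0)
  expect_equal(passHistory(fit1)[[1]]$nEvaluations, 6)

  lib2 <- testLibrary(2, seed = 22)
  mix2 <- synthesizeMixture(lib2, c(20, 30))
  fit2 <- smmFit(mix2, lib2, MeshSpec(0, 50, 10))
  expect_equal(unname(concentrations(fit2)), c(20, 30))
  expect_equal(passHistory(fit2)[[1]]$nEvaluations, 36)
})

test_that("SMM equals an independent naive exhaustive loop", {
  for (seed in 1:8) {
    lib <- testLibrary(2, seed = seed + 100)
    truth <- c(3.7, 8.2)
    mix <- synthesizeMixture(lib, truth, NoiseSpec(0.01, seed = seed))
    mesh <- MeshSpec(0, 12, 1.5)
    fit <- smmFit(mix, lib, mesh)
    grids <- lapply(1:2, function(i) seq(0, 12, by = 1.5))
    oracle <- naiveGridArgmin(mix, lib, grids)
    expect_equal(unname(concentrations(fit)), oracle$best)
    expect_equal(rmsError(fit), oracle$value, tolerance = 1e-10)
  }
})

test_that("the SMM mesh cap points users to MPLM", {
  lib <- testLibrary(3, seed = 30)
  mix <- synthesizeMixture(lib, c(1, 2, 3))
  expect_error(smmFit(mix, lib, MeshSpec(0, 50, 0.01)), "mplmFit")
})

test_that("MPLM refinement matches fine-mesh SMM and recovers identities", {
  # mixture equal to one library component at 10 %
  lib <- testLibrary(3, seed = 31)
  A1 <- referenceSpectra(lib[[1]])[[1]]
  mix <- Spectrum(wavenumbers(A1), 10 * absorbances(A1))
  fit <- mplmFit(mix, lib)
  fs <- finalStep(fit)
  expect_lt(abs(concentrations(fit)[1] - 10), fs[1] + 1e-9)
  expect_lt(max(concentrations(fit)[2:3]), fs[2] + 1e-9)

  # 2-component noisy instance: MPLM equals global fine-mesh SMM within one
  # final step per component
  lib2 <- testLibrary(2, seed = 32)
  mix2 <- synthesizeMixture(lib2, c(7.3, 21.6), NoiseSpec(0.005, seed = 5))
  mfit <- mplmFit(mix2, lib2)
  sfit <- smmFit(mix2, lib2, MeshSpec(0, 50, 0.016))
  expect_lt(max(abs(concentrations(mfit) - concentrations(sfit))),
            max(finalStep(mfit)) + 0.016 + 1e-9)
})

test_that("MPLM pass history follows the configured schedule", {
  lib <- testLibrary(1, seed = 33)
  mix <- synthesizeMixture(lib, 12.3)
  cfg <- MPLMConfig(firstStep = 10, backoff = 0.8, reduction = 4,
                    freezeStep = 1e-9, maxPasses = 9)
  fit <- mplmFit(mix, lib, cfg)
  steps <- vapply(passHistory(fit), function(p) p$step[1], numeric(1))
  expect_length(steps, 9L)
  # s[i+1] = s[i] * B / r: a fivefold shrink per pass with the defaults
  expect_equal(steps[-1] / steps[-9], rep(0.2, 8))
  expect_equal(steps[9], 10 / 5^8)

  # freezing at 0.01 % stops refinement after the 0.016 pass
  fit2 <- mplmFit(mix, lib, MPLMConfig())
  steps2 <- vapply(passHistory(fit2), function(p) p$step[1], numeric(1))
  expect_equal(steps2, c(10, 2, 0.4, 0.08, 0.016))
  expect_true(all(convergedComponents(fit2)))
})

test_that("noiseless mixtures are recovered within the final mesh step", {
  for (seed in 1:5) {
    lib <- testLibrary(3, seed = seed + 200)
    truth <- round(runif(3, 0.5, 12), 3)
    mix <- synthesizeMixture(lib, truth)
    fit <- mplmFit(mix, lib)
    expect_true(all(abs(concentrations(fit) - truth) <=
                      finalStep(fit) + 1e-9),
                info = paste("seed", seed))
  }
})

test_that("the best residual never increases across MPLM passes", {
  for (seed in 1:6) {
    lib <- testLibrary(2 + seed %% 2, seed = seed + 300)
    truth <- runif(length(lib), 0, 12)
    mix <- synthesizeMixture(lib, truth, NoiseSpec(0.01, seed = seed))
    fit <- mplmFit(mix, lib)
    eps <- vapply(passHistory(fit), function(p) p$rmsError, numeric(1))
    expect_true(all(diff(eps) <= 1e-12), info = paste("seed", seed))
  }
})

test_that("fit statistics reproduce ordinary least squares", {
  g <- seq(1, 3)
  # perfect fit
  s <- Spectrum(g, c(0.01, 0.02, 0.03))
  fs <- fitStatistics(s, s)
  expect_equal(slope(fs), 1)
  expect_equal(intercept(fs), 0)
  expect_equal(rSquared(fs), 1)
  expect_equal(rmsError(fs), 0)

  # closed-form normal equations oracle
  x <- c(0.01, 0.02, 0.03)
  y <- c(0.012, 0.019, 0.032)
  fs2 <- fitStatistics(Spectrum(g, y), Spectrum(g, x))
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b <- mean(y) - a * mean(x)
  expect_equal(slope(fs2), a)
  expect_equal(intercept(fs2), b)
  expect_equal(rSquared(fs2), cor(x, y)^2)
  expect_equal(rmsError(fs2), sqrt(mean((y - x)^2)))

  # exact affine case: measured = 2 * computed
  fs3 <- fitStatistics(Spectrum(g, 2 * x), Spectrum(g, x))
  expect_equal(slope(fs3), 2)
  expect_equal(intercept(fs3), 0)
  expect_equal(rSquared(fs3), 1)

  # constant computed spectrum is degenerate
  expect_error(fitStatistics(Spectrum(g, y), Spectrum(g, rep(0.01, 3))),
               "degenerate")

  # compact rendering scales
  r <- formatFitStatistics(fs2)
  expect_equal(unname(r["one_minus_slope_1e4"]), 1e4 * (1 - a))
  expect_equal(unname(r["intercept_1e5"]), 1e5 * b)
  expect_equal(unname(r["rmsError_pct"]), 100 * rmsError(fs2))
})

test_that("the speed-up estimator evaluates its literal closed form", {
  expect_equal(speedupEstimate(1), 1e4 / 90)
  expect_equal(speedupEstimate(9), 1e36 / (9 * 1e9))
  expect_equal(speedupEstimate(2, precision = 100, passes = 1,
                               pointsPerDim = 1), 1)
  for (n in 1:9)
    expect_equal(speedupEstimate(n), (100 / 0.01)^n / (9 * 10^n))
})

test_that("matched-reference fitting selects references near the guess", {
  grid <- testGrid()
  lib <- generateLibrary(2, grid = grid, seed = 40, refConcs = c(5, 20),
                         nonlinearity = 0.97)
  # nearest-reference selection oracle: guess 5 -> the 5 % references,
  # guess 19 -> the 20 % references
  expect_equal(attr(libraryMatrix(lib, grid, select = c(5, 5)), "refConcs"),
               c(5, 5))
  expect_equal(attr(libraryMatrix(lib, grid, select = c(19, 19)), "refConcs"),
               c(20, 20))

  # mixture built from the 20 % references at C = 19: guessing 5 triggers a
  # re-fit against the 20 % references
  mix <- beerLawMixture(c(19, 19), lib, select = c(20, 20))
  fit <- matchedReferenceRefit(mix, lib, MPLMConfig(), c(5, 5))
  expect_true(refitOccurred(fit))
  expect_true(all(abs(concentrations(fit) - 19) < 0.1))

  # guess equal to the fitted value: no re-fit
  fit2 <- matchedReferenceRefit(mix, lib, MPLMConfig(),
                                concentrations(fit))
  expect_false(refitOccurred(fit2))

  # single-reference libraries behave exactly as mplmFit
  lib1 <- testLibrary(2, seed = 41)
  mix1 <- synthesizeMixture(lib1, c(4, 6))
  fitA <- matchedReferenceRefit(mix1, lib1, MPLMConfig(), c(1, 1))
  fitB <- mplmFit(mix1, lib1)
  expect_false(refitOccurred(fitA))
  expect_equal(concentrations(fitA), concentrations(fitB))
})
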