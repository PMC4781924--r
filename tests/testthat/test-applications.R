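test_that("time-series tracking recovers generating trajectories", {
  lib <- testLibrary(2, seed = 51)
  # constant noiseless series: constant fitted trajectories
  tsc <- generateTimeSeries(lib, list(function(t) 8, function(t) 3),
                            times = c(0, 5, 10))
  fitc <- trackTimeSeries(tsc, lib)
  expect_true(all(apply(concentrations(fitc), 2, function(x)
    max(x) - min(x)) == 0))
  expect_true(all(abs(concentrations(fitc)[1, ] - c(8, 3)) <= 0.016 + 1e-9))

  # single time point equals one mplmFit
  fit1 <- trackTimeSeries(tsc[1], lib)
  expect_equal(concentrations(fit1)[1, ],
               concentrations(mplmFit(tsc[[1]]$spectrum, lib)))

  # linear rise/fall with 0.1 % noise: fitted slopes within 5 % of truth
  traj <- list(function(t) 10 - 0.012 * t, function(t) 0.03 * t)
  times <- seq(0, 400, by = 50)
  tsn <- generateTimeSeries(lib, traj, times, NoiseSpec(0.001, seed = 61))
  fitn <- trackTimeSeries(tsn, lib)
  s1 <- coef(lm(concentrations(fitn)[, 1] ~ times))[2]
  s2 <- coef(lm(concentrations(fitn)[, 2] ~ times))[2]
  expect_lt(abs(s1 / -0.012 - 1), 0.05)
  expect_lt(abs(s2 / 0.03 - 1), 0.05)
  expect_true(all(vapply(fitn@errors, is.null, logical(1))))
})

test_that("relative normalization removes bulk concentration changes", {
  fit <- new("TimeSeriesFit", times = c(0, 1, 2),
             concentrations = cbind(a = c(4, 3, 2), b = c(1, 2, 3)),
             errors = vector("list", 3))
  nsum <- normalizeRelative(fit, "sum_of_tracked")
  expect_equal(unname(rowSums(normalizedConcentrations(nsum))), rep(1, 3))

  # uniform evaporation (everything x 1.2) leaves sum-mode values unchanged
  fitEvap <- new("TimeSeriesFit", times = c(0, 1, 2),
                 concentrations = fit@concentrations * 1.2,
                 errors = vector("list", 3))
  expect_equal(normalizedConcentrations(normalizeRelative(fitEvap,
                                                          "sum_of_tracked")),
               normalizedConcentrations(nsum))

  # reference-time mode on a constant series gives all ones
  fitConst <- new("TimeSeriesFit", times = c(0, 1),
                  concentrations = cbind(a = c(5, 5), b = c(2, 2)),
                  errors = vector("list", 2))
  expect_true(all(normalizedConcentrations(
    normalizeRelative(fitConst, "reference_time")) == 1))

  # zero denominators are refused, naming the time point
  fitZero <- new("TimeSeriesFit", times = c(0, 7),
                 concentrations = cbind(a = c(1, 0), b = c(1, 0)),
                 errors = vector("list", 2))
  expect_error(normalizeRelative(fitZero, "sum_of_tracked"), "7")
})

test_that("protonation fractions come out of two-endpoint unmixing", {
  ends <- titrationEndpoints()
  # sample equal to the protonated endpoint
  fr1 <- protonationFractionFit(ends$protonated, ends$protonated,
                                ends$deprotonated)
  expect_lt(abs(fr1$fractionProtonated - 1), 0.002 + 1e-9)
  expect_lt(fr1$fractionDeprotonated, 0.002 + 1e-9)

  # forward-synthesized 0.4 / 0.6 blend
  fr2 <- protonationFractionFit(blendSpectrum(0.4, 0.6, ends),
                                ends$protonated, ends$deprotonated)
  expect_lt(abs(fr2$fractionProtonated - 0.4), 0.002 + 1e-9)
  expect_lt(abs(fr2$fractionDeprotonated - 0.6), 0.002 + 1e-9)

  # mean of the endpoints: (0.5, 0.5) by symmetry
  fr3 <- protonationFractionFit(blendSpectrum(0.5, 0.5, ends),
                                ends$protonated, ends$deprotonated)
  expect_lt(abs(fr3$fractionProtonated - 0.5), 0.002 + 1e-9)
  expect_lt(abs(fr3$fractionDeprotonated - 0.5), 0.002 + 1e-9)

  # identical endpoints are ill-conditioned
  expect_error(protonationFractionFit(ends$protonated, ends$protonated,
                                      ends$protonated), "ill-conditioned")
})

test_that("fraction normalization and pH conversions are exact", {
  n <- fractionNormalize(0.48, 0.50)
  expect_equal(n$total, 0.98)
  expect_equal(n$fractionProtonated, 0.48 / 0.98)
  expect_equal(n$fractionDeprotonated, 0.50 / 0.98)
  expect_equal(fractionNormalize(0.5, 0.5)$total, 1.0)
  expect_equal(fractionNormalize(1, 0)$fractionProtonated, 1)
  expect_error(fractionNormalize(0, 0), "positive")

  # equal fractions: pH = pKa; ratio 10: one unit above
  expect_equal(phFromFractions(0.5, 0.5, 4.76), 4.76)
  expect_equal(phFromFractions(1 / 11, 10 / 11, 4.76), 5.76)
  expect_error(phFromFractions(0, 1, 4.76), "positive")

  # inverse pair round-trips to 1e-10 across pKa +/- 3
  for (ph in seq(1.76, 7.76, by = 0.5)) {
    f <- fractionsFromPh(ph, 4.76)
    expect_equal(f$fractionProtonated + f$fractionDeprotonated, 1)
    expect_equal(phFromFractions(f$fractionProtonated,
                                 f$fractionDeprotonated, 4.76), ph,
                 tolerance = 1e-10)
  }
})

test_that("calibration-curve pH interpolation is monotone and bounded", {
  phs <- seq(2, 8, by = 0.5)
  fr <- vapply(phs, function(p) fractionsFromPh(p, 4.76)$fractionProtonated,
               numeric(1))
  # hits the calibration points exactly
  expect_equal(phFromCalibration(fr[5], fr, phs), phs[5])
  # interpolates monotonically between them
  mid <- phFromCalibration(sort(c(fr[3], fr[4], (fr[3] + fr[4]) / 2)),
                           fr, phs)
  expect_true(all(diff(mid) < 0))
  expect_error(phFromCalibration(0.99999, fr, phs), "extrapolation")
})

test_that("permeability is recovered from two-chamber equilibration", {
  times <- seq(0, 259200, by = 43200) # six samplings over three days
  kTrue <- 8e-6
  aov <- 4
  d <- diffusionSeries(kTrue, times)
  fit <- permeabilityFit(d$times, d$source, d$sink, aov)
  # noiseless self-consistency within 1 %
  expect_lt(abs(permeability(fit) / (kTrue / aov) - 1), 0.01)
  expect_lt(abs(rateConstant(fit) / kTrue - 1), 0.01)

  # 2 % noise, 20 seeds: RMSE of the recovered permeability below 5 %
  relErr <- vapply(1:20, function(seed) {
    set.seed(seed + 400)
    src <- d$source + rnorm(length(times), 0, 0.02)
    snk <- d$sink + rnorm(length(times), 0, 0.02)
    permeability(permeabilityFit(times, src, snk, aov)) /
      (kTrue / aov) - 1
  }, numeric(1))
  expect_lt(sqrt(mean(relErr^2)), 0.05)

  # equilibrated series: rate constant unidentifiable
  expect_warning(permeabilityFit(times, rep(0.5, 7), rep(0.5, 7), aov),
                 "equilibrium")
  # no net transfer: k pinned at zero with a warning
  expect_warning(permeabilityFit(times, rep(1, 7), rep(0, 7), aov),
                 "not positive")
  expect_error(permeabilityFit(c(0, 1), c(1, 1), c(0, 0), aov), "3 time")
  expect_error(permeabilityFit(c(0, 1, 1), c(1, 1, 1), c(0, 0, 0), aov),
               "increasing")
})
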