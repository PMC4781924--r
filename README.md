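# mplmfit

Quantitative spectral unmixing for FTIR (and other linearly additive
spectroscopies) by direct mesh search: the transparent alternative to
black-box chemometrics packages for labs that need component
concentrations out of mixture spectra.

## Who this is for

Anyone with (i) an absorbance spectrum of a mixture of *known* substances
and (ii) reference spectra of the pure components, who wants the component
concentrations without building and maintaining a commercial QA model:
fermentation and cell-culture monitoring, fuel-cell chemistry, titration
and pH tracking, membrane transport measurements.

## The method

Beer's law makes a dilute mixture's absorbance the concentration-weighted
sum of its component absorbances at every wavenumber:

    A_m(mix) = sum_n C_n * A_{n,m},   m = 1..M wavenumbers, n = 1..N components

Concentrations are estimated by minimising the RMS residual

    eps_RMS(C) = sqrt( (1/M) * sum_m ( A_m(mix) - sum_n C_n A_{n,m} )^2 )

over a non-negative concentration mesh, two ways:

* **SMM** (single mesh method, `smmFit`): evaluate every mesh point.
  Exact within the mesh resolution; cost grows as points^N.
* **MPLM** (multi-pass local mesh refinement, `mplmFit`): a coarse
  exhaustive pass (step 10 % over 0–50 %), then up to 8 refinement passes
  that re-centre a fivefold-finer mesh on the best point so far (back-off
  B = 0.8 previous steps each side, step reduction s[i+1] = s[i]·B/r with
  r = 4), freezing each component once its step falls below 0.01 %. Same
  answer as a fine SMM at a tiny fraction of the evaluations
  (`speedupEstimate(9)` ≈ 1.1e26).

Around the core: goodness-of-fit diagnostics (`fitStatistics`: slope,
intercept and R² of measured-vs-computed absorbance, plus eps_RMS),
concentration-matched reference selection with an automatic >15 % re-fit
rule for aqueous work (`matchedReferenceRefit`), seeded synthetic
libraries/mixtures for validation (`generateLibrary`,
`synthesizeMixture`), and three applications: time-series tracking
(`trackTimeSeries`, `normalizeRelative`), protonation-state pH analysis
(`protonationFractionFit`, `phFromFractions`), and two-chamber membrane
permeability (`permeabilityFit`).

## Worked example

Fit a noisy synthetic three-component mixture:

```r
library(mplmfit)
lib   <- generateLibrary(3, seed = 8)          # seeded synthetic references
truth <- c(12.5, 3.2, 0.8)                     # percent
mix   <- synthesizeMixture(lib, truth, NoiseSpec(0.005, seed = 9))  # 0.5 % noise

fit <- mplmFit(mix, lib)
fit
#> FitResult: 5 pass(es), rmsError = 0.000644172 AU
#> component01 component02 component03
#>      12.496       3.200       0.800

model <- beerLawMixture(concentrations(fit), lib)
stats <- fitStatistics(resampleToGrid(mix, wavenumbers(model)), model)
round(formatFitStatistics(stats), 3)
#>        rmsError_pct    one_minus_R2_1e4 one_minus_slope_1e4       intercept_1e5
#>               0.064               0.264               0.151               0.133
```

All three concentrations come back within the final mesh step (0.016) of
the generating values despite 0.5 % noise; the residual (0.064 % in
absorbance) sits at the noise floor, and slope/intercept/R² of the
measured-vs-computed line are at their ideal values (1, 0, 1) to a few
parts in 1e4 — the signature of a complete, correct component set. A
missing or spurious component inflates all four numbers.

A shell interface wrapping the same functions ships in
`inst/scripts/mplm` (sub-commands `simulate`, `fit`, `titration`,
`diffusion`; JSON/CSV outputs plus a run manifest with input hashes and
the seed).

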