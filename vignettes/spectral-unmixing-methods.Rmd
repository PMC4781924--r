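---
title: "Mesh-refinement spectral unmixing: model, algorithm and design notes"
author: "mplmfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-refinement spectral unmixing: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplmfit)
```

## The model

Quantitative analysis of an infrared (or any linearly additive) absorbance
spectrum rests on Beer's law: for a dilute mixture of $N$ known components
measured at $M$ wavenumbers, the mixture absorbance at wavenumber $m$ is

$$A_m^{\mathrm{mix}} = \sum_{n=1}^{N} C_n\, A_{n,m},$$

where $A_{n,m}$ is the unit-concentration reference absorbance of component
$n$ and $C_n$ its concentration (percent throughout this package). Real
measurements are noisy, so the concentrations are estimated by minimising
the root-mean-square residual

$$\varepsilon_{\mathrm{RMS}}(C) =
  \sqrt{\tfrac{1}{M}\sum_{m=1}^{M}
  \Bigl(A_m^{\mathrm{mix}} - \sum_n C_n A_{n,m}\Bigr)^{2}},$$

over $C_n \ge 0$. `rmsError()` evaluates this objective; `beerLawMixture()`
is the forward model. $M \gg N$ is expected (the package warns below
$M < 10N$).

The objective is a convex quadratic in $C$, and classical least-squares
(SVD, PCA, PLS) machinery could minimise it in closed form. This package
deliberately takes the transparent route instead: evaluate
$\varepsilon_{\mathrm{RMS}}$ on an explicit concentration mesh and keep the
smallest value. That makes the estimator trivially auditable, imposes the
physical bound $C_n \ge 0$ for free, and generalises unchanged if the
forward model ever becomes non-quadratic (e.g. per-component reference
switching, below).

## SMM: the exhaustive single mesh

`smmFit()` evaluates every point of a rectangular mesh
(`MeshSpec(lower, upper, step)`, per-component values recycled). It is the
reference method and the test oracle: exact within the mesh resolution and
immune to local minima, but its cardinality grows as
$(\mathrm{span}/\mathrm{step})^N$, so a safety cap (default $10^8$ points)
refuses hopeless runs and points to `mplmFit()`. Ties at exactly equal
residual are broken toward the lexicographically smallest concentration
vector in component order — the choice is arbitrary but fixed, so results
are deterministic.

## MPLM: multi-pass local mesh refinement

`mplmFit()` runs the same exhaustive evaluation on a coarse first mesh
(step $s_1$, default 10 %, over global bounds 0–50 %), then repeatedly
re-centres a finer mesh on the best point so far. Two dimensionless knobs
control the schedule:

* **back-off** $B$ (default 0.8): the refined mesh spans $B\,s_i$ on each
  side of the previous best point, guarding against the coarse pass having
  landed one cell away from the optimum;
* **reduction** $r$ (default 4): the next step is
  $s_{i+1} = s_i\,B/r$ — a fivefold shrink per pass with the defaults.

Up to 9 passes are allowed. A component whose next step would fall below
`freezeStep` (default 0.01 %) is *frozen*: it keeps its best value and is
excluded from further looping, which is what keeps late passes cheap. With
the defaults the executed steps are 10, 2, 0.4, 0.08, 0.016; the nominal
9-pass floor would be $10/5^8 \approx 2.6\times10^{-5}$ %, far below any
spectroscopic noise floor, which is why freezing exists.

Two geometric details were genuinely open and are fixed as follows:

* **Mesh anchoring.** Refined meshes are built as
  $\{best + k\,s_{i+1} : k = -\lfloor r\rfloor,\dots,\lfloor r\rfloor\}$,
  clipped to the global bounds, rather than as a lower-anchored arithmetic
  progression from $best - B s_i$. For integer $r$ the two coincide away
  from the bounds; anchoring on the best point guarantees it is always a
  point of the next mesh, which makes the per-pass best residual provably
  non-increasing (the `FitResult` validity method asserts this on every
  fit) even for non-integer $r$ or when clipping bites at a bound.
* **Full cross-product passes.** Every pass evaluates the full Cartesian
  mesh over the active (unfrozen) components rather than refining one
  component at a time; with near-orthogonal spectra both converge to the
  same point, but the cross-product form is the one whose operation count
  the speed-up formula below assumes.

`speedupEstimate(N, precision, passes, pointsPerDim)` returns the literal
operation-count ratio $(100/p)^N / (\mathrm{passes}\cdot
\mathrm{points}^N)$ comparing a single exhaustive mesh at final precision
$p$ with the multi-pass schedule — about $1.1\times10^{26}$ for $N = 9$ at
$p = 0.01$ with 9 passes of $10^N$ points. It is a planning heuristic, not
a measured benchmark.

### Evaluation engine

Expanding the objective gives
$M\varepsilon^2 = C^{\top} G C - 2 h^{\top} C + k$ with $G = AA^{\top}$
($N \times N$), $h = A\,y$ and $k = y^{\top}y$ computed once per fit, so
the cost per mesh point is $O(N^2)$, independent of $M$. Meshes are
evaluated in chunks (`chunkSize`, default $2^{20}$ points; purely a
memory/speed trade-off). Along the last mesh axis the objective is an exact
parabola, so only the two mesh points bracketing its vertex can attain the
minimum; the engine evaluates exactly those instead of sweeping the axis.
Both devices are algebraic identities — the test suite cross-checks the
argmin against an independent naive double loop. Reported
`nEvaluations` counts mesh points considered, i.e. the mesh cardinality.

Near-perfect fits push $M\varepsilon^2$ into the cancellation regime of the
Gram form (absolute error around $10^{-13}$ of the leading terms); adjacent
mesh points at practically relevant steps differ by far more, so ranking is
unaffected, and the final reported $\varepsilon_{\mathrm{RMS}}$ is always
recomputed directly from the residual vector.

## Reference handling for aqueous samples

Beer's law holds only approximately in water (solute–water interaction,
detector saturation), so a component may carry reference spectra measured
at several concentrations. `libraryMatrix()` normalises each selected
reference to unit concentration; `matchedReferenceRefit()` implements the
pragmatic protocol: select references nearest an initial guess, fit, and if
any fitted concentration deviates from its guess by more than 15 %
(relative), re-select nearest the fitted values and fit once more. One
re-fit suffices in practice because reference switching perturbs the
answer only at the level of the Beer's-law deviation itself.

## The synthetic generator

No public corpus of matched component/mixture FTIR spectra exists at this
scale, so validation uses seeded synthetic data (`generateLibrary()`,
`synthesizeMixture()`, `generateTimeSeries()`):

* grid 800–3000 cm$^{-1}$ at 1.3 cm$^{-1}$ (≈1700 points), typical of
  aqueous mid-IR ATR work;
* per component 2–5 Gaussian peaks, amplitudes log-uniform over
  0.001–0.1 AU, so major and minor bands differ by orders of magnitude;
  Gaussian rather than Lorentzian/Voigt profiles because the unmixing
  method never exploits peak shape;
* `overlap = "low"` assigns each component its own wavenumber band
  (pairwise $|\rho| < 0.3$, enforced), `"high"` builds shifted re-scaled
  near-duplicates ($\rho > 0.9$) to emulate chemically similar media
  components;
* noise adds, per point, a draw from $\mathcal{N}(0, \mu\,|A_m|)$ —
  "0.5 % noise" is read as a *relative* standard deviation, the stated
  alternative (a fixed absolute standard deviation) being available via
  `NoiseSpec(kind = "absolute")` since the convention is ambiguous in the
  field;
* multi-concentration references scale as $C^{0.97}$, a mild nonlinearity
  that exercises the matched-reference machinery.

What the generator does **not** emulate: water-band structure and its
imperfect subtraction, baseline drift, atmospheric CO$_2$/H$_2$O lines,
instrument line-shape and detector nonlinearity beyond the $C^{0.97}$
hook. Passing tests therefore demonstrate the estimator's statistical
behaviour under the stated noise model, not robustness to every artefact
of real spectrometers.

Under this model, the standing verification experiment — nine components
at (10, 10, 10, 1, 10, 2, 2, 1, 1) %, first-pass bounds 0–12 at step 3
(chosen so no true value sits on any pass mesh), 0.5 % noise, five
replicates averaged — recovers every component to ≤ 2 % relative and
≤ 0.1 concentration-percent absolute error; the noiseless fit recovers
every component within the final executed step (0.024). `scripts/acceptance.R`
re-runs exactly this experiment.

## Applications

* **Time series** (`trackTimeSeries()`): independent MPLM fits per time
  point; per-point failures are recorded, not fatal.
  `normalizeRelative()` divides either by the per-time sum of tracked
  components (exactly cancelling uniform scale changes such as
  evaporation) or by the $t_0$ value per component. Which basis is
  appropriate depends on whether an internal standard is tracked; the
  choice is the user's.
* **Protonation state / pH** (`protonationFractionFit()`): a titration
  sample is unmixed against the two titration endpoint spectra. No
  sum-to-one constraint is imposed — the raw total (via
  `fractionNormalize()`) is a diagnostic for density drift along the
  titration. pH follows from Henderson–Hasselbalch
  (`phFromFractions()`, inverse `fractionsFromPh()`) or from a measured
  calibration curve (`phFromCalibration()`, monotone shape-preserving
  interpolation, extrapolation refused). The default titration fit
  refines fractions over [0, 1.5] down to a step of 0.002.
* **Membrane permeability** (`permeabilityFit()`): two equal well-mixed
  chambers equilibrate as $\mathrm{sink}(t) = \tfrac12(1 - e^{-kt})$,
  $\mathrm{source}(t) = \tfrac12(1 + e^{-kt})$ with
  $k = P\,(A/V_1 + A/V_2)$. $k$ is fitted by joint least squares on both
  series (golden-section minimisation on $[0, 50/t_{\min}]$); the
  geometry factor, which must be measured for the cell at hand, converts
  it to a permeability in cm/s. $k$ pinned at either interval end is
  reported with a warning (no net transfer, or equilibration faster than
  the sampling).

## Numerical choices and degenerate inputs

* Duplicate wavenumbers are an error, never averaged; descending input is
  sorted silently; absorbances may be negative (water-background
  subtraction) and are never clipped.
* Fitting grids: the mixture's own grid restricted to the intersection of
  all spans (references are interpolated linearly; the measured mixture is
  never interpolated, and extrapolation is refused everywhere).
* A component spectrum identically zero on the fitting grid makes the
  parabola axis degenerate; the engine falls back to sweeping that axis.
* Identical titration endpoints, constant computed spectra in
  `fitStatistics()`, and empty meshes after bound clipping are explicit
  errors rather than silently ill-conditioned fits.

## Problem sizes in the shipped tests

Most tests run on a 401-point grid with 1–3 components, where full
enumeration oracles are feasible; the nine-component verification above
runs on the full ~1700-point default grid (six MPLM fits in total across
the test suite and the acceptance script, each evaluating about
$8\times10^8$ mesh points). These sizes were chosen to exercise every code
path at desk scale.

## Known limitations

* No uncertainty estimates beyond repeat-run statistics; the mesh search
  returns a point estimate.
* No baseline or atmospheric correction; spectra are assumed
  pre-processed.
* JCAMP-DX support covers the uncompressed AFFN `(X++(Y..Y))` dialect
  only; compressed encodings are rejected with instructions.
* The two-chamber diffusion model assumes equal volumes and symmetric
  equilibration to ½; unequal-volume cells need the generalised model
  before `permeabilityFit()` applies.
* Local minima are possible in principle for strongly collinear
  libraries; the practical mitigation is re-running with a smaller
  $s_1$ and tightened first-pass bounds (`firstPassBounds`), which is the
  package's recommended recipe rather than an automatic safeguard.
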