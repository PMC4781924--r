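#' @include unmix-core.R
NULL

#' Default synthetic wavenumber grid
#'
#' 800 to 3000 cm^-1 at 1.3 cm^-1 spacing (about 1700 points), typical of
#' aqueous mid-infrared ATR measurements.
#'
#' @return numeric wavenumber vector.
#' @export
defaultGrid <- function() seq(800, 3000, by = 1.3)

#' Synthesize a component spectrum from Gaussian peaks
#'
#' Absorbance(v) = sum over peaks of amplitude * exp(-(v - center)^2 /
#' (2 width^2)). Deterministic; the Gaussian profile is the simplest smooth
#' stand-in for condensed-phase infrared bands, and the unmixing method is
#' agnostic to the exact peak shape.
#'
#' @param peaks data frame with numeric columns `center` (cm^-1), `width`
#'   (Gaussian sigma, cm^-1, > 0) and `amplitude` (AU). Zero rows give a
#'   zero spectrum.
#' @param grid numeric wavenumber vector.
#' @param label spectrum label.
#' @return a [Spectrum-class].
#' @export
generateComponentSpectrum <- function(peaks, grid = defaultGrid(),
                                      label = "") {
  stopifnot(is.data.frame(peaks),
            all(c("center", "width", "amplitude") %in% names(peaks)))
  if (nrow(peaks) && any(peaks$width <= 0))
    .inputError("peak widths must be positive")
  a <- numeric(length(grid))
  for (i in seq_len(nrow(peaks)))
    a <- a + peaks$amplitude[i] *
      exp(-(grid - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  Spectrum(grid, a, label = label)
}

#' @rdname generateComponentSpectrum
#' @param center,width,amplitude peak parameters, recycled to equal length.
#' @export
peakModel <- function(center, width, amplitude) {
  data.frame(center = center, width = width, amplitude = amplitude)
}

#' Generate a seeded synthetic component library
#'
#' Emulates a set of aqueous-solution component spectra: each component gets
#' 2 to 5 Gaussian peaks with amplitudes log-uniform in about 0.001-0.1 AU
#' (so major and minor bands differ by orders of magnitude, as in real
#' libraries). The `overlap` setting controls pairwise spectral correlation:
#' \describe{
#'   \item{low}{each component's peaks live in its own wavenumber band, so
#'     all pairwise Pearson correlations stay below 0.3 (near-orthogonal
#'     spectra, the favourable case);}
#'   \item{medium}{peak centers are drawn anywhere on the grid;}
#'   \item{high}{consecutive components are built as slightly shifted,
#'     re-scaled copies of each other, so some pairs correlate above 0.9
#'     (emulating chemically similar media components).}
#' }
#'
#' @param nComponents number of components N (>= 1).
#' @param grid wavenumber grid (default [defaultGrid()]).
#' @param seed integer seed; the library is bit-reproducible per seed.
#' @param overlap "low", "medium" or "high".
#' @param refConcs reference concentrations per component (default 1:
#'   unit-concentration references). With several, the spectrum at reference
#'   concentration R has amplitude proportional to R^`nonlinearity`, a mild
#'   departure from strict proportionality that emulates real deviations
#'   from Beer's law and exercises [matchedReferenceRefit()].
#' @param nonlinearity exponent of the amplitude-concentration relation
#'   (default 0.97; 1 restores exact Beer's-law references).
#' @return a [ComponentLibrary-class] with components named
#'   "component01", ...
#' @export
generateLibrary <- function(nComponents, grid = defaultGrid(), seed = 1,
                            overlap = c("low", "medium", "high"),
                            refConcs = 1, nonlinearity = 0.97) {
  overlap <- match.arg(overlap)
  stopifnot(nComponents >= 1)
  span <- range(grid)
  if (overlap == "low") {
    bandWidth <- diff(span) / nComponents
    if (bandWidth < 80)
      .inputError("grid span too small to give ", nComponents,
                  " components non-overlapping bands; widen the grid or ",
                  "lower nComponents")
  }
  .withSeed(seed, {
    names <- sprintf("component%02d", seq_len(nComponents))
    peaks <- vector("list", nComponents)
    for (n in seq_len(nComponents)) {
      npk <- sample(2:5, 1)
      if (overlap == "low") {
        b0 <- span[1] + (n - 1) * bandWidth
        width <- stats::runif(npk, 8, min(30, bandWidth / 8))
        center <- stats::runif(npk, b0 + 4 * max(width),
                               b0 + bandWidth - 4 * max(width))
      } else if (overlap == "high" && n > 1 && n %% 2 == 0) {
        prev <- peaks[[n - 1]]
        npk <- nrow(prev)
        center <- prev$center + stats::runif(npk, 3, 6)
        width <- prev$width
      } else {
        width <- stats::runif(npk, 8, 40)
        center <- stats::runif(npk, span[1] + 4 * max(width),
                               span[2] - 4 * max(width))
      }
      amplitude <- 10^stats::runif(npk, log10(0.001), log10(0.1))
      if (overlap == "high" && n > 1 && n %% 2 == 0)
        amplitude <- peaks[[n - 1]]$amplitude * stats::runif(npk, 0.85, 1.15)
      peaks[[n]] <- peakModel(center, width, amplitude)
    }
    recs <- lapply(seq_len(nComponents), function(n) {
      unit <- generateComponentSpectrum(peaks[[n]], grid, label = names[n])
      specs <- lapply(refConcs, function(rc)
        Spectrum(grid, unit@absorbances * rc^nonlinearity, label = names[n]))
      ComponentRecord(names[n], specs, refConcs)
    })
    lib <- ComponentLibrary(recs)
    if (overlap == "low" && nComponents > 1) {
      A <- libraryMatrix(lib, grid)
      rho <- stats::cor(t(A))
      worst <- max(abs(rho[upper.tri(rho)]))
      if (worst >= 0.3)
        .fitError("low-overlap library infeasible on this grid (max |rho| = ",
                  round(worst, 3), "); enlarge the grid")
    }
    lib
  })
}

#' Synthesize a (possibly noisy) mixture spectrum
#'
#' Builds the Beer's-law sum of the library at the given concentrations and
#' adds, at each grid point, a draw from Normal(0, sd) with sd given by the
#' [NoiseSpec-class]: `magnitude * |A_m|` for relative noise (the default
#' reading of "x % noise"), or `magnitude` AU for absolute noise. Seeded and
#' bit-reproducible.
#'
#' @param library a [ComponentLibrary-class] (spectra on one grid).
#' @param concentrations numeric, percent, one per component.
#' @param noise a [NoiseSpec-class]; magnitude 0 gives the exact model sum.
#' @param select reference selection, see [libraryMatrix()].
#' @return a [Spectrum-class].
#' @export
synthesizeMixture <- function(library, concentrations,
                              noise = NoiseSpec(0), select = NULL) {
  stopifnot(is(noise, "NoiseSpec"))
  clean <- beerLawMixture(concentrations, library, select = select)
  if (noise@magnitude == 0) return(clean)
  sd <- if (noise@kind == "relative") noise@magnitude * abs(clean@absorbances)
        else rep(noise@magnitude, length(clean))
  eps <- .withSeed(noise@seed, stats::rnorm(length(clean), 0, sd))
  Spectrum(clean@wavenumbers, clean@absorbances + eps,
           label = "synthetic mixture")
}

#' Synthesize a time series of mixture spectra
#'
#' One noisy mixture per time point, with concentrations given by
#' per-component trajectory functions. Noise draws are independent between
#' time points but fully determined by the NoiseSpec seed.
#'
#' @param library a [ComponentLibrary-class].
#' @param trajectories list of functions of time (hours), one per component,
#'   each returning a concentration in percent; or a single function of time
#'   returning the full concentration vector.
#' @param times numeric vector of times (hours); may be empty.
#' @param noise a [NoiseSpec-class].
#' @return list with one element per time point, each a list with elements
#'   `time`, `spectrum` and `concentrations` (the generating truth).
#' @export
generateTimeSeries <- function(library, trajectories, times,
                               noise = NoiseSpec(0)) {
  N <- length(library)
  concAt <- if (is.function(trajectories)) {
    function(t) {
      v <- trajectories(t)
      if (length(v) != N) .inputError("trajectory function must return ",
                                      N, " concentrations")
      v
    }
  } else {
    if (length(trajectories) != N)
      .inputError("need one trajectory per component")
    function(t) vapply(trajectories, function(f) f(t), numeric(1))
  }
  lapply(seq_along(times), function(i) {
    conc <- concAt(times[i])
    ns <- noise
    if (!is.na(ns@seed)) ns@seed <- ns@seed + i
    list(time = times[i],
         spectrum = synthesizeMixture(library, conc, ns),
         concentrations = conc)
  })
}
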