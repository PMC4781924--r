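#' @include unmix-core.R
NULL

#' Track component concentrations over a time series of spectra
#'
#' Runs an independent [mplmFit()] for every time point. A failure at one
#' time point is recorded and does not abort the rest of the series (the
#' corresponding concentration row is NA).
#'
#' @param series list of per-time-point entries, each a list with elements
#'   `time` (hours) and `spectrum` ([Spectrum-class]), as produced by
#'   [generateTimeSeries()].
#' @param library a [ComponentLibrary-class].
#' @param config an [MPLMConfig-class].
#' @param select reference selection, see [libraryMatrix()].
#' @return a [TimeSeriesFit-class].
#' @seealso [normalizeRelative()]
#' @export
trackTimeSeries <- function(series, library, config = MPLMConfig(),
                            select = NULL) {
  if (!length(series)) .inputError("empty time series")
  N <- length(library)
  times <- vapply(series, function(p) p$time, numeric(1))
  conc <- matrix(NA_real_, length(series), N,
                 dimnames = list(NULL, componentNames(library)))
  errs <- vector("list", length(series))
  for (i in seq_along(series)) {
    fit <- tryCatch(mplmFit(series[[i]]$spectrum, library, config,
                            select = select),
                    error = function(e) e)
    if (inherits(fit, "error")) errs[[i]] <- conditionMessage(fit)
    else conc[i, ] <- concentrations(fit)
  }
  new("TimeSeriesFit", times = times, concentrations = conc, errors = errs)
}

#' Convert fitted trajectories to relative concentrations
#'
#' Dividing out a common scale removes bulk effects such as evaporation,
#' which raises every concentration without changing composition.
#' `sum_of_tracked` divides each time point's vector by the sum of the
#' tracked components at that time (rows then sum to 1 and a uniform
#' concentration rescaling cancels exactly); `reference_time` divides each
#' component by its value at the first time point.
#'
#' @param fit a [TimeSeriesFit-class].
#' @param mode "sum_of_tracked" or "reference_time".
#' @return the fit with its `normalized` matrix filled in.
#' @export
normalizeRelative <- function(fit,
                              mode = c("sum_of_tracked", "reference_time")) {
  stopifnot(is(fit, "TimeSeriesFit"))
  mode <- match.arg(mode)
  conc <- fit@concentrations
  if (!nrow(conc)) .inputError("empty time-series fit")
  if (mode == "sum_of_tracked") {
    tot <- rowSums(conc)
    bad <- which(!is.na(tot) & tot == 0)
    if (length(bad))
      .fitError("tracked components sum to zero at time ",
                fit@times[bad[1]], " h; cannot normalize")
    norm <- conc / tot
  } else {
    ref <- conc[1L, ]
    bad <- which(!is.na(ref) & ref == 0)
    if (length(bad))
      .fitError("component '", colnames(conc)[bad[1]],
                "' is zero at the reference time ", fit@times[1L],
                " h; cannot normalize")
    norm <- sweep(conc, 2L, ref, "/")
  }
  fit@normalized <- norm
  fit@normalization <- mode
  fit
}

#' Protonation-state fractions by two-endpoint unmixing
#'
#' A titration sample at intermediate pH is a linear combination of the two
#' endpoint spectra (fully protonated acid and fully deprotonated base);
#' fitting the sample as a two-component mixture yields the two fractions.
#' No sum-to-one constraint is imposed: with real spectra the total can
#' drift slightly from 1 (density changes along the titration), and that
#' drift is itself a useful diagnostic - see [fractionNormalize()].
#'
#' @param sample measured [Spectrum-class] at intermediate pH.
#' @param protonatedEnd,deprotonatedEnd endpoint [Spectrum-class] objects.
#' @param config an [MPLMConfig-class]; the default refines fractions on
#'   [0, 1.5] down to steps of 0.001.
#' @return list with `fractionProtonated`, `fractionDeprotonated` and the
#'   underlying `fit` ([FitResult-class]).
#' @export
protonationFractionFit <- function(sample, protonatedEnd, deprotonatedEnd,
                                   config = MPLMConfig(firstStep = 0.25,
                                                       upperBound = 1.5,
                                                       freezeStep = 5e-4)) {
  stopifnot(is(sample, "Spectrum"))
  lib <- ComponentLibrary(list(
    ComponentRecord("protonated", protonatedEnd),
    ComponentRecord("deprotonated", deprotonatedEnd)))
  grid <- commonGrid(sample, lib)
  A <- libraryMatrix(lib, grid)
  rho <- suppressWarnings(stats::cor(A[1L, ], A[2L, ]))
  if (!is.finite(rho) || rho > 1 - 1e-8)
    .fitError("endpoint spectra are (near-)identical; the two-state fit is ",
              "ill-conditioned")
  fit <- mplmFit(sample, lib, config)
  cc <- concentrations(fit)
  list(fractionProtonated = unname(cc[1L]),
       fractionDeprotonated = unname(cc[2L]),
       fit = fit)
}

#' Normalize protonation fractions to their total
#'
#' @param fractionProtonated,fractionDeprotonated raw fitted fractions.
#' @return list with `fractionProtonated`, `fractionDeprotonated` (each
#'   divided by their sum) and `total` (the raw sum, a diagnostic: values
#'   far from 1 indicate density drift or a poor fit).
#' @export
fractionNormalize <- function(fractionProtonated, fractionDeprotonated) {
  total <- fractionProtonated + fractionDeprotonated
  if (!is.finite(total) || total <= 0)
    .inputError("fraction total must be positive, got ", total)
  list(fractionProtonated = fractionProtonated / total,
       fractionDeprotonated = fractionDeprotonated / total,
       total = total)
}

#' pH from protonation fractions (Henderson-Hasselbalch)
#'
#' pH = pKa + log10(deprotonated / protonated).
#'
#' @param fractionProtonated,fractionDeprotonated fractions, both > 0.
#' @param pKa acid dissociation constant (e.g. 4.76 for acetic acid).
#' @return pH (dimensionless).
#' @seealso [fractionsFromPh()], [phFromCalibration()]
#' @export
phFromFractions <- function(fractionProtonated, fractionDeprotonated, pKa) {
  if (any(fractionProtonated <= 0) || any(fractionDeprotonated <= 0))
    .inputError("both fractions must be positive; at titration endpoints ",
                "use the endpoint pH directly")
  pKa + log10(fractionDeprotonated / fractionProtonated)
}

#' Protonation fractions from pH (inverse Henderson-Hasselbalch)
#'
#' @param pH solution pH.
#' @param pKa acid dissociation constant.
#' @return list with `fractionProtonated` and `fractionDeprotonated`,
#'   summing to 1.
#' @export
fractionsFromPh <- function(pH, pKa) {
  ratio <- 10^(pH - pKa)
  list(fractionProtonated = 1 / (1 + ratio),
       fractionDeprotonated = ratio / (1 + ratio))
}

#' pH from a measured calibration curve
#'
#' Interpolates a monotone calibration of protonated fraction versus pH
#' (shape-preserving monotone cubic interpolation), for systems where the
#' ideal Henderson-Hasselbalch relation is distorted by activity effects.
#' Extrapolation beyond the calibrated fraction range is refused.
#'
#' @param fraction protonated fraction(s) of the sample(s).
#' @param calibrationFractions,calibrationPh measured calibration pairs;
#'   fractions must be strictly monotone in pH.
#' @return interpolated pH value(s).
#' @export
phFromCalibration <- function(fraction, calibrationFractions, calibrationPh) {
  if (length(calibrationFractions) != length(calibrationPh) ||
      length(calibrationPh) < 3L)
    .inputError("need >= 3 calibration pairs of equal length")
  o <- order(calibrationFractions)
  f <- calibrationFractions[o]
  p <- calibrationPh[o]
  if (any(diff(f) <= 0) || !(all(diff(p) > 0) || all(diff(p) < 0)))
    .inputError("calibration fractions must be strictly monotone in pH")
  out <- fraction[fraction < min(f) - 1e-12 | fraction > max(f) + 1e-12]
  if (length(out))
    .inputError("fraction ", out[1], " lies outside the calibrated range [",
                min(f), ", ", max(f), "]; extrapolation is refused")
  stats::splinefun(f, p, method = "monoH.FC")(fraction)
}

#' Two-chamber membrane permeability from equilibration curves
#'
#' Two equal, well-mixed chambers at initial normalised concentrations 1
#' (source) and 0 (sink), separated by a membrane, equilibrate symmetrically
#' toward 1/2 under Fick's first law:
#' sink(t) = (1 - exp(-k t)) / 2, source(t) = (1 + exp(-k t)) / 2,
#' with k = P (A/V1 + A/V2). The rate constant k is fitted by least squares
#' on both series jointly; the geometry factor converts it to a
#' permeability P in cm/s.
#'
#' @param times sampling times (s), strictly increasing, >= 3 points.
#' @param sourceConc,sinkConc normalised concentrations (source starts at 1,
#'   sink at 0).
#' @param areaOverVolumes A/V1 + A/V2 in 1/cm (membrane area over chamber
#'   volumes; must be measured for the cell in use).
#' @return a [DiffusionFit-class]. If k is unidentifiable (series already at
#'   equilibrium, or equilibration faster than the sampling) a warning is
#'   issued and the boundary value is reported.
#' @export
permeabilityFit <- function(times, sourceConc, sinkConc, areaOverVolumes) {
  if (length(times) < 3L)
    .inputError("need at least 3 time points")
  if (length(sourceConc) != length(times) ||
      length(sinkConc) != length(times))
    .inputError("times, sourceConc and sinkConc must have equal length")
  if (any(diff(times) <= 0))
    .inputError("times must be strictly increasing")
  if (areaOverVolumes <= 0)
    .inputError("areaOverVolumes must be positive")
  obj <- function(k) {
    e <- exp(-k * times)
    sum((sinkConc - 0.5 * (1 - e))^2 + (sourceConc - 0.5 * (1 + e))^2)
  }
  tpos <- times[times > 0]
  kUp <- 50 / min(tpos)
  opt <- stats::optimize(obj, c(0, kUp), tol = 1e-12 * kUp)
  k <- opt$minimum
  if (k <= 1e-9 * kUp) {
    warning("fitted rate constant is not positive (k = ", signif(k, 3),
            " 1/s); no net equilibration in the data", call. = FALSE)
  } else if (k >= 0.99 * kUp) {
    warning("rate constant unidentifiable: series are at equilibrium on ",
            "the sampling timescale (k >= ", signif(kUp, 3), " 1/s)",
            call. = FALSE)
  }
  e <- exp(-k * times)
  fitted <- cbind(source = 0.5 * (1 + e), sink = 0.5 * (1 - e))
  new("DiffusionFit", permeability = k / areaOverVolumes, rateConstant = k,
      areaOverVolumes = areaOverVolumes, times = as.numeric(times),
      fitted = fitted,
      residuals = cbind(source = sourceConc - fitted[, "source"],
                        sink = sinkConc - fitted[, "sink"]))
}
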