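#' @include AllGenerics.R
NULL

#' @describeIn Spectrum wavenumber grid (cm^-1, ascending).
#' @param x,object a \code{Spectrum}.
#' @aliases wavenumbers
#' @export
setMethod("wavenumbers", "Spectrum", function(x) x@wavenumbers)

#' @describeIn Spectrum absorbance values (AU).
#' @aliases absorbances
#' @export
setMethod("absorbances", "Spectrum", function(x) x@absorbances)

#' @describeIn Spectrum free-text label.
#' @aliases specLabel
#' @export
setMethod("specLabel", "Spectrum", function(x) x@label)

#' @describeIn Spectrum number of grid points M.
#' @export
setMethod("length", "Spectrum", function(x) length(x@wavenumbers))

setMethod("show", "Spectrum", function(object) {
  w <- object@wavenumbers
  cat(sprintf("Spectrum%s: %d points, %.1f..%.1f cm-1, absorbance %.4g..%.4g AU\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              length(w), min(w), max(w),
              min(object@absorbances), max(object@absorbances)))
})

#' @describeIn ComponentRecord component name.
#' @param x,object a \code{ComponentRecord}.
#' @export
setMethod("componentNames", "ComponentRecord", function(x) x@name)

#' @describeIn ComponentRecord reference concentrations (percent, ascending).
#' @aliases referenceConcentrations
#' @export
setMethod("referenceConcentrations", "ComponentRecord", function(x) x@refConcs)

#' @describeIn ComponentRecord reference spectra, as a list parallel to
#'   \code{referenceConcentrations}.
#' @export
referenceSpectra <- function(x) {
  stopifnot(is(x, "ComponentRecord"))
  x@spectra
}

setMethod("show", "ComponentRecord", function(object) {
  cat(sprintf("ComponentRecord '%s': %d reference spectrum(s) at %s %%\n",
              object@name, length(object@refConcs),
              paste(object@refConcs, collapse = ", ")))
})

#' @describeIn ComponentLibrary component names, in order.
#' @param x,object a \code{ComponentLibrary}.
#' @aliases componentNames
#' @export
setMethod("componentNames", "ComponentLibrary",
          function(x) vapply(x@components, function(r) r@name, character(1)))

#' @describeIn ComponentLibrary number of components N.
#' @export
setMethod("length", "ComponentLibrary", function(x) length(x@components))

#' @describeIn ComponentLibrary extract one ComponentRecord by index or name.
#' @param i index or component name.
#' @param j,... unused.
#' @export
setMethod("[[", "ComponentLibrary", function(x, i, j, ...) {
  if (is.character(i)) {
    k <- match(i, componentNames(x))
    if (is.na(k)) stop("no component named '", i, "'", call. = FALSE)
    i <- k
  }
  x@components[[i]]
})

setMethod("show", "ComponentLibrary", function(object) {
  cat(sprintf("ComponentLibrary: %d component(s)\n", length(object)))
  for (r in object@components)
    cat(sprintf("  %-16s %d ref at %s %%\n", r@name, length(r@refConcs),
                paste(r@refConcs, collapse = ", ")))
})

setMethod("show", "MPLMConfig", function(object) {
  cat(sprintf(paste0("MPLMConfig: s1=%g%%, B=%g, r=%g, maxPasses=%d, ",
                     "freeze<%g%%, bounds [%g, %g]%%\n"),
              object@firstStep[1], object@backoff, object@reduction,
              object@maxPasses, object@freezeStep,
              object@lowerBound[1], object@upperBound[1]))
})

#' @describeIn FitResult fitted concentration vector (percent).
#' @param x,object a \code{FitResult}.
#' @aliases concentrations
#' @export
setMethod("concentrations", "FitResult", function(x) x@concentrations)

#' @describeIn FitResult final RMS residual (AU).
#' @export
setMethod("rmsError", "FitResult", function(x, ...) x@rmsError)

#' @describeIn FitResult per-pass records: mesh bounds, step, frozen flags,
#'   best point, best RMS residual and mesh cardinality.
#' @aliases passHistory
#' @export
setMethod("passHistory", "FitResult", function(x) x@passes)

#' @describeIn FitResult logical per component: refined below the freeze
#'   threshold.
#' @aliases convergedComponents
#' @export
setMethod("convergedComponents", "FitResult", function(x) x@convergedComponents)

#' @describeIn FitResult whether a matched-reference re-fit was triggered
#'   (NA for plain fits).
#' @aliases refitOccurred
#' @export
setMethod("refitOccurred", "FitResult", function(x) x@refitOccurred)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d pass(es), rmsError = %.6g AU\n",
              length(object@passes), object@rmsError))
  print(round(object@concentrations, 4))
})

#' @describeIn FitStatistics RMS residual (AU).
#' @param x,object a \code{FitStatistics}.
#' @export
setMethod("rmsError", "FitStatistics", function(x, ...) x@rmsError)

#' @describeIn FitStatistics OLS slope of measured on computed.
#' @aliases slope
#' @export
setMethod("slope", "FitStatistics", function(x) x@slope)

#' @describeIn FitStatistics OLS intercept (AU).
#' @aliases intercept
#' @export
setMethod("intercept", "FitStatistics", function(x) x@intercept)

#' @describeIn FitStatistics squared correlation.
#' @aliases rSquared
#' @export
setMethod("rSquared", "FitStatistics", function(x) x@rSquared)

setMethod("show", "FitStatistics", function(object) {
  cat(sprintf(paste0("FitStatistics: rmsError=%.4g AU, slope=%.6f, ",
                     "intercept=%.3g AU, R2=%.6f\n"),
              object@rmsError, object@slope, object@intercept,
              object@rSquared))
})

#' @describeIn TimeSeriesFit time points (hours).
#' @param x,object a \code{TimeSeriesFit}.
#' @export
times <- function(x) {
  stopifnot(is(x, "TimeSeriesFit") || is(x, "DiffusionFit"))
  x@times
}

#' @describeIn TimeSeriesFit fitted concentration matrix
#'   (time x component, percent).
#' @export
setMethod("concentrations", "TimeSeriesFit", function(x) x@concentrations)

#' @describeIn TimeSeriesFit normalized relative-concentration matrix
#'   (empty until [normalizeRelative()] is applied).
#' @export
normalizedConcentrations <- function(x) {
  stopifnot(is(x, "TimeSeriesFit"))
  x@normalized
}

setMethod("show", "TimeSeriesFit", function(object) {
  cat(sprintf("TimeSeriesFit: %d time point(s), %d component(s)%s\n",
              length(object@times), ncol(object@concentrations),
              if (nzchar(object@normalization))
                paste0(", normalized (", object@normalization, ")") else ""))
})

#' @describeIn DiffusionFit membrane permeability P (cm/s).
#' @param x,object a \code{DiffusionFit}.
#' @aliases permeability
#' @export
setMethod("permeability", "DiffusionFit", function(x) x@permeability)

#' @describeIn DiffusionFit equilibration rate constant k (1/s).
#' @aliases rateConstant
#' @export
setMethod("rateConstant", "DiffusionFit", function(x) x@rateConstant)

#' @describeIn DiffusionFit residual matrix (columns source, sink).
#' @export
setMethod("residuals", "DiffusionFit", function(object) object@residuals)

#' @describeIn DiffusionFit fitted model values (columns source, sink).
#' @export
setMethod("fitted", "DiffusionFit", function(object) object@fitted)

setMethod("show", "DiffusionFit", function(object) {
  cat(sprintf("DiffusionFit: P = %.4g cm/s (k = %.4g 1/s, A/V = %g 1/cm)\n",
              object@permeability, object@rateConstant,
              object@areaOverVolumes))
})
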