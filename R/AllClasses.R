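#' @import methods
NULL

#' Spectrum: a single absorbance spectrum
#'
#' A \code{Spectrum} holds one absorbance spectrum on a strictly increasing
#' wavenumber grid. Absorbances may be negative: spectra backgrounded against
#' water (rather than air) routinely dip below zero and are never clipped.
#'
#' @slot wavenumbers numeric, strictly increasing, in reciprocal centimetres.
#' @slot absorbances numeric, absorbance units (AU), same length.
#' @slot label free-text label (may be empty).
#'
#' @seealso [Spectrum()], [readSpectrumCSV()], [resampleToGrid()]
#' @exportClass Spectrum
setClass("Spectrum",
  representation(wavenumbers = "numeric", absorbances = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("Spectrum", function(object) {
  w <- object@wavenumbers
  a <- object@absorbances
  if (length(w) != length(a))
    return("wavenumbers and absorbances must have equal length")
  if (length(w) < 2L)
    return("a spectrum needs at least 2 points")
  if (anyNA(w) || anyNA(a) || any(!is.finite(w)))
    return("wavenumbers and absorbances must be finite and non-missing")
  if (any(diff(w) <= 0))
    return("wavenumbers must be strictly increasing (duplicates are an error)")
  if (length(object@label) != 1L)
    return("label must be a single character string")
  TRUE
})

#' Construct a Spectrum
#'
#' Points are stored in ascending wavenumber order; descending input is sorted
#' silently (instrument export order varies and the fit is order-invariant).
#' Duplicated wavenumbers are rejected rather than averaged so that upstream
#' export bugs surface immediately.
#'
#' @param wavenumbers numeric vector, cm^-1.
#' @param absorbances numeric vector, AU; may be negative.
#' @param label optional free-text label.
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum(c(1000, 1001, 1002), c(0.01, 0.02, 0.015))
#' wavenumbers(s)
#' @export
Spectrum <- function(wavenumbers, absorbances, label = "") {
  wavenumbers <- as.numeric(wavenumbers)
  absorbances <- as.numeric(absorbances)
  if (length(wavenumbers) != length(absorbances))
    stop("wavenumbers and absorbances must have equal length", call. = FALSE)
  if (anyDuplicated(wavenumbers))
    stop("duplicate wavenumbers: ",
         paste(unique(wavenumbers[duplicated(wavenumbers)])[1:3], collapse = ", "),
         call. = FALSE)
  o <- order(wavenumbers)
  new("Spectrum", wavenumbers = wavenumbers[o], absorbances = absorbances[o],
      label = as.character(label))
}

#' ComponentRecord: reference spectra for one mixture component
#'
#' One component of a mixture, with one or more reference spectra measured at
#' known reference concentrations. Multiple references let the fit absorb mild
#' deviations from Beer's law (water-solute interaction, detector saturation)
#' by picking the reference measured nearest the expected concentration; see
#' [matchedReferenceRefit()].
#'
#' @slot name component identifier.
#' @slot refConcs reference concentrations (percent), positive and distinct.
#' @slot spectra list of [Spectrum-class], one per reference concentration,
#'   each measured \emph{at} that concentration.
#' @exportClass ComponentRecord
setClass("ComponentRecord",
  representation(name = "character", refConcs = "numeric", spectra = "list"))

setValidity("ComponentRecord", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  if (length(object@refConcs) == 0L)
    return("at least one reference spectrum is required")
  if (any(object@refConcs <= 0))
    return("reference concentrations must be positive")
  if (anyDuplicated(object@refConcs))
    return("reference concentrations must be distinct")
  if (length(object@spectra) != length(object@refConcs))
    return("one spectrum per reference concentration is required")
  if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
    return("spectra must all be Spectrum objects")
  TRUE
})

#' @rdname ComponentRecord-class
#' @param name component identifier.
#' @param spectra a [Spectrum-class] or list of them.
#' @param refConcs reference concentrations (percent), parallel to `spectra`.
#' @export
ComponentRecord <- function(name, spectra, refConcs = 1) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  o <- order(refConcs)
  new("ComponentRecord", name = as.character(name),
      refConcs = as.numeric(refConcs)[o], spectra = spectra[o])
}

#' ComponentLibrary: an ordered set of component records
#'
#' The library supplies the reference absorbance matrix of the Beer's-law
#' model. Component order is meaningful: concentration vectors, mesh bounds
#' and tie-breaking all follow it.
#'
#' @slot components list of [ComponentRecord-class] with unique names.
#' @exportClass ComponentLibrary
setClass("ComponentLibrary", representation(components = "list"))

setValidity("ComponentLibrary", function(object) {
  if (length(object@components) < 1L)
    return("a library needs at least one component")
  if (!all(vapply(object@components, is, logical(1), "ComponentRecord")))
    return("components must all be ComponentRecord objects")
  nm <- vapply(object@components, function(x) x@name, character(1))
  if (anyDuplicated(nm))
    return("component names must be unique")
  TRUE
})

#' @rdname ComponentLibrary-class
#' @param components list of [ComponentRecord-class] objects.
#' @export
ComponentLibrary <- function(components) {
  new("ComponentLibrary", components = components)
}

#' MeshSpec: a rectangular concentration mesh
#'
#' Per-component lower bound, upper bound and step (all percent). The mesh
#' points for a component are lower, lower+step, ... capped at upper. Scalars
#' are recycled across components.
#'
#' @slot lower,upper,step numeric vectors, percent.
#' @exportClass MeshSpec
setClass("MeshSpec",
  representation(lower = "numeric", upper = "numeric", step = "numeric"))

setValidity("MeshSpec", function(object) {
  n <- max(length(object@lower), length(object@upper), length(object@step))
  lo <- rep_len(object@lower, n); up <- rep_len(object@upper, n)
  st <- rep_len(object@step, n)
  if (any(lo > up)) return("lower must not exceed upper")
  if (any(st <= 0)) return("step must be positive")
  if (any(lo < 0)) return("concentrations are non-negative; lower must be >= 0")
  TRUE
})

#' @rdname MeshSpec-class
#' @param lower,upper,step numeric (recycled), percent.
#' @export
MeshSpec <- function(lower, upper, step) {
  new("MeshSpec", lower = as.numeric(lower), upper = as.numeric(upper),
      step = as.numeric(step))
}

setClassUnion("MeshSpecOrNULL", c("MeshSpec", "NULL"))

#' MPLMConfig: multi-pass local mesh refinement settings
#'
#' Controls the refinement schedule. Pass 1 evaluates a coarse mesh at step
#' `firstStep` over the global bounds (or `firstPassBounds` if given). Each
#' later pass re-centres per-component bounds on the previous best point,
#' backing off by `backoff` previous steps in each direction, and divides the
#' step by `reduction / backoff` so that s[i+1] = s[i] * backoff / reduction.
#' A component whose next step would fall below `freezeStep` is frozen at its
#' best value and no longer looped over.
#'
#' @slot firstStep first-pass mesh step s1, percent (default 10).
#' @slot backoff back-off B in units of the previous step, 0 < B <= 1
#'   (default 0.8).
#' @slot reduction step reduction r, must exceed B so steps shrink
#'   (default 4, so steps shrink fivefold per pass).
#' @slot maxPasses maximum number of passes, at most 9 (default 9).
#' @slot freezeStep freeze threshold, percent (default 0.01).
#' @slot lowerBound,upperBound global concentration bounds, percent
#'   (defaults 0 and 50).
#' @slot firstPassBounds optional [MeshSpec-class] overriding bounds and step
#'   for pass 1 only.
#' @slot chunkSize number of mesh points evaluated per block (memory/speed
#'   trade-off; the result is independent of it).
#' @exportClass MPLMConfig
setClass("MPLMConfig",
  representation(firstStep = "numeric", backoff = "numeric",
                 reduction = "numeric", maxPasses = "integer",
                 freezeStep = "numeric", lowerBound = "numeric",
                 upperBound = "numeric", firstPassBounds = "MeshSpecOrNULL",
                 chunkSize = "numeric"),
  prototype(firstStep = 10, backoff = 0.8, reduction = 4, maxPasses = 9L,
            freezeStep = 0.01, lowerBound = 0, upperBound = 50,
            firstPassBounds = NULL, chunkSize = 2^20))

setValidity("MPLMConfig", function(object) {
  if (any(object@firstStep <= 0)) return("firstStep must be positive")
  if (object@backoff <= 0 || object@backoff > 1)
    return("backoff must satisfy 0 < B <= 1")
  if (object@reduction <= object@backoff)
    return("reduction must exceed backoff (steps must shrink)")
  if (object@maxPasses < 1L || object@maxPasses > 9L)
    return("maxPasses must be between 1 and 9")
  if (object@freezeStep <= 0) return("freezeStep must be positive")
  if (any(object@lowerBound < 0)) return("lowerBound must be >= 0")
  if (any(rep_len(object@upperBound, max(length(object@upperBound),
          length(object@lowerBound))) <=
          rep_len(object@lowerBound, max(length(object@upperBound),
          length(object@lowerBound)))))
    return("upperBound must exceed lowerBound")
  if (object@chunkSize < 1) return("chunkSize must be >= 1")
  TRUE
})

#' @rdname MPLMConfig-class
#' @param firstStep,backoff,reduction,maxPasses,freezeStep,lowerBound,upperBound,firstPassBounds,chunkSize
#'   see the class slots.
#' @export
MPLMConfig <- function(firstStep = 10, backoff = 0.8, reduction = 4,
                       maxPasses = 9, freezeStep = 0.01, lowerBound = 0,
                       upperBound = 50, firstPassBounds = NULL,
                       chunkSize = 2^20) {
  new("MPLMConfig", firstStep = as.numeric(firstStep),
      backoff = as.numeric(backoff), reduction = as.numeric(reduction),
      maxPasses = as.integer(maxPasses), freezeStep = as.numeric(freezeStep),
      lowerBound = as.numeric(lowerBound), upperBound = as.numeric(upperBound),
      firstPassBounds = firstPassBounds, chunkSize = as.numeric(chunkSize))
}

#' FitResult: the outcome of an SMM or MPLM concentration fit
#'
#' @slot concentrations named numeric, fitted concentrations (percent), in
#'   library component order.
#' @slot rmsError final root-mean-square residual, AU.
#' @slot passes list of per-pass records, each a list with elements
#'   `pass`, `lower`, `upper`, `step`, `frozen`, `best`, `rmsError`,
#'   `nEvaluations` (mesh cardinality of the pass).
#' @slot convergedComponents logical per component: step shrank below the
#'   freeze threshold.
#' @slot refitOccurred logical: did [matchedReferenceRefit()] trigger a second
#'   fit with re-selected references? `NA` for plain fits.
#' @exportClass FitResult
setClass("FitResult",
  representation(concentrations = "numeric", rmsError = "numeric",
                 passes = "list", convergedComponents = "logical",
                 refitOccurred = "logical"),
  prototype(refitOccurred = NA))

setValidity("FitResult", function(object) {
  if (length(object@rmsError) != 1L || object@rmsError < 0)
    return("rmsError must be a single non-negative number")
  if (any(object@concentrations < 0))
    return("concentrations must be non-negative")
  eps <- vapply(object@passes, function(p) p$rmsError, numeric(1))
  if (length(eps) > 1L && any(diff(eps) > 1e-12 * pmax(eps[-length(eps)], 1e-300)))
    return("per-pass best rmsError must be non-increasing")
  TRUE
})

#' FitStatistics: goodness-of-fit diagnostics
#'
#' Summarises how well a computed (modelled) spectrum reproduces a measured
#' one: the RMS residual, and the slope, intercept and R-squared of the
#' ordinary least-squares line of measured on computed absorbance. A perfect
#' fit has rmsError 0, slope 1, intercept 0, R-squared 1.
#'
#' @slot rmsError RMS residual, AU.
#' @slot slope,intercept OLS line measured = slope * computed + intercept.
#' @slot rSquared squared correlation of measured and computed.
#' @exportClass FitStatistics
setClass("FitStatistics",
  representation(rmsError = "numeric", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric"))

#' TimeSeriesFit: concentrations fitted over a time course
#'
#' @slot times numeric, hours.
#' @slot concentrations matrix, one row per time point, one column per
#'   library component (percent).
#' @slot normalized matrix of relative concentrations (same shape) or a
#'   0-row matrix before [normalizeRelative()] is applied.
#' @slot normalization character: "", "sum_of_tracked" or "reference_time".
#' @slot errors list of per-time-point error messages (NULL where the fit
#'   succeeded).
#' @exportClass TimeSeriesFit
setClass("TimeSeriesFit",
  representation(times = "numeric", concentrations = "matrix",
                 normalized = "matrix", normalization = "character",
                 errors = "list"),
  prototype(normalized = matrix(numeric(0), 0, 0), normalization = ""))

setValidity("TimeSeriesFit", function(object) {
  if (nrow(object@concentrations) != length(object@times))
    return("one concentration vector per time point is required")
  TRUE
})

#' DiffusionFit: two-chamber membrane permeability estimate
#'
#' Result of fitting the symmetric two-chamber equilibration model
#' sink(t) = (1 - exp(-k t)) / 2, source(t) = (1 + exp(-k t)) / 2
#' to normalised concentration series; k = P * (A/V1 + A/V2).
#'
#' @slot permeability P, cm/s.
#' @slot rateConstant k, 1/s.
#' @slot areaOverVolumes user-supplied geometry factor A/V1 + A/V2, 1/cm.
#' @slot times sampling times, s.
#' @slot fitted matrix with columns `source`, `sink`: model values.
#' @slot residuals matrix with columns `source`, `sink`: data minus model.
#' @exportClass DiffusionFit
setClass("DiffusionFit",
  representation(permeability = "numeric", rateConstant = "numeric",
                 areaOverVolumes = "numeric", times = "numeric",
                 fitted = "matrix", residuals = "matrix"))

#' NoiseSpec: additive noise model for synthetic spectra
#'
#' Noise is drawn per grid point from Normal(0, sd). By default the standard
#' deviation is `magnitude` times the absolute clean absorbance at that point
#' (relative noise, e.g. magnitude 0.005 for 0.5 % noise); with
#' `kind = "absolute"` the standard deviation is `magnitude` AU everywhere.
#'
#' @slot magnitude non-negative noise magnitude (relative fraction or AU).
#' @slot kind "relative" or "absolute".
#' @slot seed integer RNG seed, or NA to use the current RNG stream.
#' @exportClass NoiseSpec
setClass("NoiseSpec",
  representation(magnitude = "numeric", kind = "character", seed = "numeric"),
  prototype(magnitude = 0, kind = "relative", seed = NA_real_))

setValidity("NoiseSpec", function(object) {
  if (object@magnitude < 0) return("noise magnitude must be >= 0")
  if (!object@kind %in% c("relative", "absolute"))
    return("kind must be 'relative' or 'absolute'")
  TRUE
})

#' @rdname NoiseSpec-class
#' @param magnitude,kind,seed see the class slots.
#' @export
NoiseSpec <- function(magnitude = 0, kind = c("relative", "absolute"),
                      seed = NA) {
  kind <- match.arg(kind)
  new("NoiseSpec", magnitude = as.numeric(magnitude), kind = kind,
      seed = as.numeric(seed))
}
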