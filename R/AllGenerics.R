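#' @include AllClasses.R
NULL

#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @export
setGeneric("absorbances", function(x) standardGeneric("absorbances"))

#' @export
setGeneric("specLabel", function(x) standardGeneric("specLabel"))

#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))

#' @export
setGeneric("referenceConcentrations",
           function(x) standardGeneric("referenceConcentrations"))

#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' Root-mean-square residual of a Beer's-law model
#'
#' With a numeric first argument, evaluates the objective
#' sqrt(mean((A_mix - sum_n C_n A_n)^2)) for a concentration vector against a
#' library and mixture. With a [FitResult-class] or [FitStatistics-class],
#' extracts the stored value.
#'
#' @param x a concentration vector, [FitResult-class] or
#'   [FitStatistics-class].
#' @param ... further arguments (`library`, `mixture`, `select`) for the
#'   numeric method.
#' @return RMS residual in absorbance units.
#' @export
setGeneric("rmsError", function(x, ...) standardGeneric("rmsError"))

#' @export
setGeneric("passHistory", function(x) standardGeneric("passHistory"))

#' @export
setGeneric("convergedComponents",
           function(x) standardGeneric("convergedComponents"))

#' @export
setGeneric("refitOccurred", function(x) standardGeneric("refitOccurred"))

#' @export
setGeneric("slope", function(x) standardGeneric("slope"))

#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @export
setGeneric("permeability", function(x) standardGeneric("permeability"))

#' @export
setGeneric("rateConstant", function(x) standardGeneric("rateConstant"))
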