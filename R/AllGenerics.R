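#' @rdname kernelValues
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))

#' @rdname kernelValues
#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))

#' @rdname kernelValues
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @rdname kernelValues
#' @export
setGeneric("meanDiag", function(x) standardGeneric("meanDiag"))

#' @rdname kernelValues
#' @export
setGeneric("meanAll", function(x) standardGeneric("meanAll"))

#' @rdname dosages
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname dosages
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname dosages
#' @export
setGeneric("qcLog", function(x) standardGeneric("qcLog"))

#' @rdname spectraValues
#' @export
setGeneric("spectraValues", function(x) standardGeneric("spectraValues"))

#' @rdname spectraValues
#' @export
setGeneric("featureAxis", function(x) standardGeneric("featureAxis"))

#' @rdname spectraValues
#' @export
setGeneric("preprocessingHistory",
           function(x) standardGeneric("preprocessingHistory"))

#' @rdname vcEstimates
#' @export
setGeneric("vcEstimates", function(x) standardGeneric("vcEstimates"))

#' @rdname vcEstimates
#' @export
setGeneric("vcStandardErrors", function(x) standardGeneric("vcStandardErrors"))

#' @rdname vcEstimates
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname vcEstimates
#' @export
setGeneric("boundaryTerms", function(x) standardGeneric("boundaryTerms"))

#' @rdname blupAccessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' @rdname blupAccessors
#' @export
setGeneric("randomEffects", function(x, term) standardGeneric("randomEffects"))

#' Extract (combined) genomic estimated breeding values
#'
#' For a GBLUP [BlupSolution-class] this is the solution of the additive
#' genomic term `g`; for a [GoblupFit-class] it is the combined vector
#' ghat1 + ghat2 from the two-step procedure.
#'
#' @param fit a fitted model object.
#' @param ... unused.
#' @return named numeric vector of per-line breeding values in canonical
#'   (kernel) line order.
#' @export
setGeneric("gebv", function(fit, ...) standardGeneric("gebv"))

#' @rdname cvAccessors
#' @export
setGeneric("predictiveAbility", function(x) standardGeneric("predictiveAbility"))

#' @rdname cvAccessors
#' @export
setGeneric("lrRatios", function(x) standardGeneric("lrRatios"))
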