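#' @include AllClasses.R
NULL

#' @rdname TumorCohort-class
#' @param object,x a `TumorCohort`.
#' @export
setGeneric("indexGene", function(object) standardGeneric("indexGene"))

#' @rdname TumorCohort-class
#' @export
setGeneric("indexValues", function(object) standardGeneric("indexValues"))

#' @rdname TumorCohort-class
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))

#' @rdname BinnedFrequency-class
#' @param object a `BinnedFrequency`.
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname BinnedFrequency-class
#' @export
setGeneric("leftEdges", function(object) standardGeneric("leftEdges"))

#' @rdname BinnedFrequency-class
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))

#' @rdname BinnedFrequency-class
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))

#' @rdname BinnedFrequency-class
#' @export
setGeneric("nTotal", function(object) standardGeneric("nTotal"))

#' @rdname MixtureFit-class
#' @param object a `MixtureFit`.
#' @export
setGeneric("componentTable", function(object) standardGeneric("componentTable"))

#' @rdname MixtureFit-class
#' @export
setGeneric("componentWeights",
           function(object) standardGeneric("componentWeights"))

#' @rdname MixtureFit-class
#' @export
setGeneric("fitQuality", function(object) standardGeneric("fitQuality"))

#' @rdname MixtureFit-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname MixtureFit-class
#' @export
setGeneric("predictedCounts",
           function(object) standardGeneric("predictedCounts"))

#' Expected misassignment inside cut-off windows
#'
#' @param object a [MixtureFit-class] or a data.frame of components.
#' @param ... passed to methods.
#' @export
setGeneric("misassignment", function(object, ...)
    standardGeneric("misassignment"))

#' @rdname DecisionCurve-class
#' @param object a `DecisionCurve`.
#' @export
setGeneric("crossover", function(object) standardGeneric("crossover"))
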