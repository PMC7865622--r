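#' @include utils.R
NULL

#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @export
setGeneric("arm", function(x) standardGeneric("arm"))

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("sensorData", function(x) standardGeneric("sensorData"))

#' @export
setGeneric("setBoundaries", function(x) standardGeneric("setBoundaries"))

#' @export
setGeneric("reportedRPE", function(x) standardGeneric("reportedRPE"))

#' @export
setGeneric("dumbbellMass", function(x) standardGeneric("dumbbellMass"))

#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @export
setGeneric("significanceAllowance",
           function(x) standardGeneric("significanceAllowance"))

#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @export
setGeneric("evalMetrics", function(x) standardGeneric("evalMetrics"))

#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))
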