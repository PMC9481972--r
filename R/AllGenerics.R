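#' @rdname TissueGraph-accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname TissueGraph-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname TissueGraph-accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname TissueGraph-accessors
#' @export
setGeneric("wallData", function(x) standardGeneric("wallData"))

#' @rdname TissueGraph-accessors
#' @export
setGeneric("centerCell", function(x) standardGeneric("centerCell"))

#' @rdname TissueGraph-accessors
#' @export
setGeneric("timeIndex", function(x) standardGeneric("timeIndex"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("featureMatrix", function(x, ...) standardGeneric("featureMatrix"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @rdname LineageMap-accessors
#' @export
setGeneric("divisions", function(x) standardGeneric("divisions"))

#' @rdname LineageMap-accessors
#' @export
setGeneric("survivors", function(x) standardGeneric("survivors"))

#' @rdname LineageMap-accessors
#' @export
setGeneric("isDividing", function(x, ids) standardGeneric("isDividing"))

#' @rdname TissueSeries-accessors
#' @export
setGeneric("tissueGraphs", function(x) standardGeneric("tissueGraphs"))

#' @rdname TissueSeries-accessors
#' @export
setGeneric("lineageMaps", function(x) standardGeneric("lineageMaps"))

#' @rdname decisionValues
#' @export
setGeneric("decisionValues", function(object, newdata, ...)
  standardGeneric("decisionValues"))
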