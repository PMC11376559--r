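#' @rdname spatialCoords
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname tissueImage
#' @export
setGeneric("tissueImage", function(x) standardGeneric("tissueImage"))

#' @rdname spotCounts
#' @export
setGeneric("spotCounts", function(x) standardGeneric("spotCounts"))

#' @rdname adjacency
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname viewName
#' @export
setGeneric("viewName", function(x) standardGeneric("viewName"))

#' @rdname featureMatrix
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname domainLabels
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))
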