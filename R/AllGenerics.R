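#' @rdname DecoySet
#' @param object,x a `DecoySet` (or the class named by the generic).
#' @export
setGeneric("complexId", function(object) standardGeneric("complexId"))

#' @rdname DecoySet
#' @export
setGeneric("decoyIds", function(object) standardGeneric("decoyIds"))

#' @rdname DecoySet
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' @rdname DecoySet
#' @param value replacement value.
#' @export
setGeneric("features<-", function(object, value) standardGeneric("features<-"))

#' @rdname DecoySet
#' @export
setGeneric("labels")

#' @rdname DecoySet
#' @export
setGeneric("initialRanks", function(object) standardGeneric("initialRanks"))

#' @rdname DecoySet
#' @export
setGeneric("receptorCoords", function(object) standardGeneric("receptorCoords"))

#' @rdname DecoySet
#' @export
setGeneric("ligandCoords", function(object) standardGeneric("ligandCoords"))

#' @rdname DecoySet
#' @export
setGeneric("hasCoordinates", function(object) standardGeneric("hasCoordinates"))

#' @rdname DecoySet
#' @export
setGeneric("nDecoys", function(object) standardGeneric("nDecoys"))

#' @rdname FeatureSchema
#' @param object a `FeatureSchema`.
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @rdname FeatureSchema
#' @export
setGeneric("isFitted", function(object) standardGeneric("isFitted"))

#' @rdname RankingModel
#' @param object object to extract from.
#' @export
setGeneric("weights")

#' @rdname Clustering
#' @param object a `Clustering`, `ClusterRanking` or other object with
#'   clusters.
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname Clustering
#' @export
setGeneric("clusterAssignment",
           function(object) standardGeneric("clusterAssignment"))
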