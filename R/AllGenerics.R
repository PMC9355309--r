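#' @export
setGeneric("groupOrder", function(x) standardGeneric("groupOrder"))

#' @export
setGeneric("referenceGroup", function(x) standardGeneric("referenceGroup"))

#' @export
setGeneric("assayScale", function(x) standardGeneric("assayScale"))

#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @export
setGeneric("groupSamples", function(x, group) standardGeneric("groupSamples"))

#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))

#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @export
setGeneric("gseaTable", function(x) standardGeneric("gseaTable"))

#' @export
setGeneric("runningSums", function(x) standardGeneric("runningSums"))

#' @export
setGeneric("leadingEdges", function(x) standardGeneric("leadingEdges"))

#' @export
setGeneric("dnbTable", function(x) standardGeneric("dnbTable"))

#' @export
setGeneric("bestClusters", function(x) standardGeneric("bestClusters"))

#' @export
setGeneric("dnbEdges", function(x) standardGeneric("dnbEdges"))

#' @export
setGeneric("tippingPoint", function(x, ...) standardGeneric("tippingPoint"))
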