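#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @export
setGeneric("numtLength", function(x) standardGeneric("numtLength"))

#' @export
setGeneric("branchTable", function(x) standardGeneric("branchTable"))

#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))

#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @export
setGeneric("bestBranch", function(x) standardGeneric("bestBranch"))

#' @export
setGeneric("significanceSet", function(x) standardGeneric("significanceSet"))

#' @export
setGeneric("ageWindow", function(x) standardGeneric("ageWindow"))

#' @export
setGeneric("branchDensities", function(x) standardGeneric("branchDensities"))

#' @export
setGeneric("relation", function(x) standardGeneric("relation"))
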