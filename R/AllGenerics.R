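# Generics for the package's accessors and main verbs.

#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))

#' @export
setGeneric("nGametes", function(x) standardGeneric("nGametes"))

#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @export
setGeneric("unitLabels", function(x) standardGeneric("unitLabels"))

#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))

#' @export
setGeneric("thetas", function(x) standardGeneric("thetas"))

#' @export
setGeneric("pairSums", function(x, ...) standardGeneric("pairSums"))

#' @export
setGeneric("hudsonPairwise", function(x, ...) standardGeneric("hudsonPairwise"))

#' @export
setGeneric("sMatrix", function(x, ...) standardGeneric("sMatrix"))

#' @export
setGeneric("coancestryW", function(x) standardGeneric("coancestryW"))

#' @export
setGeneric("coancestryH", function(x) standardGeneric("coancestryH"))

#' @export
setGeneric("fittedTree", function(x) standardGeneric("fittedTree"))

#' @export
setGeneric("objectiveXi", function(x) standardGeneric("objectiveXi"))
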