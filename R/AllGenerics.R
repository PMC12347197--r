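#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @export
setGeneric("preprocessReport", function(x) standardGeneric("preprocessReport"))

#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))

#' @export
setGeneric("rankOrder", function(x) standardGeneric("rankOrder"))

#' @export
setGeneric("rankMethod", function(x) standardGeneric("rankMethod"))

#' @export
setGeneric("bestFitness", function(x) standardGeneric("bestFitness"))

#' @export
setGeneric("bestSubset", function(x) standardGeneric("bestSubset"))
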