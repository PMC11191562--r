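#' @export
setGeneric("rnaCounts", function(x) standardGeneric("rnaCounts"))

#' @export
setGeneric("atacCounts", function(x) standardGeneric("atacCounts"))

#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @export
setGeneric("tssRanges", function(x) standardGeneric("tssRanges"))

#' @export
setGeneric("cellInfo", function(x) standardGeneric("cellInfo"))

#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @export
setGeneric("blockBounds", function(x) standardGeneric("blockBounds"))

#' @export
setGeneric("deviationScores", function(x, type = c("z", "raw"))
    standardGeneric("deviationScores"))

#' @export
setGeneric("sldscCoefs", function(x) standardGeneric("sldscCoefs"))

#' @export
setGeneric("h2Estimate", function(x) standardGeneric("h2Estimate"))

#' @export
setGeneric("sldscIntercept", function(x) standardGeneric("sldscIntercept"))
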