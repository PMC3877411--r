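#' @rdname genotypeCalls
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname intensities
#' @export
setGeneric("intensityA", function(x) standardGeneric("intensityA"))

#' @rdname intensities
#' @export
setGeneric("intensityB", function(x) standardGeneric("intensityB"))

#' @rdname tabulateCounts
#' @export
setGeneric("tabulateCounts", function(x, ...) standardGeneric("tabulateCounts"))

#' @rdname estimateInbreeding
#' @export
setGeneric("estimateInbreeding",
           function(x, ...) standardGeneric("estimateInbreeding"))

#' @rdname imputeRandom
#' @export
setGeneric("imputeRandom",
           function(x, m = 50L, seed = NULL, ...) standardGeneric("imputeRandom"))

#' @rdname ImputedPanelSet-accessors
#' @export
setGeneric("completions", function(x) standardGeneric("completions"))

#' @rdname convergenceTrace
#' @export
setGeneric("convergenceTrace",
           function(x, marker = NULL) standardGeneric("convergenceTrace"))
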