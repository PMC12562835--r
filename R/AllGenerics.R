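#' @rdname YstrPanel-class
#' @param x an object.
#' @export
setGeneric("panelLoci", function(x) standardGeneric("panelLoci"))

#' @rdname YstrPanel-class
#' @export
setGeneric("expectedCopies", function(x) standardGeneric("expectedCopies"))

#' @rdname YstrPanel-class
#' @export
setGeneric("mutationRates", function(x) standardGeneric("mutationRates"))

#' @rdname YstrHaplotypes-class
#' @param x an object.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname YstrHaplotypes-class
#' @param sample sample identifier.
#' @export
setGeneric("alleleCalls", function(x, sample) standardGeneric("alleleCalls"))

#' @rdname PedigreePairs-class
#' @param x an object.
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname PedigreePairs-class
#' @export
setGeneric("meioses", function(x) standardGeneric("meioses"))

#' @rdname PairComparisonSet-class
#' @param x an object.
#' @export
setGeneric("mutationEvents", function(x) standardGeneric("mutationEvents"))

#' @rdname PairComparisonSet-class
#' @export
setGeneric("pairSummary", function(x) standardGeneric("pairSummary"))
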