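## Accessor generics. Slot access from user code should go through these.

#' @rdname AlignedPair-class
#' @param x An object.
#' @export
setGeneric("alignedRows", function(x) standardGeneric("alignedRows"))
#' @rdname AlignedPair-class
#' @export
setMethod("alignedRows", "AlignedPair", function(x) {
  stats::setNames(c(x@alnA, x@alnB), c(x@idA, x@idB))
})

#' @rdname AlignedPair-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname AlignedPair-class
#' @export
setMethod("alignmentScore", "AlignedPair", function(x) x@score)

#' @rdname IdentityTrack-class
#' @param x An object.
#' @export
setGeneric("trackCenters", function(x) standardGeneric("trackCenters"))
#' @rdname IdentityTrack-class
#' @export
setMethod("trackCenters", "IdentityTrack", function(x) x@centers)

#' @rdname IdentityTrack-class
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname IdentityTrack-class
#' @export
setMethod("trackValues", "IdentityTrack", function(x) x@values)

#' @rdname CodonAlignment-class
#' @param x An object.
#' @export
setGeneric("codonRows", function(x) standardGeneric("codonRows"))
#' @rdname CodonAlignment-class
#' @export
setMethod("codonRows", "CodonAlignment", function(x) x@aln)

#' @rdname ConversionTract-class
#' @param x An object.
#' @export
setGeneric("minimalSpan", function(x) standardGeneric("minimalSpan"))
#' @rdname ConversionTract-class
#' @export
setMethod("minimalSpan", "ConversionTract", function(x) x@minimalSpan)

#' @rdname ConversionTract-class
#' @export
setGeneric("maximalSpan", function(x) standardGeneric("maximalSpan"))
#' @rdname ConversionTract-class
#' @export
setMethod("maximalSpan", "ConversionTract", function(x) x@maximalSpan)

#' @rdname ConversionTract-class
#' @export
setGeneric("nSupportSites", function(x) standardGeneric("nSupportSites"))
#' @rdname ConversionTract-class
#' @export
setMethod("nSupportSites", "ConversionTract", function(x) x@nSupportSites)

#' @rdname ConversionTract-class
#' @export
setGeneric("tractCounts", function(x) standardGeneric("tractCounts"))
#' @rdname ConversionTract-class
#' @export
setMethod("tractCounts", "ConversionTract", function(x) {
  c(nSnpsVsRecipient = x@nSnpsVsRecipient,
    nNonsynonymous = x@nNonsynonymous,
    nSynonymous = x@nSynonymous)
})

#' @rdname ChimeraReport-class
#' @param x An object.
#' @export
setGeneric("recipientId", function(x) standardGeneric("recipientId"))
#' @rdname ChimeraReport-class
#' @export
setMethod("recipientId", "ChimeraReport", function(x) x@recipientId)
#' @rdname ChimeraReport-class
#' @export
setMethod("recipientId", "ConversionTract", function(x) x@recipientId)

#' @rdname ChimeraReport-class
#' @export
setGeneric("donorId", function(x) standardGeneric("donorId"))
#' @rdname ChimeraReport-class
#' @export
setMethod("donorId", "ChimeraReport", function(x) x@donorId)
#' @rdname ChimeraReport-class
#' @export
setMethod("donorId", "ConversionTract", function(x) x@donorId)

#' @rdname ChimeraReport-class
#' @export
setGeneric("tracts", function(x) standardGeneric("tracts"))
#' @rdname ChimeraReport-class
#' @export
setMethod("tracts", "ChimeraReport", function(x) x@tracts)

#' @rdname ChimeraReport-class
#' @export
setGeneric("residualUnexplained",
           function(x) standardGeneric("residualUnexplained"))
#' @rdname ChimeraReport-class
#' @export
setMethod("residualUnexplained", "ChimeraReport",
          function(x) x@residualUnexplained)

#' @rdname PoolCounts-class
#' @param x An object.
#' @export
setGeneric("poolSites", function(x) standardGeneric("poolSites"))
#' @rdname PoolCounts-class
#' @export
setMethod("poolSites", "PoolCounts", function(x) x@sites)

#' @rdname SegregationResult-class
#' @param x An object.
#' @export
setGeneric("patternCounts", function(x) standardGeneric("patternCounts"))
#' @rdname SegregationResult-class
#' @export
setMethod("patternCounts", "SegregationResult", function(x) x@patternCounts)

#' @rdname SegregationResult-class
#' @export
setGeneric("binomialP", function(x) standardGeneric("binomialP"))
#' @rdname SegregationResult-class
#' @export
setMethod("binomialP", "SegregationResult", function(x) x@binomialP)

#' @rdname SegregationResult-class
#' @export
setGeneric("consistentSingleLocus",
           function(x) standardGeneric("consistentSingleLocus"))
#' @rdname SegregationResult-class
#' @export
setMethod("consistentSingleLocus", "SegregationResult",
          function(x) x@consistentSingleLocus)

#' @rdname ScenarioTruth-class
#' @param x An object.
#' @export
setGeneric("scenarioTruth", function(x) standardGeneric("scenarioTruth"))
#' @rdname ScenarioTruth-class
#' @export
setMethod("scenarioTruth", "ScenarioTruth", function(x) {
  list(seed = x@seed, recipientId = x@recipientId, donorId = x@donorId,
       tract = x@tract, causalIndex = x@causalIndex,
       causalWindow = x@causalWindow)
})
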