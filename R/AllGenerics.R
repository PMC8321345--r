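#' @name wsiseg-accessors
#' @title Accessors for wsiseg S4 objects
#' @description Slot accessors for [SegNet-class], [DecoderOutputs-class],
#'   [Heatmap-class] and [SectionResult-class] objects.
#' @param object an object of the documented class.
#' @return the accessed component.
NULL

#' @rdname wsiseg-accessors
#' @export
setGeneric("networkConfig", function(object) standardGeneric("networkConfig"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("scoreMaps", function(object) standardGeneric("scoreMaps"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("probMaps", function(object) standardGeneric("probMaps"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("finalMap", function(object) standardGeneric("finalMap"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("mergeWeights", function(object) standardGeneric("mergeWeights"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("probMatrix", function(object) standardGeneric("probMatrix"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("mpp", function(object) standardGeneric("mpp"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("sectionId", function(object) standardGeneric("sectionId"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("sectionLabel", function(object) standardGeneric("sectionLabel"))

#' @rdname wsiseg-accessors
#' @export
setGeneric("tumorRegions", function(object) standardGeneric("tumorRegions"))

#' @rdname wsiseg-accessors
#' @export
setMethod("networkConfig", "SegNet", function(object) object@config)

#' @rdname wsiseg-accessors
#' @export
setMethod("nParameters", "SegNet", function(object)
  sum(vapply(object@params, length, numeric(1))))

#' @rdname wsiseg-accessors
#' @export
setMethod("scoreMaps", "DecoderOutputs", function(object) object@scoreMaps)

#' @rdname wsiseg-accessors
#' @export
setMethod("probMaps", "DecoderOutputs", function(object) object@probMaps)

#' @rdname wsiseg-accessors
#' @export
setMethod("finalMap", "DecoderOutputs", function(object) object@final)

#' @rdname wsiseg-accessors
#' @export
setMethod("mergeWeights", "SegNet", function(object) {
  w <- object@params[["merge.w"]]
  if (is.null(w)) numeric(0) else as.numeric(w)
})

#' @rdname wsiseg-accessors
#' @export
setMethod("probMatrix", "Heatmap", function(object) object@prob)

#' @rdname wsiseg-accessors
#' @export
setMethod("mpp", "Heatmap", function(object) object@mpp)

#' @rdname wsiseg-accessors
#' @export
setMethod("sectionId", "Heatmap", function(object) object@sectionId)

#' @rdname wsiseg-accessors
#' @export
setMethod("sectionId", "SectionResult", function(object) object@sectionId)

#' @rdname wsiseg-accessors
#' @export
setMethod("sectionLabel", "SectionResult", function(object) object@label)

#' @rdname wsiseg-accessors
#' @export
setMethod("tumorRegions", "SectionResult", function(object) object@regions)
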