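#' Accessors for posturePMA classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a posturePMA S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setMethod("coords", "MarkerTrial", function(object) object@coords)

#' @rdname accessors
#' @export
setGeneric("markerLabels", function(object) standardGeneric("markerLabels"))
#' @rdname accessors
#' @export
setMethod("markerLabels", "MarkerTrial", function(object) object@markers)

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setMethod("sampleRate", "MarkerTrial", function(object) object@rate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "PMScores", function(object) object@rate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "PostureMatrix", function(object) object@rate)

#' @rdname accessors
#' @export
setGeneric("trialMeta", function(object) standardGeneric("trialMeta"))
#' @rdname accessors
#' @export
setMethod("trialMeta", "MarkerTrial", function(object) object@meta)
#' @rdname accessors
#' @export
setMethod("trialMeta", "PMScores", function(object) object@meta)

#' @rdname accessors
#' @export
setGeneric("postureData", function(object) standardGeneric("postureData"))
#' @rdname accessors
#' @export
setMethod("postureData", "PostureMatrix", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("rowLedger", function(object) standardGeneric("rowLedger"))
#' @rdname accessors
#' @export
setMethod("rowLedger", "PostureMatrix", function(object) object@rowLedger)

#' @rdname accessors
#' @export
setGeneric("colLedger", function(object) standardGeneric("colLedger"))
#' @rdname accessors
#' @export
setMethod("colLedger", "PostureMatrix", function(object) object@colLedger)
#' @rdname accessors
#' @export
setMethod("colLedger", "PMBasis", function(object) object@colLedger)

#' @rdname accessors
#' @export
setGeneric("meanPosture", function(object) standardGeneric("meanPosture"))
#' @rdname accessors
#' @export
setMethod("meanPosture", "PMBasis", function(object) object@meanPosture)

#' @rdname accessors
#' @export
setGeneric("pcVectors", function(object) standardGeneric("pcVectors"))
#' @rdname accessors
#' @export
setMethod("pcVectors", "PMBasis", function(object) object@vectors)

#' @rdname accessors
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setMethod("eigenValues", "PMBasis", function(object) object@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("relEV", function(object) standardGeneric("relEV"))
#' @rdname accessors
#' @export
setMethod("relEV", "PMBasis", function(object) object@relEV)

#' @rdname accessors
#' @export
setGeneric("principalPositions", function(object) standardGeneric("principalPositions"))
#' @rdname accessors
#' @export
setMethod("principalPositions", "PMScores", function(object) object@pp)

#' @rdname accessors
#' @export
setGeneric("principalVelocities", function(object) standardGeneric("principalVelocities"))
#' @rdname accessors
#' @export
setMethod("principalVelocities", "PMScores", function(object) object@pv)

#' @rdname accessors
#' @export
setGeneric("principalAccelerations", function(object) standardGeneric("principalAccelerations"))
#' @rdname accessors
#' @export
setMethod("principalAccelerations", "PMScores", function(object) object@pa)
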