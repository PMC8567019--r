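#' @rdname betaValues
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname betaValues
#' @export
setGeneric("mValues", function(x, epsilon = 1e-6) standardGeneric("mValues"))

#' @rdname betaValues
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname probeManifest
#' @export
setGeneric("probeManifest", function(x) standardGeneric("probeManifest"))

#' @rdname probeManifest
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname computeScores
#' @export
setGeneric("computeScores", function(object, model, ...)
  standardGeneric("computeScores"))

#' @rdname ScoreModel-accessors
#' @export
setGeneric("selectedProbes", function(object) standardGeneric("selectedProbes"))
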