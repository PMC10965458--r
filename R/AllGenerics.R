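#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("clusterChannels", function(x, cluster) standardGeneric("clusterChannels"))

#' @rdname accessors
#' @export
setGeneric("electrodePositions", function(x) standardGeneric("electrodePositions"))

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname accessors
#' @export
setGeneric("trialMeta", function(x) standardGeneric("trialMeta"))

#' @rdname accessors
#' @export
setGeneric("rejectedEpochs", function(x) standardGeneric("rejectedEpochs"))

#' @rdname accessors
#' @export
setGeneric("interpolationLog", function(x) standardGeneric("interpolationLog"))

#' @rdname accessors
#' @export
setGeneric("powerValues", function(x) standardGeneric("powerValues"))

#' @rdname accessors
#' @export
setGeneric("powerFreqs", function(x) standardGeneric("powerFreqs"))

#' @rdname accessors
#' @export
setGeneric("powerTimes", function(x) standardGeneric("powerTimes"))

#' @rdname accessors
#' @export
setGeneric("diffValues", function(x) standardGeneric("diffValues"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("fdrSignificant", function(x) standardGeneric("fdrSignificant"))

#' @rdname accessors
#' @export
setGeneric("scalarTests", function(x) standardGeneric("scalarTests"))
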