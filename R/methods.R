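#' Accessors for thetapt S4 containers
#'
#' Small accessor functions are provided in place of direct slot access:
#' \code{channelLabels}, \code{samplingRate}, \code{eegData},
#' \code{eventTable}, \code{clusterChannels}, \code{electrodePositions},
#' \code{epochTimes}, \code{trialMeta}, \code{rejectedEpochs},
#' \code{interpolationLog}, \code{powerValues}, \code{powerFreqs},
#' \code{powerTimes}, \code{diffValues}, \code{pValues},
#' \code{fdrSignificant}, \code{scalarTests}.
#'
#' @param x a thetapt object.
#' @param cluster a cluster name (for \code{clusterChannels}).
#' @name accessors
NULL

#' @rdname accessors
setMethod("channelLabels", "EegMontage", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "EegRecording", function(x) rownames(x@data))
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)

#' @rdname accessors
setMethod("samplingRate", "EegRecording", function(x) x@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)

#' @rdname accessors
setMethod("eegData", "EegRecording", function(x) x@data)
#' @rdname accessors
setMethod("eegData", "EpochSet", function(x) x@data)

#' @rdname accessors
setMethod("eventTable", "EegRecording", function(x) x@events)

#' @rdname accessors
setMethod("clusterChannels", "EegMontage", function(x, cluster) {
  if (!cluster %in% names(x@clusters))
    stop("unknown cluster: ", cluster)
  x@clusters[[cluster]]
})

#' @rdname accessors
setMethod("electrodePositions", "EegMontage", function(x) x@positions)

#' @rdname accessors
setMethod("epochTimes", "EpochSet", function(x) x@times)
#' @rdname accessors
setMethod("trialMeta", "EpochSet", function(x) x@trialMeta)
#' @rdname accessors
setMethod("rejectedEpochs", "EpochSet", function(x) x@rejected)
#' @rdname accessors
setMethod("interpolationLog", "EpochSet", function(x) x@interpLog)

#' @rdname accessors
setMethod("powerValues", "ClusterPowerMap", function(x) x@power)
#' @rdname accessors
setMethod("powerFreqs", "ClusterPowerMap", function(x) x@freqs)
#' @rdname accessors
setMethod("powerTimes", "ClusterPowerMap", function(x) x@times)
#' @rdname accessors
setMethod("powerFreqs", "DiffMap", function(x) x@freqs)
#' @rdname accessors
setMethod("powerTimes", "DiffMap", function(x) x@times)
#' @rdname accessors
setMethod("powerFreqs", "StatResult", function(x) x@freqs)
#' @rdname accessors
setMethod("powerTimes", "StatResult", function(x) x@times)

#' @rdname accessors
setMethod("diffValues", "DiffMap", function(x) x@D)

#' @rdname accessors
setMethod("pValues", "StatResult", function(x) x@p)
#' @rdname accessors
setMethod("fdrSignificant", "StatResult", function(x) x@fdrMask)
#' @rdname accessors
setMethod("scalarTests", "StatResult", function(x) x@scalars)

setMethod("show", "EegMontage", function(object) {
  cat("EegMontage with", length(object@labels), "electrodes\n")
  for (nm in names(object@clusters))
    cat("  cluster", nm, ":", length(object@clusters[[nm]]), "channels\n")
})

setMethod("show", "EegRecording", function(object) {
  cat("EegRecording", object@participant, "\n")
  cat("  ", nrow(object@data), "channels x", ncol(object@data),
      "samples @", object@samplingRate, "Hz (",
      round(ncol(object@data) / object@samplingRate, 1), "s )\n")
  cat("  ", nrow(object@events), "events\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[1], "epochs x", d[2], "channels x", d[3],
      "samples @", object@samplingRate, "Hz\n")
  cat("  time", round(min(object@times), 3), "..",
      round(max(object@times), 3), "s;",
      sum(object@rejected), "epochs rejected\n")
})

setMethod("show", "ClusterPowerMap", function(object) {
  cat("ClusterPowerMap [", object@participant, "/", object@condition, "/",
      object@cluster, "]:", length(object@freqs), "freqs x",
      length(object@times), "times\n")
})

setMethod("show", "DiffMap", function(object) {
  cat("DiffMap", object@contrast, "[", object@participant, "/",
      object@cluster, "]:", length(object@freqs), "freqs x",
      length(object@times), "times\n")
})

setMethod("show", "StatResult", function(object) {
  cat("StatResult", object@contrast, "[", object@cluster, "]\n")
  if (length(object@p))
    cat("  map:", nrow(object@p), "freqs x", ncol(object@p), "times;",
        sum(object@fdrMask, na.rm = TRUE), "FDR-significant points (q =",
        object@qLevel, ")\n")
  if (nrow(object@scalars)) {
    cat("  scalar tests:\n")
    print(object@scalars, row.names = FALSE)
  }
})
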