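#' @import methods
NULL

#' Electrode montage on an idealized unit sphere
#'
#' Maps electrode labels to 3-D positions on the unit sphere and carries
#' named channel clusters (e.g. midfrontal, left/right temporal-parietal)
#' plus the outer-ring set that is dropped early in preprocessing.
#'
#' @slot labels character vector of unique electrode labels.
#' @slot positions numeric matrix (n x 3), unit-norm rows, rownames = labels.
#' @slot clusters named list of character vectors; every member label must
#'   exist in \code{labels}.
#'
#' @exportClass EegMontage
setClass("EegMontage",
  representation(labels = "character",
                 positions = "matrix",
                 clusters = "list"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@labels))
      msg <- c(msg, "electrode labels must be unique")
    if (nrow(object@positions) != length(object@labels) ||
        ncol(object@positions) != 3L)
      msg <- c(msg, "positions must be an n x 3 matrix matching labels")
    else {
      nrm <- sqrt(rowSums(object@positions^2))
      if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "positions must lie on the unit sphere")
    }
    bad <- vapply(object@clusters,
                  function(ch) !all(ch %in% object@labels), logical(1))
    if (any(bad))
      msg <- c(msg, paste("cluster(s) reference unknown labels:",
                          paste(names(object@clusters)[bad], collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  })

#' Continuous multichannel EEG recording
#'
#' @slot data numeric matrix, channels x samples, in microvolts; rownames
#'   are channel labels.
#' @slot samplingRate sampling rate in Hz.
#' @slot events data.frame with at least \code{trial_index},
#'   \code{trial_type}, \code{onset_sample} (0-based sample index of the
#'   Prompt-2 offset), \code{validity} (comma-joined codes or "") and
#'   \code{correct} (0/1/NA).
#' @slot participant participant identifier.
#'
#' @exportClass EegRecording
setClass("EegRecording",
  representation(data = "matrix",
                 samplingRate = "numeric",
                 events = "data.frame",
                 participant = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single positive number")
    if (is.null(rownames(object@data)))
      msg <- c(msg, "data must have channel labels as rownames")
    else if (anyDuplicated(rownames(object@data)))
      msg <- c(msg, "channel labels must be unique")
    ev <- object@events
    need <- c("trial_index", "trial_type", "onset_sample", "validity",
              "correct")
    if (!all(need %in% names(ev)))
      msg <- c(msg, paste("events must contain columns:",
                          paste(need, collapse = ", ")))
    else if (nrow(ev) &&
             (any(ev$onset_sample < 0) ||
              any(ev$onset_sample >= ncol(object@data))))
      msg <- c(msg, "event onset samples must fall inside the recording")
    if (is.null(msg)) TRUE else msg
  })

#' Epoched EEG, time-locked to the Prompt-2 offset
#'
#' @slot data numeric array, trials x channels x samples (microvolts).
#' @slot times time axis in seconds relative to the Prompt-2 offset;
#'   covers at least [-pad, window + pad].
#' @slot samplingRate Hz.
#' @slot channelLabels channel labels (second array dimension).
#' @slot trialMeta data.frame of trial metadata, one row per epoch.
#' @slot interpLog list (one element per epoch) of channel labels flagged
#'   for interpolation / already interpolated.
#' @slot rejected logical, one flag per epoch; rejected epochs are excluded
#'   from every downstream average.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array",
                 times = "numeric",
                 samplingRate = "numeric",
                 channelLabels = "character",
                 trialMeta = "data.frame",
                 interpLog = "list",
                 rejected = "logical"),
  validity = function(object) {
    d <- dim(object@data)
    msg <- NULL
    if (length(d) != 3L)
      msg <- c(msg, "data must be a trials x channels x samples array")
    else {
      if (d[2] != length(object@channelLabels))
        msg <- c(msg, "channelLabels must match dim 2 of data")
      if (d[3] != length(object@times))
        msg <- c(msg, "times must match dim 3 of data")
      if (d[1] != nrow(object@trialMeta))
        msg <- c(msg, "trialMeta must have one row per epoch")
      if (d[1] != length(object@rejected))
        msg <- c(msg, "rejected must have one flag per epoch")
      if (d[1] != length(object@interpLog))
        msg <- c(msg, "interpLog must have one element per epoch")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Cluster-averaged spectral power for one participant and condition
#'
#' Frequencies x times map of trial- and cluster-averaged Morlet power
#' (microvolt^2-scaled, non-negative).
#'
#' @exportClass ClusterPowerMap
setClass("ClusterPowerMap",
  representation(power = "matrix",
                 freqs = "numeric",
                 times = "numeric",
                 participant = "character",
                 condition = "character",
                 cluster = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@power) != length(object@freqs) ||
        ncol(object@power) != length(object@times))
      msg <- c(msg, "power must be freqs x times")
    if (any(object@power < 0))
      msg <- c(msg, "power must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Normalized power difference map, D = (A - B) / (A + B)
#'
#' Per-participant bounded contrast between two non-negative power maps;
#' points with A + B = 0 are masked (NA).
#'
#' @exportClass DiffMap
setClass("DiffMap",
  representation(D = "matrix",
                 freqs = "numeric",
                 times = "numeric",
                 participant = "character",
                 contrast = "character",
                 cluster = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@D) != length(object@freqs) ||
        ncol(object@D) != length(object@times))
      msg <- c(msg, "D must be freqs x times")
    v <- object@D[is.finite(object@D)]
    if (length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
      msg <- c(msg, "D must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Inference result: observed map, permutation p-values, FDR mask, scalars
#'
#' @slot observed across-participant mean D at each time-frequency point.
#' @slot p two-sided permutation p-values (freqs x times).
#' @slot fdrMask logical map of Benjamini-Hochberg rejections at qLevel.
#' @slot scalars data.frame of named scalar tests (test, statistic, df, p).
#'
#' @exportClass StatResult
setClass("StatResult",
  representation(observed = "matrix",
                 p = "matrix",
                 qLevel = "numeric",
                 fdrMask = "matrix",
                 scalars = "data.frame",
                 nPerm = "numeric",
                 seed = "numeric",
                 freqs = "numeric",
                 times = "numeric",
                 cluster = "character",
                 contrast = "character"),
  validity = function(object) {
    msg <- NULL
    pv <- object@p[is.finite(object@p)]
    if (length(pv) && (min(pv) < 0 || max(pv) > 1))
      msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(object@fdrMask) &&
        !identical(dim(object@fdrMask), dim(object@p)))
      msg <- c(msg, "fdrMask must match the p map")
    if (is.null(msg)) TRUE else msg
  })
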