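#' Time-frequency analysis parameters
#'
#' Complex Morlet wavelet family over a frequency grid (default 3-30 Hz in
#' 0.5 Hz steps) with frequency-dependent cycles (default: 3 cycles at
#' 3 Hz increasing linearly to 8 at 30 Hz), and a decimated output time
#' grid inside the unpadded 2-s experimental window.
#'
#' @param freqs ascending frequency grid in Hz.
#' @param cycles wavelet cycles per frequency (recycled/interpolated);
#'   \code{NULL} for the linear default.
#' @param output_times output time grid in seconds, inside [0, 2].
#' @return list of class \code{TfrParams}.
#' @export
tfrParams <- function(freqs = seq(3, 30, by = 0.5),
                      cycles = NULL,
                      output_times = seq(0, 2, by = 0.002)) {
  if (is.unsorted(freqs, strictly = TRUE))
    stop("freqs must be strictly ascending")
  if (is.null(cycles))
    cycles <- 3 + (freqs - 3) * (8 - 3) / (30 - 3)
  if (length(cycles) == 1) cycles <- rep(cycles, length(freqs))
  if (any(cycles < 2)) stop("cycles must be >= 2")
  p <- list(freqs = freqs, cycles = cycles, output_times = output_times)
  class(p) <- "TfrParams"
  p
}

## Half-support (seconds) of the longest wavelet: 3.5 temporal SDs.
.waveletHalfSupport <- function(params) {
  sigma <- params$cycles / (2 * pi * params$freqs)
  max(3.5 * sigma)
}

#' Per-trial Morlet spectral power
#'
#' Convolves every channel of every epoch with complex Morlet wavelets and
#' returns squared magnitudes, sampled on the output time grid. Wavelets
#' are gain-normalized so that a sinusoid of amplitude A at a matched
#' frequency yields power ~ A^2 (microvolt^2-scaled). The epoch padding
#' must cover at least half of the longest (lowest-frequency) wavelet so
#' that edge effects never reach the experimental window; otherwise an
#' error names the required padding.
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param params a \code{\link{tfrParams}}.
#' @param channels channels to transform (default: all).
#' @return numeric array trials x channels x freqs x times with dimnames
#'   on the channel axis; rejected epochs are computed like any other and
#'   must be excluded downstream (see \code{\link{aggregateCluster}}).
#' @export
morletPower <- function(ep, params = tfrParams(),
                        channels = channelLabels(ep)) {
  fs <- ep@samplingRate
  times <- ep@times
  half <- .waveletHalfSupport(params)
  ot <- params$output_times
  if (min(ot) - min(times) < half - 1e-9 ||
      max(times) - max(ot) < half - 1e-9)
    stop(sprintf(
      "insufficient padding for the %.1f Hz wavelet: need >= %.3f s on each side of [%.3f, %.3f] s",
      params$freqs[1], half, min(ot), max(ot)))
  channels <- intersect(channels, channelLabels(ep))
  ci <- match(channels, channelLabels(ep))
  n_tr <- dim(ep@data)[1]
  n_ch <- length(ci)
  nsamp <- length(times)
  wl_max <- 2L * ceiling(half * fs) + 1L
  ## circular convolution: the wrap-around of the wavelet tails stays
  ## inside the padding (pad >= half support, checked above), so the FFT
  ## length only needs to cover the epoch and the longest wavelet
  N <- stats::nextn(max(nsamp, wl_max), c(2, 3, 5))

  ## stack all trial x channel signals as columns; one forward FFT
  X <- matrix(0, N, n_tr * n_ch)
  for (i in seq_len(n_tr)) {
    m <- ep@data[i, ci, , drop = FALSE]
    dim(m) <- c(n_ch, nsamp)
    X[seq_len(nsamp), (i - 1) * n_ch + seq_len(n_ch)] <- t(m)
  }
  XF <- stats::mvfft(X)

  oi <- round((ot - times[1]) * fs) + 1
  tmp <- array(0, dim = c(length(ot), n_ch, n_tr, length(params$freqs)))
  for (k in seq_along(params$freqs)) {
    f <- params$freqs[k]
    sigma <- params$cycles[k] / (2 * pi * f)
    hw <- ceiling(3.5 * sigma * fs)
    tw <- (-hw:hw) / fs
    env <- exp(-tw^2 / (2 * sigma^2))
    w <- env * exp(2i * pi * f * tw) / (sum(env) / 2)
    ## kernel with its center wrapped to index 1 (negative lags at the end)
    kv <- complex(length.out = N)
    kv[seq_len(hw + 1)] <- w[hw + seq_len(hw + 1)]
    kv[N - hw + seq_len(hw)] <- w[seq_len(hw)]
    KF <- stats::fft(kv)
    ## the wavelet spectrum is narrow-band: invert only its support, as a
    ## band-limited inverse DFT evaluated at the output samples
    J <- which(Mod(KF) > 1e-3 * max(Mod(KF)))
    if (length(J) < N / 3) {
      E <- exp(2i * pi * outer(oi - 1, J - 1) / N) / N
      Z <- E %*% (XF[J, , drop = FALSE] * KF[J])
    } else {
      Z <- stats::mvfft(XF * KF, inverse = TRUE)[oi, , drop = FALSE] / N
    }
    tmp[, , , k] <- Re(Z)^2 + Im(Z)^2
  }
  out <- aperm(tmp, c(3, 2, 4, 1))
  dimnames(out) <- list(NULL, channels, NULL, NULL)
  attr(out, "freqs") <- params$freqs
  attr(out, "times") <- ot
  out
}

#' Map a condition selector to trial types
#'
#' \code{"PT"} pools CanSee and DoesNotSee; \code{"Control"} pools Yellow
#' and NotYellow; single trial types select themselves.
#'
#' @param condition selector string.
#' @return character vector of trial types.
#' @export
conditionTrialTypes <- function(condition) {
  switch(condition,
         PT = c("CanSee", "DoesNotSee"),
         Control = c("Yellow", "NotYellow"),
         {
           if (!condition %in% trialTypes())
             stop("unknown condition selector: ", condition)
           condition
         })
}

#' Aggregate per-trial power to a cluster/condition map
#'
#' Means the per-trial power maps over the surviving (non-rejected) trials
#' of the selected types, then over the cluster's channels.
#'
#' @param power array from \code{\link{morletPower}}.
#' @param trial_meta trial metadata aligned with the power array's first
#'   dimension (e.g. \code{trialMeta(ep)}).
#' @param cluster cluster name (for labeling) or character vector of
#'   channel labels.
#' @param condition condition selector (see
#'   \code{\link{conditionTrialTypes}}).
#' @param montage montage used to resolve a cluster name into channels.
#' @param rejected logical per-trial rejection flags (default: none).
#' @param participant participant identifier for labeling.
#' @return a \linkS4class{ClusterPowerMap}.
#' @export
aggregateCluster <- function(power, trial_meta, cluster, condition,
                             montage = NULL,
                             rejected = rep(FALSE, dim(power)[1]),
                             participant = "") {
  types <- conditionTrialTypes(condition)
  sel <- trial_meta$trial_type %in% types & !rejected
  if (!any(sel))
    stop("no surviving trials match condition ", condition,
         " (participant flagged for exclusion)")
  chans <- if (length(cluster) == 1 && !is.null(montage) &&
               cluster %in% names(montage@clusters))
    clusterChannels(montage, cluster) else cluster
  chans <- intersect(chans, dimnames(power)[[2]])
  if (length(chans) == 0) stop("no cluster channels present in power array")
  sub <- power[sel, chans, , , drop = FALSE]
  d <- dim(sub)
  map <- matrix(colMeans(matrix(sub, d[1] * d[2], d[3] * d[4])),
                d[3], d[4])
  new("ClusterPowerMap", power = map,
      freqs = attr(power, "freqs"), times = attr(power, "times"),
      participant = as.character(participant),
      condition = condition,
      cluster = if (length(cluster) == 1) cluster else "custom")
}

#' Convert a power map to decibels
#'
#' 10 * log10 of power; for reporting only (the normalized-difference
#' statistic uses raw power).
#'
#' @param x a \linkS4class{ClusterPowerMap} or numeric array of strictly
#'   positive power values.
#' @return same shape, in dB.
#' @export
toDecibel <- function(x) {
  if (is(x, "ClusterPowerMap")) {
    if (any(x@power <= 0)) stop("power must be strictly positive for dB")
    return(10 * log10(x@power))
  }
  if (any(x <= 0)) stop("power must be strictly positive for dB")
  10 * log10(x)
}
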