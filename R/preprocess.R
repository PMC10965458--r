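#' Preprocessing configuration
#'
#' All thresholds of the artifact-rejection cascade, with the printed
#' study values as defaults so any deviation is a visible diff.
#'
#' The +/-1000 threshold of the combined voltage/spectral epoch rule is
#' interpreted in microvolts (a millivolt threshold would never trigger on
#' scalp EEG). The dB of the 20-40 Hz spectral rule is 10*log10 of mean
#' band power in microvolt^2.
#'
#' @param band band-pass edges in Hz.
#' @param target_rate resampling target in Hz.
#' @param ica_highpass high-pass (Hz) applied to the ICA copy.
#' @param ica_epoch_len epoch length (s) for the ICA artifact scan.
#' @param volt_thresh voltage threshold (microvolts) of the epoch rule.
#' @param spect_band frequency band (Hz) of the spectral epoch rule.
#' @param spect_range admissible band-power range in dB.
#' @param chan_bad_epoch_frac channels with more than this fraction of
#'   artifacted 1-s epochs are removed (strictly greater).
#' @param ocular_thresh ocular voltage threshold (microvolts).
#' @param ocular_channels frontal channel set for the ocular rule.
#' @param interp_frac epochs with more than this fraction of flagged
#'   channels are rejected (strictly greater).
#' @param pad epoch padding on each side, seconds.
#' @param ica_ncomp maximum number of ICA components.
#' @param ica_blink_topo frontal/global mean |topography| ratio above which
#'   (together with dominant low-frequency power) a component counts as a
#'   blink.
#' @param ica_lowfreq_frac fraction of source power below 3 Hz required
#'   for the blink rule.
#' @param ica_kurt_thresh excess-kurtosis threshold for transient
#'   components.
#' @param ica_muscle_frac fraction of source power above 20 Hz above which
#'   a component counts as muscle.
#' @return list of class \code{PreprocConfig}.
#' @export
preprocConfig <- function(band = c(0.3, 50),
                          target_rate = 500,
                          ica_highpass = 1,
                          ica_epoch_len = 1,
                          volt_thresh = 1000,
                          spect_band = c(20, 40),
                          spect_range = c(-100, 30),
                          chan_bad_epoch_frac = 0.20,
                          ocular_thresh = 250,
                          ocular_channels = ocularChannels(),
                          interp_frac = 0.10,
                          pad = 1,
                          ica_ncomp = 30L,
                          ica_blink_topo = 2,
                          ica_lowfreq_frac = 0.5,
                          ica_kurt_thresh = 10,
                          ica_muscle_frac = 0.6) {
  cfg <- list(band = band, target_rate = target_rate,
              ica_highpass = ica_highpass, ica_epoch_len = ica_epoch_len,
              volt_thresh = volt_thresh, spect_band = spect_band,
              spect_range = spect_range,
              chan_bad_epoch_frac = chan_bad_epoch_frac,
              ocular_thresh = ocular_thresh,
              ocular_channels = ocular_channels,
              interp_frac = interp_frac, pad = pad,
              ica_ncomp = as.integer(ica_ncomp),
              ica_blink_topo = ica_blink_topo,
              ica_lowfreq_frac = ica_lowfreq_frac,
              ica_kurt_thresh = ica_kurt_thresh,
              ica_muscle_frac = ica_muscle_frac)
  stopifnot(all(c(cfg$volt_thresh, cfg$ocular_thresh) > 0),
            cfg$chan_bad_epoch_frac > 0, cfg$chan_bad_epoch_frac < 1,
            cfg$interp_frac > 0, cfg$interp_frac < 1)
  class(cfg) <- "PreprocConfig"
  cfg
}

#' Design a Hamming-window band-pass FIR filter
#'
#' Windowed-sinc design. The transition bandwidth at the low edge is
#' \code{min(max(0.25 * low, 2), low)} Hz and at the high edge
#' \code{min(max(0.25 * high, 2), nyquist - high)}; the filter order is
#' \code{ceiling(3.3 / narrowest transition in normalized frequency)},
#' rounded up to even, and the -6 dB cutoffs sit mid-transition outside
#' the passband.
#'
#' @param low,high passband edges in Hz.
#' @param fs sampling rate in Hz.
#' @return list: \code{b} (coefficients), \code{order}, \code{cutoffs},
#'   \code{transition}.
#' @export
designBandpassFir <- function(low, high, fs) {
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("need 0 < low < high < fs/2")
  tb_low <- min(max(0.25 * low, 2), low)
  tb_high <- min(max(0.25 * high, 2), nyq - high)
  tb <- min(tb_low, tb_high)
  m <- ceiling(3.3 * fs / tb)
  if (m %% 2 == 1) m <- m + 1
  cut <- c(low - tb_low / 2, high + tb_high / 2)
  b <- signal::fir1(m, cut / nyq, type = "pass")
  list(b = as.numeric(b), order = m, cutoffs = cut,
       transition = c(low = tb_low, high = tb_high))
}

#' Frequency response magnitude of an FIR design
#'
#' @param design result of \code{\link{designBandpassFir}}.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return numeric vector of response magnitudes.
#' @export
firResponse <- function(design, freqs, fs) {
  k <- seq_along(design$b) - 1
  vapply(freqs, function(f)
    Mod(sum(design$b * exp(-2i * pi * f * k / fs))), numeric(1))
}

## Zero-phase FIR filtering of a channels x samples matrix: linear
## convolution by FFT, compensated by the group delay (order/2).
.firFilterMatrix <- function(data, b) {
  m <- length(b) - 1
  nsamp <- ncol(data)
  N <- stats::nextn(nsamp + m, c(2, 3, 5))
  B <- stats::fft(c(b, rep(0, N - length(b))))
  out <- matrix(0, nrow(data), nsamp, dimnames = dimnames(data))
  blocks <- split(seq_len(nrow(data)), ceiling(seq_len(nrow(data)) / 32))
  for (blk in blocks) {
    X <- rbind(t(data[blk, , drop = FALSE]),
               matrix(0, N - nsamp, length(blk)))
    Y <- Re(stats::mvfft(stats::mvfft(X) * B, inverse = TRUE)) / N
    out[blk, ] <- t(Y[m / 2 + seq_len(nsamp), , drop = FALSE])
  }
  out
}

#' Zero-phase band-pass filter a recording
#'
#' Applies the \code{\link{designBandpassFir}} filter to every channel,
#' compensating the linear-phase group delay so the output is zero-phase.
#'
#' @param rec an \linkS4class{EegRecording}.
#' @param low,high passband edges in Hz.
#' @return filtered \linkS4class{EegRecording}; the design is attached as
#'   attribute \code{"filter"} of the returned object's data.
#' @export
bandpassFir <- function(rec, low, high) {
  des <- designBandpassFir(low, high, rec@samplingRate)
  if (ncol(rec@data) <= des$order)
    stop("signal shorter than the filter order (", des$order, " samples)")
  rec@data <- .firFilterMatrix(rec@data, des$b)
  attr(rec@data, "filter") <- des[c("order", "cutoffs", "transition")]
  rec
}

#' Anti-aliased polyphase resampling
#'
#' Resamples every channel with \code{signal::resample} and rescales event
#' sample indices by \code{floor(s * p / q + 0.5)} (round half up).
#'
#' @param rec an \linkS4class{EegRecording}.
#' @param target target rate in Hz; must divide into a rational factor of
#'   the current rate and be below it.
#' @return resampled \linkS4class{EegRecording} with
#'   \code{ceiling(n * p / q)} samples.
#' @export
resampleRecording <- function(rec, target) {
  fs <- rec@samplingRate
  if (target >= fs) stop("target rate must be below the current rate")
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  a <- round(target * 1000); b <- round(fs * 1000)
  g <- gcd2(a, b)
  p <- a / g; q <- b / g
  n_out <- ceiling(ncol(rec@data) * p / q)
  out <- matrix(0, nrow(rec@data), n_out, dimnames = dimnames(rec@data))
  for (ch in seq_len(nrow(rec@data))) {
    y <- signal::resample(rec@data[ch, ], p, q)
    if (length(y) < n_out)            # pad the trailing edge sample
      y <- c(y, rep(y[length(y)], n_out - length(y)))
    out[ch, ] <- y[seq_len(n_out)]
  }
  rec@data <- out
  rec@samplingRate <- target
  rec@events$onset_sample <- pmin(n_out - 1L,
    as.integer(floor(rec@events$onset_sample * p / q + 0.5)))
  rec
}

#' Remove the 24 outer-ring channels
#'
#' Drops the channels of the montage's \code{outer_ring} cluster (they
#' mostly overlay neck and ears). Channels already absent are skipped: a
#' partial overlap warns, a second application is a no-op.
#'
#' @param rec an \linkS4class{EegRecording}.
#' @param montage an \linkS4class{EegMontage} with an \code{outer_ring}
#'   cluster.
#' @return \linkS4class{EegRecording} without the ring channels, order
#'   preserved.
#' @export
removeOuterRing <- function(rec, montage) {
  ring <- clusterChannels(montage, "outer_ring")
  present <- intersect(rownames(rec@data), ring)
  if (length(present) == 0) return(rec)
  if (length(present) < length(ring))
    warning("only ", length(present), " of ", length(ring),
            " outer-ring channels present; removing those")
  rec@data <- rec@data[setdiff(rownames(rec@data), ring), , drop = FALSE]
  rec
}

.robustZ <- function(x) {
  s <- stats::mad(x)
  if (s == 0) return(rep(0, length(x)))
  (x - stats::median(x)) / s
}

## Hurst exponent on a bounded-length segment (feature only; absolute
## precision is irrelevant, deviation from the channel median is what
## counts).
.hurstFeature <- function(x) {
  n <- length(x)
  if (n > 5000) x <- x[seq.int(floor(n / 2) - 2500 + 1, length.out = 5000)]
  pracma::hurstexp(x, display = FALSE)$Hs
}

#' Detect artifacted channels from per-channel features
#'
#' Flags channels whose robust z-score (median/MAD) exceeds 3 on any of
#' three features: variance (either direction), mean absolute correlation
#' with the other channels (low correlations flag), and deviation of the
#' Hurst exponent (either direction).
#'
#' @param rec an \linkS4class{EegRecording} with at least 8 channels.
#' @return character vector of flagged labels; the per-channel feature
#'   table is attached as attribute \code{"features"}.
#' @export
detectBadChannels <- function(rec) {
  data <- rec@data
  if (nrow(data) < 8) stop("need at least 8 channels")
  nsamp <- ncol(data)
  sub <- if (nsamp > 20000) data[, seq(1, nsamp, length.out = 20000)]
         else data
  v <- apply(sub, 1, stats::var)
  cm <- abs(stats::cor(t(sub)))
  diag(cm) <- NA
  mc <- rowMeans(cm, na.rm = TRUE)
  hu <- apply(sub, 1, .hurstFeature)
  zv <- .robustZ(v); zc <- .robustZ(mc); zh <- .robustZ(hu)
  flagged <- abs(zv) > 3 | zc < -3 | abs(zh) > 3
  feat <- data.frame(channel = rownames(data), variance = v,
                     mean_abs_cor = mc, hurst = hu,
                     z_var = zv, z_cor = zc, z_hurst = zh,
                     flagged = flagged, row.names = NULL)
  out <- rownames(data)[flagged]
  attr(out, "features") <- feat
  out
}

## Per-channel, per-epoch artifact scan on 1-s segments: voltage beyond
## +/-volt_thresh or 20-40 Hz band power (dB) outside spect_range.
.epochArtifactScan <- function(data, fs, cfg) {
  len <- round(cfg$ica_epoch_len * fs)
  n_ep <- floor(ncol(data) / len)
  bad <- matrix(FALSE, nrow(data), n_ep,
                dimnames = list(rownames(data), NULL))
  fgrid <- (seq_len(len) - 1) / len * fs
  in_band <- fgrid >= cfg$spect_band[1] & fgrid <= cfg$spect_band[2] &
    fgrid <= fs / 2
  for (e in seq_len(n_ep)) {
    seg <- data[, (e - 1) * len + seq_len(len), drop = FALSE]
    volt <- apply(abs(seg), 1, max) > cfg$volt_thresh
    P <- Mod(stats::mvfft(t(seg)))^2 / len
    bp <- colMeans(P[in_band, , drop = FALSE])
    dB <- 10 * log10(pmax(bp, 1e-300))
    bad[, e] <- volt | dB < cfg$spect_range[1] | dB > cfg$spect_range[2]
  }
  bad
}

#' ICA-based artifact removal
#'
#' Follows the copied-dataset strategy: (i) a copy of the recording is
#' high-pass filtered at \code{ica_highpass} Hz and scanned in 1-s epochs
#' for values beyond the voltage threshold or 20-40 Hz band power outside
#' the admissible dB range; (ii) channels artifacted in more than
#' \code{chan_bad_epoch_frac} of epochs are removed from both copy and
#' original; (iii) ICA is fitted on the clean epochs of the copy;
#' (iv) components are classified as artifacts by a deterministic feature
#' rule set (frontal-dominant topography with dominant low-frequency power
#' = blink; high temporal kurtosis = transient; dominant power above 20 Hz
#' = muscle); (v) flagged components are projected out of the original
#' recording.
#'
#' @param rec a band-passed, resampled \linkS4class{EegRecording}.
#' @param config a \code{\link{preprocConfig}}.
#' @param seed integer seed for the ICA initialization.
#' @return list: \code{recording} (cleaned original), \code{report}
#'   (removed channels, removed component indices, component feature
#'   table, number of artifacted scan epochs).
#' @export
icaArtifactRemoval <- function(rec, config = preprocConfig(), seed = 1L) {
  fs <- rec@samplingRate
  copy <- bandpassFir(rec, config$ica_highpass, 0.9 * fs / 2)
  bad <- .epochArtifactScan(copy@data, fs, config)
  frac <- rowMeans(bad)
  drop_ch <- rownames(rec@data)[frac > config$chan_bad_epoch_frac]
  keep <- setdiff(rownames(rec@data), drop_ch)
  rec@data <- rec@data[keep, , drop = FALSE]
  copy@data <- copy@data[keep, , drop = FALSE]
  bad <- bad[keep, , drop = FALSE]

  ## ICA on the concatenated clean 1-s epochs of the copy
  len <- round(config$ica_epoch_len * fs)
  clean_ep <- which(!apply(bad, 2, any))
  if (length(clean_ep) < 5)
    stop("too few clean epochs to fit ICA")
  idx <- as.vector(vapply(clean_ep,
                          function(e) as.integer((e - 1) * len +
                                                   seq_len(len)),
                          integer(len)))
  X <- copy@data[, idx, drop = FALSE]
  fit <- .fastICA(X, n_comp = min(nrow(X), config$ica_ncomp), seed = seed)

  cls <- .classifyComponents(fit, rownames(rec@data), fs, config)
  art <- which(cls$artifact)
  if (length(art)) {
    mu <- rowMeans(rec@data)
    S_orig <- fit$W %*% (rec@data - mu)
    rec@data <- rec@data -
      fit$A[, art, drop = FALSE] %*% S_orig[art, , drop = FALSE]
  }
  list(recording = rec,
       report = list(removed_channels = drop_ch,
                     removed_components = art,
                     component_features = cls$features,
                     n_artifact_epochs = sum(apply(bad, 2, any)),
                     n_scan_epochs = ncol(bad)))
}

## Deterministic component classifier replacing visual inspection.
.classifyComponents <- function(fit, labels, fs, cfg) {
  nc <- ncol(fit$A)
  frontal <- intersect(cfg$ocular_channels, labels)
  feats <- data.frame(component = seq_len(nc), frontal_ratio = NA_real_,
                      lowfreq_frac = NA_real_, kurtosis = NA_real_,
                      highfreq_frac = NA_real_, rule = "ok",
                      stringsAsFactors = FALSE)
  n <- ncol(fit$S)
  fgrid <- (seq_len(n) - 1) / n * fs
  half <- fgrid <= fs / 2
  for (k in seq_len(nc)) {
    a <- abs(fit$A[, k])
    feats$frontal_ratio[k] <- if (length(frontal))
      mean(a[match(frontal, labels)]) / mean(a) else 0
    s <- fit$S[k, ]
    P <- Mod(stats::fft(s))^2
    tot <- sum(P[half][-1])
    feats$lowfreq_frac[k] <- sum(P[half & fgrid < 3 & fgrid > 0]) /
      max(tot, 1e-300)
    feats$highfreq_frac[k] <- sum(P[half & fgrid > 20]) / max(tot, 1e-300)
    feats$kurtosis[k] <- mean((s - mean(s))^4) / stats::var(s)^2 - 3
  }
  blink <- feats$frontal_ratio > cfg$ica_blink_topo &
    feats$lowfreq_frac > cfg$ica_lowfreq_frac
  transient <- feats$kurtosis > cfg$ica_kurt_thresh
  muscle <- feats$highfreq_frac > cfg$ica_muscle_frac
  feats$rule[muscle] <- "muscle"
  feats$rule[transient] <- "transient"
  feats$rule[blink] <- "blink"
  list(artifact = blink | transient | muscle, features = feats)
}

#' Segment a recording into event-locked epochs
#'
#' One epoch per event, time-locked to the Prompt-2 offset, covering
#' \code{[window[1] - pad, window[2] + pad)}. Events too close to a
#' recording edge are dropped and logged in attribute \code{"dropped"} of
#' the returned object's trial metadata.
#'
#' @param rec an \linkS4class{EegRecording}.
#' @param events event data.frame (defaults to the recording's valid
#'   trials, i.e. those without validity codes).
#' @param window experimental window in seconds, default \code{c(0, 2)}.
#' @param pad padding on each side in seconds, default 1.
#' @return an \linkS4class{EpochSet}.
#' @export
epochRecording <- function(rec, events = NULL, window = c(0, 2), pad = 1) {
  if (is.null(events))
    events <- filterValidTrials(eventTable(rec))$events
  if (nrow(events) == 0) stop("zero valid trials: nothing to epoch")
  fs <- rec@samplingRate
  npre <- round(pad * fs)
  npost <- round((window[2] + pad) * fs)
  len <- npre + npost
  nsamp <- ncol(rec@data)
  ok <- events$onset_sample - npre + 1 >= 1 &
    events$onset_sample + npost <= nsamp
  dropped <- events[!ok, , drop = FALSE]
  events <- events[ok, , drop = FALSE]
  if (nrow(events) == 0) stop("all events fall too close to an edge")
  arr <- array(0, dim = c(nrow(events), nrow(rec@data), len))
  for (i in seq_len(nrow(events))) {
    s0 <- events$onset_sample[i] - npre + 1
    arr[i, , ] <- rec@data[, s0 + seq_len(len) - 1]
  }
  meta <- events
  rownames(meta) <- NULL
  attr(meta, "dropped") <- dropped
  new("EpochSet", data = arr,
      times = (seq_len(len) - npre - 1) / fs,
      samplingRate = fs,
      channelLabels = rownames(rec@data),
      trialMeta = meta,
      interpLog = rep(list(character(0)), nrow(events)),
      rejected = rep(FALSE, nrow(events)))
}

#' Mark ocular-threshold violations on the frontal channel set
#'
#' Epochs in which any channel of the frontal set exceeds the ocular
#' voltage threshold get those frontal channels added to the epoch's
#' interpolation log. Only channels of the configured frontal set are ever
#' marked by this rule.
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param config a \code{\link{preprocConfig}}.
#' @return the \linkS4class{EpochSet} with updated interpolation log.
#' @export
ocularThresholdReject <- function(ep, config = preprocConfig()) {
  frontal <- intersect(config$ocular_channels, ep@channelLabels)
  if (length(frontal) == 0)
    stop("none of the configured frontal channels are present")
  fi <- match(frontal, ep@channelLabels)
  for (i in seq_len(dim(ep@data)[1])) {
    mx <- apply(abs(ep@data[i, fi, , drop = FALSE]), 2, max)
    hit <- frontal[mx > config$ocular_thresh]
    if (length(hit))
      ep@interpLog[[i]] <- union(ep@interpLog[[i]], hit)
  }
  ep
}

#' Interpolate flagged channels and prune over-artifacted epochs
#'
#' Per epoch, channels flagged in the interpolation log are replaced by
#' spherical-spline interpolation from the remaining channels. Epochs in
#' which more than \code{interp_frac} of channels are flagged are rejected
#' (strictly greater than: a fraction exactly at the boundary is kept), as
#' are epochs with fewer than 4 clean channels to interpolate from.
#'
#' @param ep an \linkS4class{EpochSet}.
#' @param montage an \linkS4class{EegMontage} covering the epoch channels.
#' @param interp_frac rejection boundary (default 0.10).
#' @param params \code{\link{csdParams}} controlling the spline.
#' @return the \linkS4class{EpochSet} with interpolated data and updated
#'   rejection flags; rejection reasons in attribute
#'   \code{"rejection_reasons"}.
#' @export
interpolateAndPrune <- function(ep, montage, interp_frac = 0.10,
                                params = csdParams()) {
  nchan <- length(ep@channelLabels)
  reasons <- character(dim(ep@data)[1])
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(dim(ep@data)[1])) {
    flagged <- intersect(ep@interpLog[[i]], ep@channelLabels)
    if (length(flagged) == 0) next
    if (length(flagged) / nchan > interp_frac) {
      ep@rejected[i] <- TRUE
      reasons[i] <- "interp_fraction_exceeded"
      next
    }
    good <- setdiff(ep@channelLabels, flagged)
    if (length(good) < 4) {
      ep@rejected[i] <- TRUE
      reasons[i] <- "too_few_good_channels"
      next
    }
    key <- paste(flagged, collapse = ",")
    M <- if (!is.null(cache[[key]])) cache[[key]]
    else cache[[key]] <- interpolationMatrix(montage, good, flagged,
                                            params)
    gi <- match(good, ep@channelLabels)
    bi <- match(flagged, ep@channelLabels)
    ep@data[i, bi, ] <- M %*% ep@data[i, gi, ]
  }
  attr(ep@rejected, "rejection_reasons") <- reasons
  ep
}

#' Re-reference epochs to the average of all electrodes
#'
#' Subtracts the across-channel mean at every sample; the output channel
#' mean is zero everywhere, and the operation is idempotent.
#'
#' @param ep an \linkS4class{EpochSet} with at least 2 channels.
#' @return the re-referenced \linkS4class{EpochSet}.
#' @export
averageReference <- function(ep) {
  if (dim(ep@data)[2] < 2) stop("need at least 2 channels")
  d <- dim(ep@data)
  for (i in seq_len(d[1])) {
    x <- matrix(ep@data[i, , ], d[2], d[3])
    ep@data[i, , ] <- x - rep(colMeans(x), each = nrow(x))
  }
  ep
}

#' Run the full preprocessing cascade on one recording
#'
#' Fixed stage order: band-pass filter, resample, outer-ring removal,
#' bad-channel removal, ICA cleanup, epoching of valid trials, ocular
#' threshold marking, spherical-spline interpolation with epoch pruning,
#' average reference. No stage modifies trial metadata beyond adding
#' flags and logs. Stages can be switched off for clean simulated data
#' (\code{run_filter}, \code{run_resample}, \code{run_ica},
#' \code{run_bad_channels}).
#'
#' @param rec an \linkS4class{EegRecording}.
#' @param montage the montage the recording was acquired on.
#' @param config a \code{\link{preprocConfig}}.
#' @param seed seed for the ICA stage.
#' @param run_filter,run_resample,run_bad_channels,run_ica stage toggles.
#' @return list: \code{epochs} (\linkS4class{EpochSet}), \code{montage}
#'   (restricted to surviving channels), \code{log} (per-stage entries of
#'   parameters and items removed).
#' @export
preprocessRecording <- function(rec, montage, config = preprocConfig(),
                                seed = 1L,
                                run_filter = TRUE, run_resample = TRUE,
                                run_bad_channels = TRUE, run_ica = TRUE) {
  log <- list()
  add <- function(stage, ...) log[[length(log) + 1]] <<-
    c(list(stage = stage), list(...))
  if (run_filter) {
    rec <- bandpassFir(rec, config$band[1], config$band[2])
    add("bandpass", band = config$band,
        order = attr(rec@data, "filter")$order)
  }
  if (run_resample && config$target_rate < rec@samplingRate) {
    rec <- resampleRecording(rec, config$target_rate)
    add("resample", target = config$target_rate)
  }
  n0 <- nrow(rec@data)
  rec <- removeOuterRing(rec, montage)
  add("outer_ring", removed = n0 - nrow(rec@data))
  if (run_bad_channels) {
    bad <- detectBadChannels(rec)
    if (length(bad))
      rec@data <- rec@data[setdiff(rownames(rec@data), bad), ,
                           drop = FALSE]
    add("bad_channels", removed = as.character(bad))
  }
  if (run_ica) {
    ica <- icaArtifactRemoval(rec, config, seed = seed)
    rec <- ica$recording
    add("ica", removed_channels = ica$report$removed_channels,
        removed_components = ica$report$removed_components)
  }
  ep <- epochRecording(rec, window = c(0, 2), pad = config$pad)
  add("epoch", n_epochs = dim(ep@data)[1],
      n_dropped_edge = nrow(attr(ep@trialMeta, "dropped")))
  if (length(intersect(config$ocular_channels, ep@channelLabels))) {
    ep <- ocularThresholdReject(ep, config)
    add("ocular", n_marked = sum(lengths(ep@interpLog) > 0))
  } else {
    add("ocular", skipped = "no frontal channels remain")
  }
  mon_now <- subsetMontage(montage, ep@channelLabels)
  ep <- interpolateAndPrune(ep, mon_now, config$interp_frac)
  add("interpolate", n_rejected = sum(ep@rejected))
  ep <- averageReference(ep)
  add("average_reference")
  list(epochs = ep, montage = subsetMontage(montage, ep@channelLabels),
       log = log)
}
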