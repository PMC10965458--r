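#' Trial types and validity codes
#'
#' The four trial types of the toy-passing task (two perspective-taking,
#' two control prompts) and the enumerated trial-validity codes derived
#' from video coding.
#'
#' @return character vector.
#' @export
trialTypes <- function() c("CanSee", "DoesNotSee", "Yellow", "NotYellow")

#' @rdname trialTypes
#' @export
validityCodes <- function() c("verbalized", "turned", "caregiver",
                              "experimenter_error")

#' @rdname trialTypes
#' @param types character vector of trial types.
#' @export
isPerspectiveTaking <- function(types) types %in% c("CanSee", "DoesNotSee")

## 1/f^chi noise via spectral shaping, per-channel target RMS (microvolts).
## Channels are processed in blocks to bound the FFT working memory.
.pinkNoise <- function(nsamp, nchan, chi, rms) {
  N <- stats::nextn(nsamp, c(2, 3, 5))
  m <- pmin(0:(N - 1), N - (0:(N - 1)))   # symmetric frequency index
  scale <- c(0, m[-1]^(-chi / 2))          # zero out DC
  out <- matrix(0, nchan, nsamp)
  blocks <- split(seq_len(nchan), ceiling(seq_len(nchan) / 32))
  for (b in blocks) {
    W <- matrix(stats::rnorm(N * length(b)), N, length(b))
    F <- stats::mvfft(W) * scale
    x <- Re(stats::mvfft(F, inverse = TRUE)) / N
    x <- x[seq_len(nsamp), , drop = FALSE]
    sds <- apply(x, 2, stats::sd)
    out[b, ] <- t(x) * (rms / sds)
  }
  out
}

## Ongoing alpha: per-channel random phase and a slow sinusoidal amplitude
## envelope; normalized to the target RMS.
.alphaOscillation <- function(nsamp, nchan, srate, freq, rms) {
  t <- seq_len(nsamp) / srate
  out <- matrix(0, nchan, nsamp)
  for (ch in seq_len(nchan)) {
    phi <- stats::runif(2, 0, 2 * pi)
    fm <- stats::runif(1, 0.05, 0.2)
    env <- 1 + 0.4 * sin(2 * pi * fm * t + phi[2])
    x <- env * sin(2 * pi * freq * t + phi[1])
    out[ch, ] <- x * (rms / stats::sd(x))
  }
  out
}

## Band-limited burst: superposition of random-phase sinusoids with
## frequencies drawn in the band, Hann-windowed, unit RMS over the window.
.bandBurst <- function(nsamp_window, srate, band) {
  t <- seq_len(nsamp_window) / srate
  f <- stats::runif(5, band[1], band[2])
  phi <- stats::runif(5, 0, 2 * pi)
  x <- rowSums(vapply(1:5, function(k) sin(2 * pi * f[k] * t + phi[k]),
                      numeric(nsamp_window)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = nsamp_window))
  x <- x * w
  x / sqrt(mean(x^2))
}

## Gaussian spatial gain profile around the centroid of a channel set.
.clusterGains <- function(montage, channels, sigma = 0.6) {
  pos <- electrodePositions(montage)
  ctr <- colMeans(pos[channels, , drop = FALSE])
  ctr <- ctr / sqrt(sum(ctr^2))
  ang <- acos(pmin(1, pmax(-1, pos[channels, , drop = FALSE] %*% ctr)))
  as.numeric(exp(-ang^2 / (2 * sigma^2)))
}

.truncPct <- function(x) pmin(100, pmax(0, x))

#' Simulate one participant's recording, events and behavior
#'
#' Continuous EEG = 1/f^chi background + ongoing alpha + condition-locked
#' band-limited bursts added on the effect-cluster channels during the
#' effect window of perspective-taking trials (Does-Not-See trials get an
#' extra \code{mismatch_boost} amplitude factor). Events mark the Prompt-2
#' offset of each trial (0-based sample index) with trial type and
#' validity codes; behavioral correctness is generated per trial from
#' latent condition accuracies, with Does-Not-See accuracy coupled to the
#' effect amplitude (see \code{\link{participantSpec}}).
#'
#' @param spec a \code{\link{participantSpec}}.
#' @param montage an \linkS4class{EegMontage}; only its channels are
#'   simulated.
#' @param sampling_rate Hz.
#' @param seed integer seed (fully determines the output).
#' @return list with elements \code{recording}
#'   (\linkS4class{EegRecording}), \code{events} (data.frame),
#'   \code{behavior} (data.frame: trial_index, correct) and \code{latent}
#'   (latent condition accuracies).
#' @export
simulateParticipant <- function(spec, montage, sampling_rate, seed) {
  validateParticipantSpec(spec)
  set.seed(seed)
  fs <- sampling_rate
  ntt <- spec$n_trials_per_type
  n_trials <- 4L * ntt
  lead <- 4; tail <- 4
  if (spec$iti_s < 2 + 2 * 1)
    stop("epoch window plus padding exceeds the inter-trial spacing")
  dur <- lead + (n_trials - 1) * spec$iti_s + tail
  nsamp <- round(dur * fs)
  labs <- channelLabels(montage)
  nchan <- length(labs)

  data <- .pinkNoise(nsamp, nchan, spec$chi, spec$background_rms) +
    .alphaOscillation(nsamp, nchan, fs, spec$alpha_freq, spec$alpha_rms)
  rownames(data) <- labs

  types <- sample(rep(trialTypes(), each = ntt))
  onset <- round((lead + (seq_len(n_trials) - 1) * spec$iti_s) * fs)

  ## condition-locked burst on perspective-taking trials
  eff_ch <- unique(unlist(lapply(
    intersect(spec$effect_clusters, names(montage@clusters)),
    function(cl) clusterChannels(montage, cl))))
  eff_ch <- intersect(eff_ch, labs)
  w0 <- round(spec$effect_window_s[1] * fs)
  wl <- max(2L, round(diff(spec$effect_window_s) * fs))
  if (length(eff_ch) && spec$effect_amplitude > 0) {
    gains <- .clusterGains(montage, eff_ch)
    for (i in which(isPerspectiveTaking(types))) {
      amp <- spec$effect_amplitude *
        (1 + if (types[i] == "DoesNotSee") spec$mismatch_boost else 0)
      burst <- amp * .bandBurst(wl, fs, spec$effect_band_hz)
      idx <- onset[i] + w0 + seq_len(wl)
      data[eff_ch, idx] <- data[eff_ch, idx] + outer(gains, burst)
    }
  }

  ## validity codes
  validity <- rep("", n_trials)
  inv <- stats::runif(n_trials) < spec$artifact_rates$invalid_trial_rate
  validity[inv] <- sample(validityCodes(), sum(inv), replace = TRUE)

  ## latent accuracies; Does-Not-See coupled to the effect amplitude
  bh <- spec$behavior; cp <- spec$coupling
  z <- if (cp$ref_sd > 0) (spec$effect_amplitude - cp$ref_mean) / cp$ref_sd
       else 0
  lat <- c(
    CanSee = .truncPct(stats::rnorm(1, bh$can_see_mean, bh$can_see_sd)),
    DoesNotSee = .truncPct(bh$does_not_see_mean +
                             cp$r * bh$does_not_see_sd * z +
                             sqrt(max(0, 1 - cp$r^2)) * bh$does_not_see_sd *
                             stats::rnorm(1)),
    Yellow = .truncPct(stats::rnorm(1, bh$control_mean, bh$control_sd)),
    NotYellow = .truncPct(stats::rnorm(1, bh$control_mean, bh$control_sd)))
  correct <- as.integer(stats::runif(n_trials) < lat[types] / 100)

  events <- data.frame(trial_index = seq_len(n_trials),
                       trial_type = types,
                       onset_sample = onset,
                       validity = validity,
                       correct = correct,
                       stringsAsFactors = FALSE)
  rec <- new("EegRecording", data = data, samplingRate = fs,
             events = events, participant = spec$participant_id)
  list(recording = rec,
       events = events,
       behavior = data.frame(trial_index = events$trial_index,
                             correct = correct),
       latent = lat)
}

#' Inject ocular, bad-channel and muscle artifacts into a recording
#'
#' Adds blink-shaped low-frequency transients maximal at frontal channels,
#' replaces randomly chosen channels with high-variance noise ("bad"
#' channels), and adds broadband 20-40 Hz muscle bursts. Returns the
#' modified copy together with a ground-truth log of what was injected
#' where; with all rates zero the recording is returned unchanged.
#'
#' @param recording an \linkS4class{EegRecording}.
#' @param artifact_rates list: \code{blinks_per_min},
#'   \code{n_bad_channels}, \code{muscle_bursts_per_min}.
#' @param seed integer seed.
#' @param montage montage supplying frontal topography for blinks.
#' @return list(recording = modified \linkS4class{EegRecording},
#'   log = list(blink_samples, bad_channels, muscle_samples,
#'   muscle_channels)).
#' @export
injectArtifacts <- function(recording, artifact_rates, seed,
                            montage = buildIdealizedMontage()) {
  rates <- utils::modifyList(list(blinks_per_min = 0, n_bad_channels = 0,
                                  muscle_bursts_per_min = 0),
                             artifact_rates)
  if (any(unlist(rates) < 0)) stop("artifact rates must be non-negative")
  log <- list(blink_samples = integer(0), bad_channels = character(0),
              muscle_samples = integer(0), muscle_channels = character(0))
  if (all(unlist(rates) == 0))
    return(list(recording = recording, log = log))
  set.seed(seed)
  data <- recording@data
  fs <- recording@samplingRate
  nsamp <- ncol(data)
  labs <- rownames(data)
  minutes <- nsamp / fs / 60

  ## blinks: 400-ms raised-cosine transients, frontal-dominant topography
  n_blinks <- stats::rpois(1, rates$blinks_per_min * minutes)
  if (n_blinks > 0) {
    pos <- electrodePositions(montage)[labs, , drop = FALSE]
    front <- c(0, 0.97, 0.05)
    ang <- acos(pmin(1, pmax(-1, pos %*% front)))
    gain <- as.numeric(exp(-ang^2 / (2 * 0.5^2)))
    bl <- round(0.4 * fs)
    shape <- 400 * (0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = bl)))
    starts <- sort(sample.int(nsamp - bl, n_blinks))
    for (s in starts)
      data[, s + seq_len(bl)] <- data[, s + seq_len(bl)] +
        outer(gain, shape)
    log$blink_samples <- starts
  }

  ## bad channels: replaced by high-variance white noise
  nb <- min(rates$n_bad_channels, nrow(data))
  if (nb > 0) {
    bad <- sample(labs, nb)
    base_sd <- stats::median(apply(data, 1, stats::sd))
    for (ch in bad)
      data[ch, ] <- stats::rnorm(nsamp, sd = 8 * base_sd)
    log$bad_channels <- bad
  }

  ## muscle bursts: 300-ms 20-40 Hz noise on a few random channels
  n_musc <- stats::rpois(1, rates$muscle_bursts_per_min * minutes)
  if (n_musc > 0) {
    ml <- round(0.3 * fs)
    mch <- sample(labs, min(5, length(labs)))
    starts <- sort(sample.int(nsamp - ml, n_musc))
    for (s in starts) {
      t <- seq_len(ml) / fs
      f <- stats::runif(4, 20, 40)
      phi <- stats::runif(4, 0, 2 * pi)
      x <- rowSums(vapply(1:4, function(k) sin(2 * pi * f[k] * t + phi[k]),
                          numeric(ml)))
      w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = ml))
      x <- 60 * x * w / sqrt(mean((x * w)^2))
      data[mch, s + seq_len(ml)] <- data[mch, s + seq_len(ml)] +
        matrix(x, length(mch), ml, byrow = TRUE)
    }
    log$muscle_samples <- starts
    log$muscle_channels <- mch
  }

  rec <- recording
  rec@data <- data
  list(recording = rec, log = log)
}

#' Simulate a cohort of participants
#'
#' Draws across-participant effect amplitudes from the cohort
#' distribution (normal, truncated at zero), derives one deterministic
#' seed per participant from the cohort seed, simulates each participant
#' and (when artifact rates are non-zero) injects artifacts. The
#' ground-truth table records each participant's true amplitude, latent
#' Does-Not-See accuracy and the injected band/window/clusters.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param montage montage to simulate on (default: full idealized
#'   128-channel montage; pass a \code{\link{subsetMontage}} for reduced
#'   simulation studies).
#' @return list of class \code{CohortDataset}: \code{participants} (each a
#'   \code{\link{simulateParticipant}} result plus \code{artifact_log}),
#'   \code{montage}, \code{ground_truth} (data.frame), \code{spec}.
#' @export
simulateCohort <- function(spec, montage = buildIdealizedMontage()) {
  validateCohortSpec(spec)
  set.seed(spec$seed)
  n <- spec$n_participants
  amps <- pmax(0, stats::rnorm(n, spec$amp_mean, spec$amp_sd))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  parts <- vector("list", n)
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    args <- utils::modifyList(
      spec$participant_args,
      list(participant_id = sprintf("sub-%03d", i),
           effect_amplitude = amps[i],
           coupling = utils::modifyList(
             list(ref_mean = spec$amp_mean, ref_sd = spec$amp_sd),
             if (is.null(spec$participant_args$coupling)) list()
             else spec$participant_args$coupling)))
    pspec <- do.call(participantSpec, args)
    sim <- simulateParticipant(pspec, montage, spec$sampling_rate,
                               seed = seeds[i])
    if (any(unlist(pspec$artifact_rates[c("blinks_per_min",
                                          "n_bad_channels",
                                          "muscle_bursts_per_min")]) > 0)) {
      inj <- injectArtifacts(sim$recording, pspec$artifact_rates,
                             seed = seeds[n + i], montage = montage)
      sim$recording <- inj$recording
      sim$artifact_log <- inj$log
    } else sim$artifact_log <- NULL
    sim$spec <- pspec
    parts[[i]] <- sim
    gt[[i]] <- data.frame(participant_id = pspec$participant_id,
                          effect_amplitude = amps[i],
                          dns_latent_accuracy = sim$latent[["DoesNotSee"]],
                          band_lo = pspec$effect_band_hz[1],
                          band_hi = pspec$effect_band_hz[2],
                          window_lo = pspec$effect_window_s[1],
                          window_hi = pspec$effect_window_s[2],
                          clusters = paste(pspec$effect_clusters,
                                           collapse = ";"))
  }
  out <- list(participants = parts, montage = montage,
              ground_truth = do.call(rbind, gt), spec = spec)
  class(out) <- "CohortDataset"
  out
}
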