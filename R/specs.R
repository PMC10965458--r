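#' Participant-level simulation specification
#'
#' Describes one simulated participant: trial counts, the condition-locked
#' narrow-band effect (band, time window, carrying clusters, amplitude),
#' artifact rates, the ongoing-background model, and the coupling between
#' the neural effect and behavioral accuracy.
#'
#' The injected effect is an amplitude-modulated band-limited burst added
#' on the effect-cluster channels during \code{effect_window_s} on
#' perspective-taking trials; Does-Not-See trials receive an extra
#' \code{mismatch_boost} amplitude factor. \code{effect_amplitude} is the
#' burst RMS in microvolts.
#'
#' Behavioral accuracy on Does-Not-See trials is coupled to the effect
#' amplitude: the latent percent-correct is
#' \code{mean + r * sd * z + sqrt(1 - r^2) * sd * noise}, where \code{z}
#' standardizes \code{effect_amplitude} against the cohort reference
#' distribution (\code{coupling$ref_mean}, \code{coupling$ref_sd}).
#' Per-trial correctness is Bernoulli with the (truncated) latent accuracy
#' as success probability.
#'
#' @param participant_id identifier.
#' @param n_trials_per_type trials per trial type (4 types; default 8, i.e.
#'   16 perspective-taking and 16 control trials).
#' @param effect_amplitude burst RMS in microvolts (default 8).
#' @param effect_band_hz frequency interval of the injected burst (Hz).
#' @param effect_window_s time interval of the burst within the 2-s epoch.
#' @param effect_clusters montage cluster names carrying the effect.
#' @param mismatch_boost extra amplitude factor on Does-Not-See trials.
#' @param artifact_rates list: \code{blinks_per_min},
#'   \code{n_bad_channels}, \code{muscle_bursts_per_min},
#'   \code{invalid_trial_rate}.
#' @param coupling list: \code{r} (population correlation between effect
#'   amplitude and Does-Not-See accuracy), \code{ref_mean}, \code{ref_sd}.
#' @param behavior list of latent accuracy means/SDs (percent) per
#'   condition: \code{can_see_mean/sd}, \code{does_not_see_mean/sd},
#'   \code{control_mean/sd}.
#' @param background_rms RMS of the 1/f background, microvolts.
#' @param chi spectral exponent of the 1/f^chi background.
#' @param alpha_freq,alpha_rms ongoing alpha frequency (Hz) and RMS (uV).
#' @param iti_s inter-trial interval, seconds (trial pacing is a design
#'   choice of the generator; long enough for a 2-s epoch plus padding).
#' @return a validated list of class \code{ParticipantSpec}.
#' @export
participantSpec <- function(participant_id = "sub-001",
                            n_trials_per_type = 8L,
                            effect_amplitude = 8,
                            effect_band_hz = c(6.2, 7.7),
                            effect_window_s = c(1.368, 1.466),
                            effect_clusters = "right_tp",
                            mismatch_boost = 0.3,
                            artifact_rates = list(),
                            coupling = list(),
                            behavior = list(),
                            background_rms = 15,
                            chi = 1,
                            alpha_freq = 8.7,
                            alpha_rms = 6,
                            iti_s = 6) {
  ar <- utils::modifyList(list(blinks_per_min = 0, n_bad_channels = 0,
                               muscle_bursts_per_min = 0,
                               invalid_trial_rate = 0),
                          artifact_rates)
  cp <- utils::modifyList(list(r = 0.35, ref_mean = 8, ref_sd = 3),
                          coupling)
  bh <- utils::modifyList(list(can_see_mean = 82.61, can_see_sd = 21.18,
                               does_not_see_mean = 76.26,
                               does_not_see_sd = 25.77,
                               control_mean = 88.40, control_sd = 17.41),
                          behavior)
  spec <- list(participant_id = as.character(participant_id),
               n_trials_per_type = as.integer(n_trials_per_type),
               effect_amplitude = effect_amplitude,
               effect_band_hz = effect_band_hz,
               effect_window_s = effect_window_s,
               effect_clusters = effect_clusters,
               mismatch_boost = mismatch_boost,
               artifact_rates = ar,
               coupling = cp,
               behavior = bh,
               background_rms = background_rms,
               chi = chi,
               alpha_freq = alpha_freq,
               alpha_rms = alpha_rms,
               iti_s = iti_s)
  class(spec) <- "ParticipantSpec"
  validateParticipantSpec(spec)
  spec
}

#' @rdname participantSpec
#' @param spec a ParticipantSpec.
#' @export
validateParticipantSpec <- function(spec) {
  stopifnot(inherits(spec, "ParticipantSpec"))
  if (spec$n_trials_per_type < 1L)
    stop("n_trials_per_type must be >= 1")
  if (spec$effect_band_hz[1] < 3 || spec$effect_band_hz[2] > 30 ||
      diff(spec$effect_band_hz) < 0)
    stop("effect_band_hz must be an ascending interval within [3, 30] Hz")
  if (spec$effect_window_s[1] < 0 || spec$effect_window_s[2] > 2 ||
      diff(spec$effect_window_s) <= 0)
    stop("effect_window_s must be an ascending interval within [0, 2] s")
  if (any(unlist(spec$artifact_rates) < 0))
    stop("artifact rates must be non-negative")
  if (spec$effect_amplitude < 0)
    stop("effect_amplitude must be non-negative")
  if (abs(spec$coupling$r) > 1)
    stop("coupling r must lie in [-1, 1]")
  if (spec$iti_s < 4)
    stop("inter-trial interval too short for a 2-s epoch plus 1-s padding")
  invisible(TRUE)
}

#' Cohort-level simulation specification
#'
#' @param n_participants number of participants (default 46, the size of
#'   the analytic cohort the analysis is designed for).
#' @param amp_mean,amp_sd across-participant mean and SD of
#'   \code{effect_amplitude} (microvolts RMS; draws truncated at 0).
#' @param sampling_rate acquisition rate in Hz (default 1000).
#' @param seed integer seed; all per-participant seeds derive from it.
#' @param participant_args list of overrides passed to
#'   \code{\link{participantSpec}} for every participant.
#' @return a validated list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(n_participants = 46L,
                       amp_mean = 8, amp_sd = 3,
                       sampling_rate = 1000,
                       seed = 1L,
                       participant_args = list()) {
  spec <- list(n_participants = as.integer(n_participants),
               amp_mean = amp_mean, amp_sd = amp_sd,
               sampling_rate = sampling_rate,
               seed = as.integer(seed),
               participant_args = participant_args)
  class(spec) <- "CohortSpec"
  validateCohortSpec(spec)
  spec
}

#' @rdname cohortSpec
#' @param spec a CohortSpec.
#' @export
validateCohortSpec <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (spec$n_participants < 1L)
    stop("n_participants must be >= 1")
  if (spec$amp_sd < 0)
    stop("amp_sd must be non-negative")
  ## highest simulated frequency: alpha, effect band, or 40 Hz muscle noise
  p <- do.call(participantSpec, spec$participant_args)
  fmax <- max(p$alpha_freq, p$effect_band_hz[2],
              if (p$artifact_rates$muscle_bursts_per_min > 0) 40 else 0)
  if (spec$sampling_rate <= 2 * fmax)
    stop("sampling_rate must exceed twice the highest simulated frequency")
  invisible(TRUE)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' The file mirrors the \code{\link{cohortSpec}} /
#' \code{\link{participantSpec}} fields: top-level cohort fields plus an
#' optional \code{participant} block of overrides.
#'
#' @param path path to a .yaml/.yml/.json file.
#' @return a \code{CohortSpec}.
#' @export
readCohortConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  pa <- cfg$participant
  cfg$participant <- NULL
  do.call(cohortSpec, c(cfg, if (!is.null(pa))
    list(participant_args = pa) else NULL))
}
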