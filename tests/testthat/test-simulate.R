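## direct periodogram band power, the independent oracle used against the
## wavelet/permutation machinery
bandPower <- function(x, fs, band) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) / n * fs
  mean(P[f >= band[1] & f <= band[2]])
}

test_that("simulation is deterministic given spec and seed", {
  mon <- clusterMontage()
  spec <- participantSpec(n_trials_per_type = 2, iti_s = 5)
  a <- simulateParticipant(spec, mon, 100, seed = 42)
  b <- simulateParticipant(spec, mon, 100, seed = 42)
  expect_identical(a, b)
  c <- simulateParticipant(spec, mon, 100, seed = 43)
  expect_false(identical(eegData(a$recording), eegData(c$recording)))
})

test_that("spec validation enforces the stated invariants", {
  expect_error(participantSpec(n_trials_per_type = 0), ">= 1")
  expect_error(participantSpec(effect_band_hz = c(2, 7)), "\\[3, 30\\]")
  expect_error(participantSpec(effect_window_s = c(1.5, 2.5)), "\\[0, 2\\]")
  expect_error(participantSpec(artifact_rates = list(blinks_per_min = -1)),
               "non-negative")
  expect_error(cohortSpec(sampling_rate = 15), "twice the highest")
})

test_that("injected bursts raise perspective-taking band power", {
  mon <- clusterMontage()
  fs <- 100
  spec <- participantSpec(effect_amplitude = 16, mismatch_boost = 0,
                          n_trials_per_type = 4, iti_s = 5)
  sim <- simulateParticipant(spec, mon, fs, seed = 7)
  ev <- sim$events
  ch <- clusterChannels(mon, "right_tp")[1:3]
  w0 <- spec$effect_window_s
  pw <- function(types) {
    rows <- ev[ev$trial_type %in% types, ]
    # half-second window straddling the burst; long enough for the
    # periodogram to resolve the 5-9 Hz band
    idx0 <- round((mean(w0) - 0.25) * fs) + seq_len(round(0.5 * fs))
    mean(vapply(seq_len(nrow(rows)), function(i) {
      idx <- rows$onset_sample[i] + idx0
      mean(vapply(ch, function(cc)
        bandPower(eegData(sim$recording)[cc, idx], fs, c(5, 9)),
        numeric(1)))
    }, numeric(1)))
  }
  expect_gt(pw(c("CanSee", "DoesNotSee")), pw(c("Yellow", "NotYellow")))
})

test_that("amplitude zero leaves trial types spectrally exchangeable", {
  mon <- subsetMontage(clusterMontage(),
                       clusterChannels(clusterMontage(), "right_tp")[1:2])
  fs <- 50
  diffs <- vapply(1:20, function(s) {
    spec <- participantSpec(effect_amplitude = 0, n_trials_per_type = 4,
                            iti_s = 5)
    sim <- simulateParticipant(spec, mon, fs, seed = 1000 + s)
    ev <- sim$events
    one <- function(types) {
      rows <- ev[ev$trial_type %in% types, ]
      mean(vapply(seq_len(nrow(rows)), function(i) {
        idx <- rows$onset_sample[i] + seq_len(2 * fs)
        bandPower(eegData(sim$recording)[1, idx], fs, c(6, 8))
      }, numeric(1)))
    }
    a <- one(c("CanSee", "DoesNotSee")); b <- one(c("Yellow", "NotYellow"))
    (a - b) / (a + b)
  }, numeric(1))
  ## package permutation test on the per-seed normalized differences:
  ## no injected effect => null should not be rejected at the 1% level
  sr <- permutationTestVsZero(matrix(diffs, ncol = 1), n_perm = 2000,
                              seed = 5)
  expect_gt(pValues(sr)[1, 1], 0.01)
})

test_that("artifact injection honours rates and leaves a ground truth", {
  mon <- buildIdealizedMontage()
  spec <- participantSpec(n_trials_per_type = 1, iti_s = 5)
  sim <- simulateParticipant(spec, mon, 100, seed = 3)
  none <- injectArtifacts(sim$recording, list(), seed = 1, montage = mon)
  expect_identical(eegData(none$recording), eegData(sim$recording))

  inj <- injectArtifacts(sim$recording,
                         list(blinks_per_min = 8, n_bad_channels = 1,
                              muscle_bursts_per_min = 4),
                         seed = 9, montage = mon)
  log <- inj$log
  expect_length(log$bad_channels, 1)
  v <- apply(eegData(inj$recording), 1, var)
  expect_gt(v[log$bad_channels], median(v))
  # blink transients exceed +/-250 uV on at least one frontal channel
  expect_gt(length(log$blink_samples), 0)
  frontal <- intersect(ocularChannels(), rownames(eegData(inj$recording)))
  expect_gt(max(abs(eegData(inj$recording)[frontal, ])), 250)
})

test_that("cohorts have derived seeds, stated size and amplitude spread", {
  mon <- subsetMontage(clusterMontage(),
                       clusterChannels(clusterMontage(), "right_tp")[1:2])
  cs <- cohortSpec(n_participants = 5, sampling_rate = 50, seed = 11,
                   participant_args = list(n_trials_per_type = 1,
                                           iti_s = 5))
  d1 <- simulateCohort(cs, montage = mon)
  expect_length(d1$participants, 5)
  expect_identical(d1, simulateCohort(cs, montage = mon))
  expect_equal(nrow(d1$ground_truth), 5)

  cs0 <- cohortSpec(n_participants = 4, amp_sd = 0, sampling_rate = 50,
                    seed = 2,
                    participant_args = list(n_trials_per_type = 1,
                                            iti_s = 5))
  d0 <- simulateCohort(cs0, montage = mon)
  expect_equal(var(d0$ground_truth$effect_amplitude), 0)
})

test_that("behavioral coupling carries the configured sign and size", {
  mon <- subsetMontage(clusterMontage(),
                       clusterChannels(clusterMontage(), "right_tp")[1:2])
  cs <- cohortSpec(n_participants = 300, sampling_rate = 50, seed = 4,
                   participant_args = list(n_trials_per_type = 1,
                                           iti_s = 5))
  d <- simulateCohort(cs, montage = mon)
  gt <- d$ground_truth
  r <- cor(gt$effect_amplitude, gt$dns_latent_accuracy)
  expect_gt(r, 0.2)
  expect_lt(r, 0.5)
})

test_that("invalid-trial rate zero yields no validity codes", {
  mon <- clusterMontage()
  sim <- simulateParticipant(participantSpec(n_trials_per_type = 2,
                                             iti_s = 5), mon, 100,
                             seed = 6)
  expect_true(all(sim$events$validity == ""))
  simr <- simulateParticipant(
    participantSpec(n_trials_per_type = 8, iti_s = 5,
                    artifact_rates = list(invalid_trial_rate = 0.5)),
    mon, 100, seed = 6)
  expect_gt(sum(simr$events$validity != ""), 0)
  expect_true(all(simr$events$validity[simr$events$validity != ""] %in%
                    validityCodes()))
})
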