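makeRecording <- function(data, fs, events = NULL, id = "sub-001") {
  if (is.null(events))
    events <- data.frame(trial_index = integer(0),
                         trial_type = character(0),
                         onset_sample = integer(0),
                         validity = character(0), correct = integer(0))
  new("EegRecording", data = data, samplingRate = fs, events = events,
      participant = id)
}

test_that("FIR design meets its pass- and stop-band specification", {
  des <- designBandpassFir(0.3, 50, 1000)
  # frequency-response oracle at the probe frequencies
  expect_lt(abs(firResponse(des, 10, 1000) - 1), 0.05)
  expect_lt(firResponse(des, 60, 1000), 10^(-20 / 20))
  expect_lt(firResponse(des, 0, 1000), 0.05)
})

test_that("band-pass filtering matches its own frequency response", {
  fs <- 500
  t <- seq_len(15 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  rec <- makeRecording(rbind(E1 = x, E2 = x), fs)
  out <- bandpassFir(rec, 0.3, 50)
  mid <- (6 * fs):(9 * fs)
  amp <- max(abs(eegData(out)[1, mid]))
  expect_lt(abs(amp - 1), 0.05)
  # DC is in the stopband
  recdc <- makeRecording(rbind(E1 = rep(1, 15 * fs)), fs)
  outdc <- bandpassFir(recdc, 0.3, 50)
  expect_lt(max(abs(eegData(outdc)[1, mid])), 0.05)
  # too-short signals are refused
  short <- makeRecording(rbind(E1 = rnorm(100)), fs)
  expect_error(bandpassFir(short, 0.3, 50), "shorter than the filter")
})

test_that("resampling halves lengths, keeps peaks, rescales events", {
  fs <- 1000
  n <- 4001
  t <- seq_len(n) / fs
  ev <- data.frame(trial_index = 1L, trial_type = "CanSee",
                   onset_sample = 1000L, validity = "", correct = 1L)
  rec <- makeRecording(rbind(E1 = sin(2 * pi * 7 * t)), fs, ev)
  out <- resampleRecording(rec, 500)
  expect_equal(ncol(eegData(out)), ceiling(n / 2))
  expect_equal(eventTable(out)$onset_sample, 500L)
  expect_equal(samplingRate(out), 500)
  # dominant periodogram peak stays at 7 Hz
  y <- eegData(out)[1, ]
  P <- Mod(fft(y))^2
  f <- (seq_along(y) - 1) / length(y) * 500
  keep <- f > 0 & f <= 250
  expect_lt(abs(f[keep][which.max(P[keep])] - 7), 0.5)
  expect_error(resampleRecording(out, 500), "below the current rate")
})

test_that("outer-ring removal keeps 104 channels and is idempotent", {
  mon <- buildIdealizedMontage()
  data <- matrix(rnorm(128 * 100), 128,
                 dimnames = list(channelLabels(mon), NULL))
  rec <- makeRecording(data, 100)
  out <- removeOuterRing(rec, mon)
  expect_equal(nrow(eegData(out)), 104)
  expect_false(any(clusterChannels(mon, "outer_ring") %in%
                     rownames(eegData(out))))
  # order of the survivors is preserved
  expect_identical(rownames(eegData(out)),
                   setdiff(rownames(data),
                           clusterChannels(mon, "outer_ring")))
  expect_identical(removeOuterRing(out, mon), out)
  # partial overlap warns and removes the rest
  rec23 <- makeRecording(data[-match("E17", rownames(data)), ], 100)
  expect_warning(out23 <- removeOuterRing(rec23, mon), "23")
  expect_equal(nrow(eegData(out23)), 104)
})

test_that("bad-channel features flag variance outliers, spare copies", {
  set.seed(31)
  fs <- 100
  n <- 30 * fs
  data <- matrix(rnorm(20 * n), 20,
                 dimnames = list(paste0("E", 1:20), NULL))
  data["E5", ] <- 10 * rnorm(n)
  rec <- makeRecording(data, fs)
  bad <- detectBadChannels(rec)
  expect_true("E5" %in% bad)
  # near-duplicate of another channel: high correlation is no criterion
  data2 <- matrix(rnorm(20 * n), 20,
                  dimnames = list(paste0("E", 1:20), NULL))
  data2["E7", ] <- data2["E8", ] + 0.01 * rnorm(n)
  bad2 <- detectBadChannels(makeRecording(data2, fs))
  expect_false("E7" %in% bad2)
  expect_error(detectBadChannels(makeRecording(data[1:4, ], fs)),
               "at least 8")
})

test_that("false-positive rate on homogeneous channels is small", {
  fs <- 100
  rates <- vapply(1:5, function(s) {
    set.seed(400 + s)
    data <- matrix(rnorm(20 * 20 * fs), 20,
                   dimnames = list(paste0("E", 1:20), NULL))
    length(detectBadChannels(makeRecording(data, fs))) / 20
  }, numeric(1))
  expect_lt(mean(rates), 0.15)
})

test_that("epoch scan applies the voltage and dB rules at their printed boundaries", {
  cfg <- preprocConfig()
  fs <- 100
  n_ep <- 10
  data <- matrix(rnorm(3 * n_ep * fs), 3,
                 dimnames = list(c("E1", "E2", "E3"), NULL))
  # blink-like slow transients on a noise floor, rescaled to peak exactly
  # at / just beyond +/-1000 uV, so only the voltage rule is probed
  blink <- 900 * (0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = 30)))
  peak_at <- function(x, v) {           # rescale, pin the peak exactly
    x <- x * (v / max(abs(x)))
    i <- which.max(abs(x))
    x[i] <- sign(x[i]) * v
    x
  }
  e2 <- rnorm(fs); e2[36 + seq_along(blink)] <- e2[36 + seq_along(blink)] + blink
  data["E2", seq_len(fs)] <- peak_at(e2, 1000)
  e3 <- rnorm(fs); e3[36 + seq_along(blink)] <- e3[36 + seq_along(blink)] + blink
  data["E3", fs + seq_len(fs)] <- peak_at(e3, 1001)
  bad <- thetapt:::.epochArtifactScan(data, fs, cfg)
  expect_false(bad["E2", 1])
  expect_true(bad["E3", 2])
  # 20-40 Hz band power above 30 dB trips the spectral rule
  t <- seq_len(fs) / fs
  data["E1", (2 * fs) + seq_len(fs)] <- 400 * sin(2 * pi * 30 * t)
  bad <- thetapt:::.epochArtifactScan(data, fs, cfg)
  expect_true(bad["E1", 3])
})

test_that("channels beyond the 20% artifacted-epoch rule are removed", {
  set.seed(17)
  fs <- 100
  n_ep <- 20
  labs <- paste0("E", 1:10)
  data <- matrix(rnorm(10 * n_ep * fs), 10, dimnames = list(labs, NULL))
  # E4 artifacted in 30% of epochs (> 20%: removed);
  # E6 in exactly 20% (kept)
  for (e in 1:6) data["E4", (e - 1) * fs + 3] <- 2000
  for (e in 1:4) data["E6", (e - 1) * fs + 3] <- 2000
  rec <- makeRecording(data, fs)
  out <- suppressWarnings(icaArtifactRemoval(rec, preprocConfig(),
                                             seed = 2))
  expect_true("E4" %in% out$report$removed_channels)
  expect_false("E6" %in% out$report$removed_channels)
  expect_false("E4" %in% rownames(eegData(out$recording)))
})

test_that("ICA cleanup attenuates injected blinks on frontal channels", {
  mon <- buildIdealizedMontage()
  keep <- c(ocularChannels()[1:6], clusterChannels(mon, "right_tp"),
            clusterChannels(mon, "midfrontal"))
  monk <- subsetMontage(mon, keep)
  spec <- participantSpec(n_trials_per_type = 1, iti_s = 5)
  sim <- simulateParticipant(spec, monk, 100, seed = 8)
  inj <- injectArtifacts(sim$recording, list(blinks_per_min = 10),
                         seed = 12, montage = mon)
  frontal <- intersect(ocularChannels(), rownames(eegData(inj$recording)))
  pre <- max(abs(eegData(inj$recording)[frontal, ]))
  out <- suppressWarnings(icaArtifactRemoval(inj$recording,
                                             preprocConfig(), seed = 3))
  fr2 <- intersect(frontal, rownames(eegData(out$recording)))
  post <- max(abs(eegData(out$recording)[fr2, ]))
  expect_gt(length(out$report$removed_components), 0)
  expect_lt(post, pre)
})

test_that("clean recordings lose at most about one component", {
  mon <- clusterMontage()
  ns <- vapply(1:3, function(s) {
    sim <- simulateParticipant(participantSpec(n_trials_per_type = 1,
                                               iti_s = 5),
                               mon, 100, seed = 600 + s)
    out <- suppressWarnings(icaArtifactRemoval(sim$recording,
                                               preprocConfig(),
                                               seed = s))
    length(out$report$removed_components)
  }, numeric(1))
  expect_lte(mean(ns), 1)
})

test_that("epoching is prompt-locked with padding and edge logging", {
  fs <- 100
  n <- 40 * fs
  ev <- data.frame(trial_index = 1:3,
                   trial_type = c("CanSee", "Yellow", "NotYellow"),
                   onset_sample = c(500L, 1500L, n - 50L),
                   validity = "", correct = 1L)
  rec <- makeRecording(matrix(rnorm(2 * n), 2,
                              dimnames = list(c("E1", "E2"), NULL)),
                       fs, ev)
  ep <- epochRecording(rec, window = c(0, 2), pad = 1)
  expect_equal(dim(eegData(ep))[1], 2)      # third trial lost to the edge
  expect_equal(dim(eegData(ep))[3], (2 + 2 * 1) * fs)
  expect_equal(nrow(attr(trialMeta(ep), "dropped")), 1)
  expect_equal(range(epochTimes(ep)), c(-1, 2 + 1 - 1 / fs))
  # time zero sits exactly on the event sample
  i0 <- which(abs(epochTimes(ep)) < 1e-9)
  expect_equal(eegData(ep)[1, 1, i0], as.numeric(eegData(rec)[1, 501]))
  # a 32-trial session with all trials valid yields 32 epochs
  ev32 <- data.frame(trial_index = 1:32, trial_type = rep(trialTypes(), 8),
                     onset_sample = as.integer(seq(500, by = 500,
                                                   length.out = 32)),
                     validity = "", correct = 1L)
  n2 <- max(ev32$onset_sample) + 400
  rec32 <- makeRecording(matrix(rnorm(n2), 1, dimnames = list("E1", NULL)),
                         fs, ev32)
  expect_equal(dim(eegData(epochRecording(rec32)))[1], 32)
  ev0 <- ev; ev0$validity <- "verbalized"
  rec0 <- makeRecording(eegData(rec), fs, ev0)
  expect_error(epochRecording(rec0), "zero valid trials")
})

test_that("ocular rule marks only frontal channels beyond 250 uV", {
  fs <- 100
  mk <- function() matrix(rnorm(3 * 400), 3,
                          dimnames = list(c("E8", "E30", "E90"), NULL))
  m1 <- mk(); m1["E8", 150] <- 300
  m2 <- mk()
  m3 <- mk(); m3["E90", 150] <- 400
  ep <- makeEpochs(list(m1, m2, m3), fs)
  out <- ocularThresholdReject(ep, preprocConfig())
  expect_identical(interpolationLog(out)[[1]], "E8")
  expect_identical(interpolationLog(out)[[2]], character(0))
  expect_identical(interpolationLog(out)[[3]], character(0))
  ep2 <- makeEpochs(list(mk()), fs, labels = c("X1", "X2", "X3"))
  expect_error(ocularThresholdReject(ep2), "frontal channels")
})

test_that("interpolation boundary is strict and reconstruction accurate", {
  mon <- fibMontage(100)
  pos <- electrodePositions(mon)
  field <- pos[, 1] * pos[, 3] + 0.5 * pos[, 2]   # smooth dipolar-like
  fs <- 10
  m <- matrix(rep(field, 5), 100, 5,
              dimnames = list(channelLabels(mon), NULL))
  ep <- makeEpochs(list(m, m), fs)
  # 11 of 100 flagged: rejected (strictly more than 10%)
  ep@interpLog[[1]] <- channelLabels(mon)[1:11]
  # 10 of 100 flagged: interpolated and kept
  ep@interpLog[[2]] <- channelLabels(mon)[1:10]
  out <- interpolateAndPrune(ep, mon, interp_frac = 0.10)
  expect_true(rejectedEpochs(out)[1])
  expect_false(rejectedEpochs(out)[2])
  got <- eegData(out)[2, 1:10, 1]
  expect_lt(sqrt(mean((got - field[1:10])^2)) / sqrt(mean(field^2)), 0.10)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  ep <- makeEpochs(list(matrix(rnorm(12), 3, 4,
                               dimnames = list(c("A", "B", "C"), NULL))),
                   10, labels = c("A", "B", "C"))
  out <- averageReference(ep)
  expect_equal(max(abs(colSums(eegData(out)[1, , ]))), 0,
               tolerance = 1e-12)
  expect_equal(eegData(averageReference(out)), eegData(out),
               tolerance = 1e-12)
  two <- makeEpochs(list(matrix(c(1, -1), 2, 1)), 10,
                    labels = c("A", "B"))
  expect_equal(eegData(averageReference(two)), eegData(two))
})

test_that("artifact-free recordings keep nearly all epochs end to end", {
  mon <- buildIdealizedMontage()
  surv <- vapply(1:2, function(s) {
    sim <- simulateParticipant(participantSpec(n_trials_per_type = 2,
                                               iti_s = 5),
                               mon, 250, seed = 900 + s)
    pp <- suppressWarnings(
      preprocessRecording(sim$recording, mon,
                          preprocConfig(target_rate = 125), seed = s))
    mean(!rejectedEpochs(pp$epochs))
  }, numeric(1))
  expect_gte(mean(surv), 0.95)
})
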