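## Shared small fixtures, built in code.

# full-sphere Fibonacci montage for spline oracles (no hemisphere boundary)
fibMontage <- function(n = 96) {
  k <- seq_len(n)
  z <- -1 + (2 * k - 1) / n
  th <- pi * (3 - sqrt(5)) * k
  r <- sqrt(pmax(0, 1 - z^2))
  eegMontage(paste0("C", k), cbind(r * cos(th), r * sin(th), z))
}

# minimal EpochSet around given per-trial channel x sample matrices
makeEpochs <- function(mats, fs, times = NULL,
                       trial_type = rep("CanSee", length(mats)),
                       labels = rownames(mats[[1]])) {
  nsamp <- ncol(mats[[1]])
  if (is.null(times)) times <- (seq_len(nsamp) - 1) / fs
  arr <- array(0, dim = c(length(mats), nrow(mats[[1]]), nsamp))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  new("EpochSet", data = arr, times = times, samplingRate = fs,
      channelLabels = labels,
      trialMeta = data.frame(trial_index = seq_along(mats),
                             trial_type = trial_type,
                             onset_sample = 0L,
                             validity = "",
                             correct = 1L),
      interpLog = rep(list(character(0)), length(mats)),
      rejected = rep(FALSE, length(mats)))
}

# small clean participant on the cluster channels only (fast to simulate)
clusterMontage <- function() {
  mon <- buildIdealizedMontage()
  keep <- unique(unlist(lapply(c("midfrontal", "left_tp", "right_tp"),
                               clusterChannels, x = mon)))
  subsetMontage(mon, keep)
}

# ClusterPowerMap from a plain matrix
makePowerMap <- function(m, freqs = seq_len(nrow(m)),
                         times = seq_len(ncol(m)), condition = "PT",
                         cluster = "right_tp", participant = "sub-001") {
  new("ClusterPowerMap", power = m, freqs = freqs, times = times,
      participant = participant, condition = condition, cluster = cluster)
}

# DiffMap from a plain matrix
makeDiffMap <- function(D, freqs = seq_len(nrow(D)),
                        times = seq_len(ncol(D)),
                        participant = "sub-001",
                        contrast = "PTvsControl", cluster = "right_tp") {
  new("DiffMap", D = D, freqs = freqs, times = times,
      participant = participant, contrast = contrast, cluster = cluster)
}
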