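## BrainVision (.vhdr/.vmrk/.eeg) writer/reader. The canonical on-disk
## dialect of this package is BrainVision with IEEE float32 multiplexed
## data in microvolts; the reader additionally accepts INT_16 with a
## per-channel resolution.

.writeBrainVision <- function(rec, base) {
  labs <- rownames(rec@data)
  vhdr <- paste0(base, ".vhdr")
  vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  si <- 1e6 / rec@samplingRate
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", length(labs)),
    sprintf("SamplingInterval=%.6f", si),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(labs), labs))
  writeLines(lines, vhdr, useBytes = TRUE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          "Codepage=UTF-8",
          paste0("DataFile=", basename(eeg)),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0,00000000000000000000")
  ev <- rec@events
  if (nrow(ev))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(ev)) + 1,
                        ev$trial_type, ev$onset_sample + 1L))
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec@data), con, size = 4, endian = "little")
  invisible(c(vhdr = vhdr, vmrk = vmrk, eeg = eeg))
}

.parseIni <- function(lines) {
  out <- list()
  sec <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (grepl("^\\[", ln)) {
      sec <- gsub("^\\[|\\]$", "", trimws(ln))
      out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(sec)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[sec]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

.readBrainVision <- function(vhdr_path, participant = "") {
  ini <- .parseIni(readLines(vhdr_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  nchan <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  fmt <- ini[["Binary Infos"]]$BinaryFormat
  chinfo <- ini[["Channel Infos"]]
  labs <- character(nchan)
  res <- rep(1, nchan)
  for (k in seq_len(nchan)) {
    parts <- strsplit(chinfo[[paste0("Ch", k)]], ",")[[1]]
    labs[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      res[k] <- as.numeric(parts[3])
  }
  eeg_path <- file.path(dirname(vhdr_path), ci$DataFile)
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw <- readBin(con, numeric(), n = sz / 4, size = 4,
                   endian = "little")
  } else if (identical(fmt, "INT_16")) {
    raw <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                   endian = "little") * rep(res, length.out = sz / 2)
  } else stop("unsupported BinaryFormat: ", fmt)
  data <- matrix(raw, nrow = nchan)
  rownames(data) <- labs
  new("EegRecording", data = data, samplingRate = fs,
      events = data.frame(trial_index = integer(0),
                          trial_type = character(0),
                          onset_sample = integer(0),
                          validity = character(0),
                          correct = integer(0)),
      participant = participant)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
}

.readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                    stringsAsFactors = FALSE)
}

#' Write a cohort dataset in a BIDS-style layout
#'
#' One directory per participant:
#' \code{sub-XXX/eeg/sub-XXX_task-toypass_eeg.\{vhdr,vmrk,eeg\}} (raw
#' BrainVision, microvolts), \code{_events.tsv} (onset, duration, sample,
#' trial_index, trial_type, validity), \code{_eeg.json} (sampling
#' frequency sidecar), \code{_channels.tsv}, and
#' \code{sub-XXX/beh/sub-XXX_task-toypass_beh.tsv} (trial_index,
#' correct). Behavioral correctness lives in its own file, mirroring
#' separate video coding. The montage (labels, positions, clusters) is
#' written to \code{montage.json} at the root, the ground-truth table (if
#' any) to \code{ground_truth.tsv}.
#'
#' @param dataset a \code{CohortDataset} from \code{\link{simulateCohort}}
#'   or \code{\link{readDataset}}.
#' @param root output directory (created if needed).
#' @return invisibly, a manifest data.frame of participants and paths.
#' @export
writeDataset <- function(dataset, root) {
  if (length(dataset$participants) == 0)
    return(invisible(data.frame(participant = character(0),
                                path = character(0))))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) stop("cannot create output directory: ", root)
  mon <- dataset$montage
  jsonlite::write_json(
    list(labels = channelLabels(mon),
         positions = unname(electrodePositions(mon)),
         clusters = mon@clusters),
    file.path(root, "montage.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(dataset$ground_truth))
    .writeTsv(dataset$ground_truth, file.path(root, "ground_truth.tsv"))
  rows <- lapply(dataset$participants, function(p) {
    id <- p$recording@participant
    eegdir <- file.path(root, id, "eeg")
    behdir <- file.path(root, id, "beh")
    dir.create(eegdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(behdir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(eegdir, paste0(id, "_task-toypass_eeg"))
    .writeBrainVision(p$recording, base)
    fs <- p$recording@samplingRate
    jsonlite::write_json(list(SamplingFrequency = fs,
                              EEGReference = "Cz",
                              PowerLineFrequency = 60),
                         paste0(base, ".json"), auto_unbox = TRUE,
                         digits = NA)
    ev <- p$events
    .writeTsv(data.frame(onset = ev$onset_sample / fs,
                         duration = 2,
                         sample = ev$onset_sample,
                         trial_index = ev$trial_index,
                         trial_type = ev$trial_type,
                         validity = ifelse(ev$validity == "", NA,
                                           ev$validity)),
              file.path(eegdir, paste0(id, "_task-toypass_events.tsv")))
    .writeTsv(data.frame(name = rownames(p$recording@data),
                         type = "EEG", units = "uV"),
              file.path(eegdir, paste0(id, "_task-toypass_channels.tsv")))
    .writeTsv(p$behavior,
              file.path(behdir, paste0(id, "_task-toypass_beh.tsv")))
    data.frame(participant = id, path = file.path(root, id))
  })
  invisible(do.call(rbind, rows))
}

#' Read a cohort dataset written by \code{\link{writeDataset}}
#'
#' Reconstructs per-participant recordings, event tables and behavior
#' records. A missing events file raises a descriptive parse error; a
#' sampling-rate disagreement between the JSON sidecar and the
#' BrainVision header raises a validation error.
#'
#' @param root dataset directory.
#' @return a \code{CohortDataset}.
#' @export
readDataset <- function(root) {
  mj <- file.path(root, "montage.json")
  montage <- NULL
  if (file.exists(mj)) {
    m <- jsonlite::read_json(mj, simplifyVector = TRUE)
    montage <- eegMontage(m$labels, m$positions,
                          lapply(m$clusters, unlist))
  }
  subs <- sort(list.dirs(root, recursive = FALSE))
  subs <- subs[grepl("^sub-", basename(subs))]
  parts <- lapply(subs, function(sd) {
    id <- basename(sd)
    base <- file.path(sd, "eeg", paste0(id, "_task-toypass_eeg"))
    evf <- file.path(sd, "eeg", paste0(id, "_task-toypass_events.tsv"))
    if (!file.exists(evf))
      stop("missing events file for ", id, ": expected ", evf)
    rec <- .readBrainVision(paste0(base, ".vhdr"), participant = id)
    side <- paste0(base, ".json")
    if (file.exists(side)) {
      fs_side <- jsonlite::read_json(side)$SamplingFrequency
      if (abs(fs_side - rec@samplingRate) > 1e-6)
        stop("sampling-rate mismatch for ", id, ": sidecar ", fs_side,
             " Hz vs header ", rec@samplingRate, " Hz")
    }
    evt <- .readTsv(evf)
    behf <- file.path(sd, "beh", paste0(id, "_task-toypass_beh.tsv"))
    beh <- if (file.exists(behf)) .readTsv(behf)
           else data.frame(trial_index = integer(0), correct = integer(0))
    events <- data.frame(
      trial_index = evt$trial_index,
      trial_type = evt$trial_type,
      onset_sample = as.integer(evt$sample),
      validity = ifelse(is.na(evt$validity), "", evt$validity),
      correct = beh$correct[match(evt$trial_index, beh$trial_index)],
      stringsAsFactors = FALSE)
    rec@events <- events
    list(recording = rec, events = events, behavior = beh)
  })
  gtf <- file.path(root, "ground_truth.tsv")
  out <- list(participants = parts,
              montage = montage,
              ground_truth = if (file.exists(gtf)) .readTsv(gtf) else NULL,
              spec = NULL)
  class(out) <- "CohortDataset"
  out
}

#' Remove trials carrying validity codes
#'
#' Drops every trial with a non-empty validity code (children verbalized
#' or turned around, caregiver interference, experimenter error) and
#' reports counts removed per code. Idempotent.
#'
#' @param events event data.frame with a \code{validity} column
#'   (comma-joined codes, empty string when valid).
#' @return list: \code{events} (valid trials only), \code{removed} (named
#'   integer vector of counts per code).
#' @export
filterValidTrials <- function(events) {
  codes <- validityCodes()
  removed <- stats::setNames(integer(length(codes)), codes)
  has <- nzchar(events$validity) & !is.na(events$validity)
  for (cd in codes)
    removed[cd] <- sum(vapply(strsplit(events$validity[has], ","),
                              function(v) cd %in% trimws(v), logical(1)))
  list(events = events[!has, , drop = FALSE], removed = removed)
}
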