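#' Pipeline configuration
#'
#' Bundles every stage's parameter block. Two profiles are provided:
#' \code{"full"} runs the complete cascade (filter, resample, bad-channel
#' removal, ICA, CSD) on the full montage; \code{"fast"} is the reduced
#' spectral-analysis path used for cohort-level simulation studies — it
#' simulates only the analysis-cluster channels, epochs the valid trials
#' directly and proceeds to time-frequency power and inference, skipping
#' the artifact stages (the simulated data are artifact-free by
#' construction) and the CSD transform (meaningless on a sparse channel
#' subset).
#'
#' @param cohort a \code{\link{cohortSpec}} (ignored when \code{input_dir}
#'   is given).
#' @param input_dir optional dataset directory to read instead of
#'   simulating.
#' @param profile \code{"full"} or \code{"fast"}.
#' @param preproc a \code{\link{preprocConfig}}.
#' @param csd a \code{\link{csdParams}}.
#' @param tfr a \code{\link{tfrParams}}.
#' @param clusters analysis clusters.
#' @param contrasts named list of contrasts, each \code{c(A, B)} condition
#'   selectors.
#' @param n_perm permutations for the sign-flip test.
#' @param q_map FDR level for time-frequency maps.
#' @param q_corr FDR level for the correlation family.
#' @param stat_band frequency band (Hz) of the point-wise test.
#' @param min_trials participants with fewer surviving trials than this in
#'   either pooled condition are excluded (strictly fewer).
#' @param seed master seed for permutation and ICA stages.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(cohort = cohortSpec(),
                           input_dir = NULL,
                           profile = c("full", "fast"),
                           preproc = preprocConfig(),
                           csd = csdParams(),
                           tfr = tfrParams(),
                           clusters = c("midfrontal", "left_tp",
                                        "right_tp"),
                           contrasts = list(
                             PTvsControl = c("PT", "Control"),
                             DNSvsCS = c("DoesNotSee", "CanSee"),
                             NYvsY = c("NotYellow", "Yellow")),
                           n_perm = 5000,
                           q_map = 0.05,
                           q_corr = 0.2,
                           stat_band = c(3, 20),
                           min_trials = 5L,
                           seed = 1L) {
  profile <- match.arg(profile)
  cfg <- list(cohort = cohort, input_dir = input_dir, profile = profile,
              preproc = preproc, csd = csd, tfr = tfr,
              clusters = clusters, contrasts = contrasts,
              n_perm = n_perm, q_map = q_map, q_corr = q_corr,
              stat_band = stat_band, min_trials = as.integer(min_trials),
              seed = as.integer(seed))
  stopifnot(cfg$min_trials >= 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Reduced-scale configuration for simulation studies
#'
#' The \code{"fast"} profile at the problem sizes used for the package's
#' cohort-level simulation studies: 100 Hz generation on the
#' analysis-cluster channels, a 1-Hz frequency grid over the 3-20 Hz test
#' band, a 10-ms output time grid and 1000 permutations. Generator effect
#' parameters are untouched.
#'
#' @param n_participants cohort size.
#' @param seed cohort and analysis seed.
#' @param effect_amplitude passed to the cohort's participant template
#'   (default: generator default).
#' @param amp_sd across-participant amplitude SD.
#' @param n_perm permutations.
#' @return a \code{\link{pipelineConfig}}.
#' @export
fastPipelineConfig <- function(n_participants = 46L, seed = 1L,
                               effect_amplitude = NULL, amp_sd = 3,
                               n_perm = 1000) {
  amp <- if (is.null(effect_amplitude)) 8 else effect_amplitude
  pipelineConfig(
    cohort = cohortSpec(n_participants = n_participants,
                        amp_mean = amp, amp_sd = amp_sd,
                        sampling_rate = 100, seed = seed),
    profile = "fast",
    tfr = tfrParams(freqs = seq(3, 20, by = 1),
                    output_times = seq(0, 2, by = 0.02)),
    n_perm = n_perm,
    seed = seed)
}

#' Exclude participants with too few surviving trials
#'
#' Removes participants with fewer than \code{min_trials} surviving
#' (artifact-free, valid) trials in either pooled condition
#' (perspective-taking or control); the boundary is strict, a participant
#' with exactly \code{min_trials} in both is retained.
#'
#' @param counts data.frame with columns \code{participant_id},
#'   \code{pt}, \code{control} (surviving trial counts).
#' @param min_trials exclusion boundary (default 5).
#' @return list: \code{keep} (ids), \code{excluded} (ids), \code{log}
#'   (the counts table with an \code{excluded} flag).
#' @export
excludeParticipants <- function(counts, min_trials = 5L) {
  if (nrow(counts) == 0) {
    warning("empty dataset: nothing to exclude")
    return(list(keep = character(0), excluded = character(0),
                log = cbind(counts, excluded = logical(0))))
  }
  excl <- counts$pt < min_trials | counts$control < min_trials
  list(keep = counts$participant_id[!excl],
       excluded = counts$participant_id[excl],
       log = cbind(counts, excluded = excl))
}

## Process one participant to per-cluster condition power maps.
.participantMaps <- function(part, montage, cfg, seed_i) {
  if (cfg$profile == "full") {
    pp <- preprocessRecording(part$recording, montage,
                              config = cfg$preproc, seed = seed_i)
    ep <- csdTransform(pp$epochs, pp$montage, cfg$csd)
    mon <- pp$montage
  } else {
    ep <- epochRecording(part$recording, window = c(0, 2),
                         pad = cfg$preproc$pad)
    mon <- subsetMontage(montage, channelLabels(ep))
  }
  id <- part$recording@participant
  meta <- trialMeta(ep)
  surv <- !rejectedEpochs(ep)
  n_pt <- sum(surv & isPerspectiveTaking(meta$trial_type))
  n_ctrl <- sum(surv & !isPerspectiveTaking(meta$trial_type))
  chans <- unique(unlist(lapply(intersect(cfg$clusters,
                                          names(mon@clusters)),
                                clusterChannels, x = mon)))
  pw <- morletPower(ep, cfg$tfr, channels = chans)
  conds <- unique(unlist(cfg$contrasts))
  maps <- list()
  for (cl in cfg$clusters) {
    cch <- intersect(clusterChannels(mon, cl), dimnames(pw)[[2]])
    if (length(cch) == 0) next
    pw_cl <- pw[, cch, , , drop = FALSE]
    attr(pw_cl, "freqs") <- attr(pw, "freqs")
    attr(pw_cl, "times") <- attr(pw, "times")
    for (cond in conds) {
      key <- paste(cl, cond, sep = ".")
      maps[[key]] <- tryCatch({
        m <- aggregateCluster(pw_cl, meta, cch, cond,
                              rejected = rejectedEpochs(ep),
                              participant = id)
        m@cluster <- cl
        m
      }, error = function(e) NULL)
    }
  }
  list(id = id, maps = maps, n_pt = n_pt, n_control = n_ctrl,
       events = meta)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, preprocesses each participant according
#' to the configured profile, applies the CSD transform (full profile),
#' estimates per-trial Morlet power, aggregates per cluster and
#' condition, forms per-participant normalized-difference maps, tests
#' them against zero with the sign-flip permutation test and per-cluster
#' BH-FDR, and computes the behavioral summary, group behavioral tests
#' and brain-behavior correlations. Deterministic given the
#' configuration.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param dataset optionally, a pre-built \code{CohortDataset} (overrides
#'   simulation/reading; its montage is used).
#' @return list of class \code{ReportBundle}: \code{stats} (nested
#'   cluster -> contrast \linkS4class{StatResult}), \code{diff_maps},
#'   \code{behavior_summary}, \code{behavior_tests}, \code{correlations},
#'   \code{effect_scalar}, \code{exclusions}, \code{ground_truth},
#'   \code{config}.
#' @export
runPipeline <- function(config, dataset = NULL) {
  if (is.null(dataset)) {
    dataset <- if (!is.null(config$input_dir)) readDataset(config$input_dir)
    else {
      mon <- buildIdealizedMontage()
      if (config$profile == "fast") {
        keep <- unique(unlist(lapply(config$clusters, clusterChannels,
                                     x = mon)))
        mon <- subsetMontage(mon, keep)
      }
      simulateCohort(config$cohort, montage = mon)
    }
  }
  montage <- dataset$montage
  if (is.null(montage)) montage <- buildIdealizedMontage()

  n <- length(dataset$participants)
  per <- vector("list", n)
  for (i in seq_len(n))
    per[[i]] <- .participantMaps(dataset$participants[[i]], montage,
                                 config, seed_i = config$seed + i)

  counts <- do.call(rbind, lapply(per, function(p)
    data.frame(participant_id = p$id, pt = p$n_pt, control = p$n_control)))
  excl <- excludeParticipants(counts, config$min_trials)
  per <- per[counts$participant_id %in% excl$keep]

  stats_out <- list()
  diff_maps <- list()
  for (cl in config$clusters) {
    stats_out[[cl]] <- list()
    diff_maps[[cl]] <- list()
    for (cn in names(config$contrasts)) {
      ab <- config$contrasts[[cn]]
      dm <- list()
      for (p in per) {
        A <- p$maps[[paste(cl, ab[1], sep = ".")]]
        B <- p$maps[[paste(cl, ab[2], sep = ".")]]
        if (!is.null(A) && !is.null(B))
          dm[[length(dm) + 1]] <- normalizedDifference(A, B,
                                                       contrast = cn)
      }
      diff_maps[[cl]][[cn]] <- dm
      if (length(dm) >= 2)
        stats_out[[cl]][[cn]] <- permutationTestVsZero(
          dm, n_perm = config$n_perm, seed = config$seed,
          q = config$q_map, fmin = config$stat_band[1],
          fmax = config$stat_band[2])
    }
  }

  ev_list <- stats::setNames(lapply(per, function(p) p$events),
                             vapply(per, function(p) p$id, character(1)))
  bsum <- behaviorAccuracy(ev_list)
  btests <- if (nrow(bsum) >= 3) behaviorTests(bsum) else NULL
  eff <- corr <- NULL
  main_cl <- if ("right_tp" %in% names(stats_out)) "right_tp"
             else names(stats_out)[1]
  main <- stats_out[[main_cl]][["PTvsControl"]]
  if (!is.null(main)) {
    eff <- effectScalar(diff_maps[[main_cl]][["PTvsControl"]], main)
    corr <- brainBehaviorCorrelations(eff, bsum, q = config$q_corr)
  }

  out <- list(stats = stats_out, diff_maps = diff_maps,
              behavior_summary = bsum, behavior_tests = btests,
              correlations = corr, effect_scalar = eff,
              exclusions = excl, ground_truth = dataset$ground_truth,
              config = config)
  class(out) <- "ReportBundle"
  out
}

#' Write a results bundle to disk
#'
#' Writes, per cluster and contrast, the observed mean-D map, the p map
#' and the FDR mask as TSV matrices (frequencies in rows); the scalar
#' behavioral tests and correlations as TSVs; and a JSON run manifest
#' (seed, permutations, grids, exclusions, config hash) so every output
#' names its provenance.
#'
#' @param bundle a \code{ReportBundle}.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
writeResultsBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.json")
  cfg <- bundle$config
  cfg_json <- list(profile = cfg$profile, n_perm = cfg$n_perm,
                   seed = cfg$seed, q_map = cfg$q_map,
                   q_corr = cfg$q_corr, stat_band = cfg$stat_band,
                   min_trials = cfg$min_trials,
                   clusters = cfg$clusters,
                   cohort = cfg$cohort[setdiff(names(cfg$cohort),
                                               "participant_args")])
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(cfg_path))
  wm <- function(m, path) {
    df <- as.data.frame(m)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  for (cl in names(bundle$stats))
    for (cn in names(bundle$stats[[cl]])) {
      sr <- bundle$stats[[cl]][[cn]]
      base <- file.path(dir, paste0(cl, "_", cn))
      wm(sr@observed, paste0(base, "_observed.tsv"))
      wm(sr@p, paste0(base, "_p.tsv"))
      wm(sr@fdrMask * 1, paste0(base, "_fdrmask.tsv"))
    }
  if (!is.null(bundle$behavior_tests))
    .writeTsv(bundle$behavior_tests, file.path(dir, "behavior_tests.tsv"))
  if (!is.null(bundle$correlations))
    .writeTsv(bundle$correlations, file.path(dir, "correlations.tsv"))
  .writeTsv(bundle$behavior_summary,
            file.path(dir, "behavior_summary.tsv"))
  manifest <- list(config_hash = hash, seed = bundle$config$seed,
                   n_perm = bundle$config$n_perm,
                   excluded = bundle$exclusions$excluded,
                   included = bundle$exclusions$keep,
                   freqs = if (!is.null(bundle$stats[[1]][[1]]))
                     bundle$stats[[1]][[1]]@freqs else NULL,
                   times = if (!is.null(bundle$stats[[1]][[1]]))
                     bundle$stats[[1]][[1]]@times else NULL)
  mpath <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
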