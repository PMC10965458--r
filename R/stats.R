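#' Normalized power difference D = (A - B) / (A + B)
#'
#' Bounded contrast of two non-negative power maps on the same grid;
#' points with A + B = 0 are masked (NA).
#'
#' @param A,B \linkS4class{ClusterPowerMap}s with matching grids.
#' @param contrast label, e.g. \code{"PTvsControl"}.
#' @return a \linkS4class{DiffMap}.
#' @export
normalizedDifference <- function(A, B, contrast = paste0(A@condition,
                                                         "vs",
                                                         B@condition)) {
  if (!isTRUE(all.equal(A@freqs, B@freqs)) ||
      !isTRUE(all.equal(A@times, B@times)))
    stop("A and B are on different time-frequency grids")
  s <- A@power + B@power
  D <- (A@power - B@power) / s
  D[s == 0] <- NA_real_
  new("DiffMap", D = D, freqs = A@freqs, times = A@times,
      participant = A@participant, contrast = contrast,
      cluster = A@cluster)
}

## Stack a list of DiffMaps (shared grid) into participants x points.
.stackDiffMaps <- function(maps, fmin = 3, fmax = 20) {
  f <- maps[[1]]@freqs; t <- maps[[1]]@times
  for (m in maps)
    if (!isTRUE(all.equal(m@freqs, f)) || !isTRUE(all.equal(m@times, t)))
      stop("participants' maps are on non-overlapping grids")
  fi <- which(f >= fmin & f <= fmax)
  M <- do.call(rbind, lapply(maps, function(m)
    as.vector(m@D[fi, , drop = FALSE])))
  list(M = M, freqs = f[fi], times = t, nf = length(fi), nt = length(t))
}

#' Point-wise sign-flip permutation test of D maps against zero
#'
#' Observed statistic: across-participant mean of D at each
#' time-frequency point within 3-20 Hz. The null is built by randomly
#' negating each participant's whole map (one-sample sign-flipping); the
#' two-sided p-value is \code{(1 + #(|mean_perm| >= |mean_obs|)) /
#' (1 + n_perm)}. With \code{exhaustive = TRUE} (n <= 16) all 2^n sign
#' patterns are enumerated and \code{p = #(|mean_perm| >= |mean_obs|) /
#' 2^n}. Deterministic given the seed. The Benjamini-Hochberg mask at
#' \code{q} is computed over all unmasked points of the map.
#'
#' @param maps list of per-participant \linkS4class{DiffMap}s on a shared
#'   grid, or a participants x points numeric matrix.
#' @param n_perm number of random sign-flip permutations (default 5000; a
#'   warning is issued below 100).
#' @param seed integer seed.
#' @param q FDR level for the map mask (default 0.05).
#' @param fmin,fmax frequency band of the point-wise comparison.
#' @param exhaustive enumerate all sign patterns instead of sampling.
#' @return a \linkS4class{StatResult}.
#' @export
permutationTestVsZero <- function(maps, n_perm = 5000, seed = 1L,
                                  q = 0.05, fmin = 3, fmax = 20,
                                  exhaustive = FALSE) {
  if (is.list(maps)) {
    if (length(maps) < 2) stop("need at least 2 participants")
    st <- .stackDiffMaps(maps, fmin, fmax)
    M <- st$M; freqs <- st$freqs; times <- st$times
    cluster <- maps[[1]]@cluster; contrast <- maps[[1]]@contrast
  } else {
    M <- as.matrix(maps); freqs <- numeric(0); times <- numeric(0)
    cluster <- ""; contrast <- ""
    if (nrow(M) < 2) stop("need at least 2 participants")
  }
  n <- nrow(M)
  M0 <- M
  M0[is.na(M0)] <- 0                      # masked points contribute zero
  n_ok <- colSums(!is.na(M))
  obs <- colSums(M0) / pmax(n_ok, 1)

  if (exhaustive) {
    if (n > 16) stop("exhaustive enumeration limited to n <= 16")
    n_perm <- 2^n
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- (signs %*% M0) / rep(pmax(n_ok, 1), each = n_perm)
    exc <- colSums(abs(perm) >= matrix(abs(obs), n_perm, ncol(M),
                                       byrow = TRUE) - 1e-12)
    p <- exc / n_perm
  } else {
    if (n_perm < 100) warning("n_perm < 100: permutation p is coarse")
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    n_perm, n)
    perm <- (signs %*% M0) / rep(pmax(n_ok, 1), each = n_perm)
    exc <- colSums(abs(perm) >= matrix(abs(obs), n_perm, ncol(M),
                                       byrow = TRUE) - 1e-12)
    p <- (1 + exc) / (1 + n_perm)
  }
  p[n_ok == 0] <- NA_real_

  fm <- fdrMask(p, q)
  shape <- function(v) if (length(freqs))
    matrix(v, length(freqs), length(times)) else matrix(v, 1)
  new("StatResult", observed = shape(obs), p = shape(p),
      qLevel = q, fdrMask = shape(fm$mask),
      scalars = data.frame(), nPerm = n_perm, seed = as.numeric(seed),
      freqs = freqs, times = times, cluster = cluster,
      contrast = contrast)
}

#' Benjamini-Hochberg rejection mask
#'
#' BH-FDR over all unmasked (non-NA) p-values of one family (one
#' cluster's map, or one family of correlations): reject where the
#' BH-adjusted p-value is at most \code{q}.
#'
#' @param p numeric vector/matrix of p-values in [0, 1]; NAs stay NA.
#' @param q FDR level.
#' @return list: \code{mask} (logical, same shape), \code{cut} (largest
#'   rejected raw p, 0 if none).
#' @export
fdrMask <- function(p, q = 0.05) {
  mask <- rep(NA, length(p))
  ok <- !is.na(p)
  if (any(ok)) {
    adj <- stats::p.adjust(p[ok], method = "BH")
    mask[ok] <- adj <= q
  }
  cut <- if (any(ok) && any(mask[ok])) max(p[ok][mask[ok]]) else 0
  if (is.matrix(p)) mask <- matrix(mask, nrow(p), ncol(p))
  list(mask = mask, cut = cut)
}

#' Per-participant behavioral accuracy summary
#'
#' Percent correct over valid trials, per pooled condition (PT, control)
#' and per trial type; NA where a participant has no valid trial of a
#' type.
#'
#' @param events_list named list (one element per participant) of event
#'   data.frames carrying \code{trial_type}, \code{validity} and
#'   \code{correct}.
#' @return data.frame with one row per participant and columns
#'   \code{pt}, \code{control}, \code{can_see}, \code{does_not_see},
#'   \code{yellow}, \code{not_yellow} (0-100).
#' @export
behaviorAccuracy <- function(events_list) {
  pct <- function(ev, types) {
    sel <- ev$trial_type %in% types & ev$validity == "" &
      !is.na(ev$correct)
    if (!any(sel)) return(NA_real_)
    100 * mean(ev$correct[sel])
  }
  rows <- lapply(names(events_list), function(id) {
    ev <- events_list[[id]]
    data.frame(participant_id = id,
               pt = pct(ev, c("CanSee", "DoesNotSee")),
               control = pct(ev, c("Yellow", "NotYellow")),
               can_see = pct(ev, "CanSee"),
               does_not_see = pct(ev, "DoesNotSee"),
               yellow = pct(ev, "Yellow"),
               not_yellow = pct(ev, "NotYellow"))
  })
  do.call(rbind, rows)
}

#' One-sample t statistic from summary numbers
#'
#' \code{t = (mean - mu) / (sd / sqrt(n))} with \code{df = n - 1}; the
#' form used to test group accuracy against chance from reported summary
#' statistics.
#'
#' @param mean,sd,n summary statistics.
#' @param mu null value (default 50, chance percent correct).
#' @return list: \code{statistic}, \code{df}, \code{p} (two-sided).
#' @export
oneSampleTFromSummary <- function(mean, sd, n, mu = 50) {
  t <- (mean - mu) / (sd / sqrt(n))
  list(statistic = t, df = n - 1,
       p = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Behavioral group tests
#'
#' One-sample t of perspective-taking accuracy against chance (50),
#' paired t of CanSee vs DoesNotSee (pairwise complete), and the
#' two-level repeated-measures ANOVA of PT vs control implemented through
#' the paired-t identity (F = t^2 on df = (1, n - 1); exact for two
#' levels).
#'
#' @param summary data.frame from \code{\link{behaviorAccuracy}}.
#' @param chance chance level in percent (default 50).
#' @return data.frame with columns test, statistic, df1, df2, p.
#' @export
behaviorTests <- function(summary, chance = 50) {
  if (nrow(summary) < 3) stop("need at least 3 participants")
  pt <- summary$pt[!is.na(summary$pt)]
  if (stats::sd(pt) == 0)
    stop("zero variance in PT accuracy: one-sample t is degenerate")
  t1 <- stats::t.test(pt, mu = chance)

  cc <- stats::complete.cases(summary$can_see, summary$does_not_see)
  d <- summary$can_see[cc] - summary$does_not_see[cc]
  if (stats::sd(d) == 0)
    stop("zero variance in CanSee - DoesNotSee differences: paired t is degenerate")
  t2 <- stats::t.test(summary$can_see[cc], summary$does_not_see[cc],
                      paired = TRUE)

  cc3 <- stats::complete.cases(summary$pt, summary$control)
  d3 <- summary$pt[cc3] - summary$control[cc3]
  if (stats::sd(d3) == 0 && any(d3 != 0))
    stop("zero variance in PT - control differences: RM-ANOVA is degenerate")
  if (all(d3 == 0)) {
    Fv <- 0; pF <- 1
  } else {
    t3 <- stats::t.test(summary$pt[cc3], summary$control[cc3],
                        paired = TRUE)
    Fv <- unname(t3$statistic)^2
    pF <- t3$p.value
  }
  data.frame(
    test = c("pt_vs_chance_t", "cansee_vs_doesnotsee_paired_t",
             "pt_vs_control_rm_anova_F"),
    statistic = c(unname(t1$statistic), unname(t2$statistic), Fv),
    df1 = c(unname(t1$parameter), unname(t2$parameter), 1),
    df2 = c(NA, NA, sum(cc3) - 1),
    p = c(t1$p.value, t2$p.value, pF))
}

#' Brain-behavior correlations with FDR over the outcome family
#'
#' Pearson correlations between a per-participant neural effect scalar
#' (e.g. mean D over the FDR-significant region of the PT-vs-control
#' contrast) and behavioral accuracy on each of the six outcomes, pairwise
#' complete; outcomes with fewer than 4 complete pairs are skipped with a
#' log entry. Benjamini-Hochberg correction at \code{q} (default 0.2) is
#' applied across the tested outcomes.
#'
#' @param effect named numeric vector of neural scalars, names =
#'   participant ids.
#' @param summary data.frame from \code{\link{behaviorAccuracy}}.
#' @param q FDR level for the correlation family.
#' @return data.frame with columns outcome, r, df, p, q_significant, n;
#'   skipped outcomes carry NA and \code{q_significant = NA}.
#' @export
brainBehaviorCorrelations <- function(effect, summary, q = 0.2) {
  outcomes <- c(pt = "pt", control = "control", can_see = "can_see",
                does_not_see = "does_not_see", yellow = "yellow",
                not_yellow = "not_yellow")
  eff <- effect[match(summary$participant_id, names(effect))]
  rows <- lapply(names(outcomes), function(oc) {
    y <- summary[[outcomes[[oc]]]]
    cc <- stats::complete.cases(eff, y)
    if (sum(cc) < 4)
      return(data.frame(outcome = oc, r = NA_real_, df = NA_real_,
                        p = NA_real_, n = sum(cc)))
    ct <- stats::cor.test(eff[cc], y[cc])
    data.frame(outcome = oc, r = unname(ct$estimate),
               df = unname(ct$parameter), p = ct$p.value, n = sum(cc))
  })
  res <- do.call(rbind, rows)
  fm <- fdrMask(res$p, q)
  res$q_significant <- fm$mask
  res
}

#' Neural effect scalar per participant
#'
#' Mean of a participant's D map over a region: either the
#' FDR-significant region of a group \linkS4class{StatResult} (the
#' default) or a fixed a-priori band/window.
#'
#' @param maps list of per-participant \linkS4class{DiffMap}s.
#' @param region either a \linkS4class{StatResult} (its
#'   \code{fdrSignificant} mask is used) or a list with \code{band} and
#'   \code{window} (Hz, s).
#' @return named numeric vector, names = participant ids.
#' @export
effectScalar <- function(maps, region) {
  f <- maps[[1]]@freqs; t <- maps[[1]]@times
  if (is(region, "StatResult")) {
    sel_f <- match(round(region@freqs, 9), round(f, 9))
    mask <- matrix(FALSE, length(f), length(t))
    mask[sel_f, ] <- region@fdrMask %in% TRUE
  } else {
    mask <- outer(f >= region$band[1] & f <= region$band[2],
                  t >= region$window[1] & t <= region$window[2], "&")
  }
  if (!any(mask)) mask[] <- TRUE          # fall back to the whole map
  out <- vapply(maps, function(m) mean(m@D[mask], na.rm = TRUE),
                numeric(1))
  names(out) <- vapply(maps, function(m) m@participant, character(1))
  out
}
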