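## Printed electrode sets of the 128-channel geodesic net used throughout:
## the three analysis clusters, the 24-channel outer ring that overlays neck
## and ears, and the small frontal set used for the ocular voltage rule.

.MIDFRONTAL <- c("E11", "E16", "E19", "E12", "E5", "E4", "E6")
.LEFT_TP <- c("E30", "E36", "E37", "E41", "E42", "E46", "E47", "E52", "E53")
.RIGHT_TP <- c("E86", "E87", "E92", "E93", "E98", "E102", "E103", "E104",
               "E105")
.OUTER_RING <- c("E17", "E38", "E43", "E44", "E48", "E49", "E113", "E114",
                 "E119", "E120", "E121", "E125", "E126", "E127", "E128",
                 "E56", "E63", "E68", "E73", "E81", "E88", "E94", "E99",
                 "E107")
.OCULAR <- c("E1", "E8", "E14", "E21", "E25", "E32", "E17")

#' Construct an EegMontage
#'
#' @param labels character vector of electrode labels.
#' @param positions n x 3 numeric matrix of unit-sphere positions.
#' @param clusters named list of character vectors.
#' @return an \linkS4class{EegMontage}.
#' @export
eegMontage <- function(labels, positions, clusters = list()) {
  positions <- as.matrix(positions)
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  new("EegMontage", labels = labels, positions = positions,
      clusters = clusters)
}

#' Build the idealized 128-channel montage
#'
#' Places 128 electrodes on an idealized unit sphere (deterministic
#' Fibonacci spiral covering the head down to just below the equator) and
#' assigns labels so that the named channel sets are spatially coherent:
#' the 24 outer-ring channels occupy the lowest band, the midfrontal
#' cluster sits anterior-superior, the temporal-parietal clusters sit
#' lateral-posterior, and the frontal ocular channels sit low over the
#' face. Positions are idealized, not digitized head coordinates.
#'
#' Coordinate convention: +x right, +y anterior, +z up; unit head radius.
#'
#' @param n_channels number of channels; only 128 is supported.
#' @return an \linkS4class{EegMontage} with clusters \code{midfrontal},
#'   \code{left_tp}, \code{right_tp} and \code{outer_ring}.
#' @examples
#' mon <- buildIdealizedMontage()
#' lengths(mon@clusters)
#' @export
buildIdealizedMontage <- function(n_channels = 128L) {
  if (!identical(as.integer(n_channels), 128L))
    stop("only the 128-channel geodesic-style montage is supported")
  n <- 128L
  ## Fibonacci spiral from z just below the equator up to near the vertex
  k <- seq_len(n)
  z <- -0.30 + (k - 0.5) / n * (0.995 + 0.30)
  golden <- pi * (3 - sqrt(5))
  th <- golden * k
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z)

  labels <- character(n)
  free <- rep(TRUE, n)

  assign_nearest <- function(target, lab_set) {
    target <- target / sqrt(sum(target^2))
    d <- acos(pmin(1, pmax(-1, pos %*% target)))
    d[!free] <- Inf
    idx <- order(d)[seq_along(lab_set)]
    labels[idx] <<- lab_set
    free[idx] <<- FALSE
  }

  ## outer ring: lowest 24 positions, labelled in azimuthal order
  ring_idx <- order(z)[1:24]
  ring_idx <- ring_idx[order(atan2(pos[ring_idx, 2], pos[ring_idx, 1]))]
  labels[ring_idx] <- .OUTER_RING
  free[ring_idx] <- FALSE

  assign_nearest(c(0, 0.97, 0.05), setdiff(.OCULAR, .OUTER_RING))
  assign_nearest(c(0, 0.50, 0.87), .MIDFRONTAL)
  assign_nearest(c(-0.77, -0.51, 0.38), .LEFT_TP)
  assign_nearest(c(0.77, -0.51, 0.38), .RIGHT_TP)

  rest <- setdiff(paste0("E", 1:128), labels)
  labels[free] <- rest
  eegMontage(labels, pos,
             clusters = list(midfrontal = .MIDFRONTAL,
                             left_tp = .LEFT_TP,
                             right_tp = .RIGHT_TP,
                             outer_ring = .OUTER_RING))
}

#' Restrict a montage to a subset of channels
#'
#' Drops the listed channels (or keeps only \code{keep}); clusters are
#' intersected with the remaining labels.
#'
#' @param montage an \linkS4class{EegMontage}.
#' @param keep channel labels to keep, in montage order.
#' @return an \linkS4class{EegMontage}.
#' @export
subsetMontage <- function(montage, keep) {
  keep <- intersect(montage@labels, keep)
  idx <- match(keep, montage@labels)
  cl <- lapply(montage@clusters, intersect, y = keep)
  cl <- cl[vapply(cl, length, integer(1)) > 0]
  eegMontage(keep, montage@positions[idx, , drop = FALSE], cl)
}

#' Frontal channels used by the ocular voltage rule
#'
#' The printed frontal set contains E17, which is also listed in the outer
#' ring and is therefore usually gone by the time the ocular rule runs; the
#' rule is applied to whichever of these channels remain.
#'
#' @return character vector of channel labels.
#' @export
ocularChannels <- function() .OCULAR
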