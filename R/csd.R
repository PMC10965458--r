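#' Spherical-spline surface-Laplacian parameters
#'
#' Defaults mirror the published defaults of the widely used CSD toolbox:
#' spline order m = 4, regularization 1e-5, 50 Legendre terms, unit head
#' radius.
#'
#' @param m spline order (>= 2).
#' @param lambda regularization added to the diagonal of G (>= 0).
#' @param legendre_terms number of Legendre terms (>= 10).
#' @param head_radius head radius in the unit of choice; the Laplacian
#'   scales with 1 / head_radius^2.
#' @return list of class \code{CsdParams}.
#' @export
csdParams <- function(m = 4L, lambda = 1e-5, legendre_terms = 50L,
                      head_radius = 1) {
  stopifnot(m >= 2, lambda >= 0, legendre_terms >= 10, head_radius > 0)
  p <- list(m = as.integer(m), lambda = lambda,
            legendre_terms = as.integer(legendre_terms),
            head_radius = head_radius)
  class(p) <- "CsdParams"
  p
}

## G and H kernel matrices of the spherical-spline expansion evaluated at
## the inter-electrode cosines. g uses (n(n+1))^-m; its surface Laplacian
## multiplies each degree-n term by -n(n+1), giving h with (n(n+1))^(1-m)
## and a negative sign.
.splineKernels <- function(cosang, params) {
  N <- params$legendre_terms
  Pprev <- matrix(1, nrow(cosang), ncol(cosang))  # P_0
  Pcur <- cosang                                  # P_1
  G <- matrix(0, nrow(cosang), ncol(cosang))
  H <- G
  for (n in seq_len(N)) {
    if (n > 1) {
      Pnew <- ((2 * n - 1) * cosang * Pcur - (n - 1) * Pprev) / n
      Pprev <- Pcur
      Pcur <- Pnew
    }
    w <- (2 * n + 1) / (n * (n + 1))^params$m
    G <- G + w * Pcur
    H <- H - (2 * n + 1) / (n * (n + 1))^(params$m - 1) * Pcur
  }
  list(G = G / (4 * pi), H = H / (4 * pi))
}

.cosAngles <- function(P, Q) {
  x <- P %*% t(Q)
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

## Constrained spline solve: rows of the returned matrix map potentials V
## at the electrodes to spline coefficients c with sum(c) = 0, after
## removing the fitted constant.
.splineCoefMatrix <- function(G, lambda) {
  Gs <- G + diag(lambda, nrow(G))
  Gi <- solve(Gs)
  ones <- rep(1, nrow(G))
  u <- (Gi %*% ones) / as.numeric(t(ones) %*% Gi %*% ones)
  list(TC = Gi - Gi %*% ones %*% t(u), u = u)
}

#' Surface-Laplacian (CSD) transform matrix for a montage
#'
#' Computes the linear map from scalp potentials to spherical-spline
#' surface-Laplacian estimates at the same electrodes. The matrix depends
#' only on the montage subset and the parameters, so it can be cached and
#' re-applied; the transform is reference-free (adding a constant to all
#' channels leaves the output unchanged) and maps a degree-l spherical
#' harmonic approximately to -l(l+1) times itself (unit head radius).
#'
#' @param montage an \linkS4class{EegMontage}.
#' @param labels channels to include (default: all montage channels).
#' @param params a \code{\link{csdParams}}.
#' @return numeric channels x channels matrix.
#' @export
csdTransformMatrix <- function(montage, labels = channelLabels(montage),
                               params = csdParams()) {
  pos <- electrodePositions(montage)[labels, , drop = FALSE]
  cosang <- .cosAngles(pos, pos)
  off <- cosang
  diag(off) <- 0
  if (any(off > 1 - 1e-12))
    stop("duplicate electrode positions make the spline system singular")
  kern <- .splineKernels(cosang, params)
  sol <- .splineCoefMatrix(kern$G, params$lambda)
  out <- (kern$H %*% sol$TC) / params$head_radius^2
  dimnames(out) <- list(labels, labels)
  out
}

#' Apply the CSD transform to an epoch set
#'
#' Per sample, maps average-referenced potentials (microvolts) to
#' surface-Laplacian estimates (microvolts / head_radius^2). Linear in the
#' input and independent of the reference.
#'
#' @param ep an \linkS4class{EpochSet} with at least 8 channels.
#' @param montage montage covering the epoch channels.
#' @param params a \code{\link{csdParams}}.
#' @return the transformed \linkS4class{EpochSet}.
#' @export
csdTransform <- function(ep, montage, params = csdParams()) {
  if (dim(ep@data)[2] < 8) stop("need at least 8 channels for CSD")
  Tm <- csdTransformMatrix(montage, ep@channelLabels, params)
  for (i in seq_len(dim(ep@data)[1]))
    ep@data[i, , ] <- Tm %*% ep@data[i, , ]
  ep
}

#' Spherical-spline interpolation matrix
#'
#' Linear map reconstructing the potentials at \code{bad} electrodes from
#' those at \code{good} electrodes by spherical-spline interpolation
#' (same kernel family as the CSD transform). Exact for spatially constant
#' potentials.
#'
#' @param montage an \linkS4class{EegMontage} containing all electrodes.
#' @param good,bad disjoint character vectors of channel labels.
#' @param params a \code{\link{csdParams}}.
#' @return length(bad) x length(good) matrix.
#' @export
interpolationMatrix <- function(montage, good, bad,
                                params = csdParams()) {
  pos <- electrodePositions(montage)
  pg <- pos[good, , drop = FALSE]
  pb <- pos[bad, , drop = FALSE]
  kern_gg <- .splineKernels(.cosAngles(pg, pg), params)
  kern_bg <- .splineKernels(.cosAngles(pb, pg), params)
  sol <- .splineCoefMatrix(kern_gg$G, params$lambda)
  M <- rep(1, length(bad)) %*% t(sol$u) + kern_bg$G %*% sol$TC
  dimnames(M) <- list(bad, good)
  M
}
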