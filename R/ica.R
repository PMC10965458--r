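## FastICA (symmetric decorrelation, logcosh contrast), written for the
## artifact-removal stage: deterministic given the seed, PCA-whitened,
## with a single documented retry on non-convergence.
##
## X: channels x samples (microvolts). Returns mixing A (channels x comp),
## unmixing W (comp x channels, including whitening, applied to centered
## data) and sources S = W (X - rowMeans(X)).
.fastICA <- function(X, n_comp, seed, max_iter = 300, tol = 1e-4) {
  set.seed(seed)
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  C <- tcrossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  n_comp <- min(n_comp, sum(pos))
  D <- eg$values[seq_len(n_comp)]
  E <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  K <- diag(1 / sqrt(D), n_comp) %*% t(E)        # whitening
  Kinv <- E %*% diag(sqrt(D), n_comp)            # de-whitening
  Z <- K %*% Xc

  run <- function() {
    W <- matrix(stats::rnorm(n_comp^2), n_comp)
    sym <- function(W) {
      s <- La.svd(W)
      s$u %*% s$vt
    }
    W <- sym(W)
    for (it in seq_len(max_iter)) {
      WZ <- W %*% Z
      G <- tanh(WZ)
      gp <- rowMeans(1 - G^2)
      W1 <- sym(tcrossprod(G, Z) / n - diag(gp, n_comp) %*% W)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) return(list(W = W, converged = TRUE))
    }
    list(W = W, converged = FALSE)
  }
  fit <- run()
  if (!fit$converged) fit <- run()               # one retry, new init
  ## near-Gaussian directions never meet the fixed-point tolerance; the
  ## kurtotic (artifact) components stabilize long before max_iter, so the
  ## final iterate is still a usable basis for component classification
  if (!fit$converged)
    warning("FastICA tolerance not reached after retry; ",
            "using the final iterate")
  W <- fit$W
  if (any(!is.finite(W))) stop("FastICA diverged to non-finite values")
  Wfull <- W %*% K
  A <- Kinv %*% t(W)
  list(A = A, W = Wfull, S = Wfull %*% Xc, mu = mu, n_comp = n_comp)
}
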