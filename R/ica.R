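#' Fast fixed-point independent component analysis
#'
#' Seeded symmetric fixed-point ICA with the logcosh contrast: rows of `X`
#' are centered, whitened through the eigendecomposition of the channel
#' covariance, and the orthogonal unmixing matrix is iterated from a seeded
#' random rotation with symmetric decorrelation until the update falls below
#' `tol`. As many components as channels are extracted.
#'
#' @param X channels x samples numeric matrix.
#' @param seed integer seed for the initial rotation.
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on `max |1 - diag(W W_old')|`.
#' @param stall_tol divergence guard: when the iteration cap is reached, a
#'   basis whose update is still below `stall_tol` is accepted (with
#'   `converged = FALSE`); above it a convergence error is raised. A signal
#'   whose sources are (near-)Gaussian leaves the rotation of that subspace
#'   unidentifiable — the fixed point then wanders at sample-noise level
#'   without ever damaging the reconstruction, which is exact for any
#'   orthogonal rotation of the whitened space.
#' @return list with `S` (components x samples source estimates), `A`
#'   (channels x components mixing matrix such that
#'   `A %*% S + residual + mean` reconstructs `X`, where `residual` is the
#'   signal content of directions discarded by the rank reduction), `W`
#'   (unmixing), `mean` (channel means), and `iterations`.
#' @details Whitening directions whose variance falls below `1e-8` of the
#'   leading one are dropped (they arise e.g. from interpolated channels),
#'   so the number of components can be slightly below the channel count;
#'   the discarded subspace is preserved untouched in the reconstruction.
#' @export
fast_ica <- function(X, seed = 1, max_iter = 500, tol = 1e-4,
                     stall_tol = 0.5) {
  m <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- Xc %*% t(Xc) / m
  e <- eigen(C, symmetric = TRUE)
  r <- sum(e$values > 1e-8 * max(e$values))
  ev <- e$values[seq_len(r)]
  V <- e$vectors[, seq_len(r), drop = FALSE]
  n <- r
  K <- (1 / sqrt(ev)) * t(V)                  # whitening: K %*% Xc is white
  Z <- K %*% Xc
  W <- withr::with_seed(seed, {
    qr.Q(qr(matrix(rnorm(n * n), n, n)))
  })
  it <- 0L
  converged <- FALSE
  W_prev2 <- NULL
  repeat {
    it <- it + 1L
    WX <- W %*% Z
    G <- tanh(WX)
    gprime <- rowMeans(1 - G^2)
    W1 <- G %*% t(Z) / m - gprime * W
    # symmetric decorrelation: W <- (W1 W1')^{-1/2} W1
    s <- eigen(W1 %*% t(W1), symmetric = TRUE)
    sv <- pmax(s$values, 1e-16)
    W1 <- s$vectors %*% ((1 / sqrt(sv)) * t(s$vectors)) %*% W1
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    # a symmetric update can flip-flop between two equivalent orderings of
    # the same components; compare against the iterate two steps back too
    delta2 <- if (is.null(W_prev2)) Inf else {
      max(abs(1 - abs(rowSums(W1 * W_prev2))))
    }
    W_prev2 <- W
    W <- W1
    if (min(delta, delta2) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) {
      if (min(delta, delta2) < stall_tol) break  # stable-but-rotating subspace
      stop_eeg(sprintf("ICA did not converge in %d iterations (delta %.2e)",
                       it, delta), "convergence")
    }
  }
  S <- W %*% Z
  # Xc = V D^{1/2} Z and Z = W' S, so the mixing matrix is A = V D^{1/2} W'
  A <- V %*% (sqrt(ev) * t(W))
  list(S = S, A = A, W = W %*% K, mean = mu, iterations = it,
       converged = converged)
}
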