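# Symmetric matrix function via eigendecomposition. `floor_ev` guards matrix
# roots/logs of nominally-SPD inputs against round-off; pass 0 for plain
# symmetric inputs (e.g. the matrix exponential of a tangent vector).
sym_fun <- function(P, f, floor_ev = 0) {
  P <- (P + t(P)) / 2
  e <- eigen(P, symmetric = TRUE)
  v <- if (floor_ev > 0) pmax(e$values, floor_ev) else e$values
  M <- e$vectors %*% (f(v) * t(e$vectors))
  (M + t(M)) / 2
}

spd_sqrt <- function(P) sym_fun(P, sqrt, floor_ev = 1e-12)
spd_invsqrt <- function(P) sym_fun(P, function(v) 1 / sqrt(v),
                                   floor_ev = 1e-12)
spd_logm <- function(P) sym_fun(P, log, floor_ev = 1e-12)
sym_expm <- function(S) sym_fun(S, exp)

assert_spd <- function(P, name = "matrix") {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop_eeg(sprintf("%s must be square", name), "shape")
  }
  if (max(abs(P - t(P))) > 1e-10 * max(1, max(abs(P)))) {
    stop_eeg(sprintf("%s is not symmetric", name), "domain")
  }
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_eeg(sprintf("%s is not positive definite", name), "domain")
  }
  invisible(P)
}

assert_same_dim <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop_eeg("dimension mismatch", "shape")
}

#' Shrunk spatial covariance of an epoch
#'
#' Sample covariance of a channels x samples epoch, blended with a scaled
#' identity target: `(1 - s) C + s * mean(diag(C)) I`. Any positive shrinkage
#' guarantees a symmetric positive-definite result; with `shrinkage = 0` a
#' numerically singular covariance raises an error.
#'
#' @param epoch channels x samples numeric matrix (microvolts).
#' @param shrinkage shrinkage fraction in `[0, 1)`.
#' @return the covariance matrix (microvolt^2).
#' @export
spd_covariance <- function(epoch, shrinkage = 0) {
  epoch <- as.matrix(epoch)
  L <- ncol(epoch)
  if (L < 2) stop_eeg("need more than one sample", "invalid_config")
  Xc <- epoch - rowMeans(epoch)
  C <- Xc %*% t(Xc) / (L - 1)
  C <- (C + t(C)) / 2
  if (shrinkage > 0) {
    C <- (1 - shrinkage) * C + shrinkage * mean(diag(C)) * diag(nrow(C))
  } else {
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= max(ev) * nrow(C) * .Machine$double.eps) {
      stop_eeg("singular covariance with shrinkage = 0", "singular")
    }
  }
  C
}

#' Exponential map on the SPD manifold
#'
#' Maps the symmetric tangent vector `S` at the base point `P` back to the
#' manifold under the affine-invariant metric:
#' `Exp_P(S) = P^{1/2} exp(P^{-1/2} S P^{-1/2}) P^{1/2}`.
#'
#' @param P SPD base point.
#' @param S symmetric tangent matrix of the same dimension.
#' @return an SPD matrix.
#' @export
exp_map <- function(P, S) {
  assert_spd(P, "P")
  assert_same_dim(P, S)
  if (max(abs(S - t(S))) > 1e-10 * max(1, max(abs(S)))) {
    stop_eeg("tangent vector must be symmetric", "domain")
  }
  Ph <- spd_sqrt(P)
  Pw <- spd_invsqrt(P)
  Ph %*% sym_expm(Pw %*% S %*% Pw) %*% Ph
}

#' Logarithmic map on the SPD manifold
#'
#' Inverse of [exp_map()]: the tangent vector at `P` pointing to `Pi`,
#' `Log_P(Pi) = P^{1/2} log(P^{-1/2} Pi P^{-1/2}) P^{1/2}`.
#'
#' @param P SPD base point.
#' @param Pi SPD target point.
#' @return a symmetric matrix; zero when `Pi == P`.
#' @export
log_map <- function(P, Pi) {
  assert_spd(P, "P")
  assert_spd(Pi, "Pi")
  assert_same_dim(P, Pi)
  Ph <- spd_sqrt(P)
  Pw <- spd_invsqrt(P)
  Ph %*% spd_logm(Pw %*% Pi %*% Pw) %*% Ph
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta(P1, P2) = || log(P1^{-1/2} P2 P1^{-1/2}) ||_F`, i.e. the root sum
#' of squared log generalized eigenvalues. Symmetric, zero iff equal, and
#' invariant under congruence `P -> W' P W`.
#'
#' @param P1,P2 SPD matrices of equal dimension.
#' @return a non-negative scalar.
#' @export
riemannian_distance <- function(P1, P2) {
  assert_spd(P1, "P1")
  assert_spd(P2, "P2")
  assert_same_dim(P1, P2)
  Pw <- spd_invsqrt(P1)
  M <- Pw %*% P2 %*% Pw
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(pmax(ev, 1e-300))^2))
}

#' Frechet (geometric) mean of SPD matrices
#'
#' Fixed-point iteration for the point `M` where the mean of the whitened
#' logarithms `log(M^{-1/2} Pi M^{-1/2})` vanishes, starting from the
#' arithmetic mean, with step halving on divergence.
#'
#' @param plist non-empty list of same-dimension SPD matrices.
#' @param tol convergence tolerance on the Frobenius norm of the mean
#'   tangent update (default 1e-8).
#' @param max_iter iteration cap (default 50).
#' @return the mean SPD matrix; attribute `iterations` logs the count.
#' @export
riemannian_mean <- function(plist, tol = 1e-8, max_iter = 50) {
  if (length(plist) == 0) stop_eeg("empty set", "invalid_config")
  if (length(plist) == 1) return(plist[[1]])
  M <- Reduce(`+`, plist) / length(plist)
  step <- 1
  prev_norm <- Inf
  for (it in seq_len(max_iter)) {
    Mw <- spd_invsqrt(M)
    Mh <- spd_sqrt(M)
    H <- Reduce(`+`, lapply(plist, function(P) {
      spd_logm(Mw %*% P %*% Mw)
    })) / length(plist)
    h <- sqrt(sum(H^2))
    if (h < tol) {
      attr(M, "iterations") <- it
      return(M)
    }
    if (h > prev_norm) step <- step / 2 else prev_norm <- h
    M <- Mh %*% sym_expm(step * H) %*% Mh
    M <- (M + t(M)) / 2
  }
  stop_eeg(sprintf("Frechet mean did not converge in %d iterations",
                   max_iter), "convergence")
}

#' Isometric vectorization of a symmetric matrix
#'
#' Flattens the upper triangle (column-major) with off-diagonal entries
#' scaled by sqrt(2), so the Euclidean norm of the vector equals the
#' Frobenius norm of the matrix. Inverse: [tangent_unvectorize()].
#'
#' @param S symmetric n x n matrix.
#' @return numeric vector of length `n(n+1)/2`.
#' @export
tangent_vectorize <- function(S) {
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop_eeg("input is not symmetric", "domain")
  }
  n <- nrow(S)
  w <- matrix(sqrt(2), n, n)
  diag(w) <- 1
  ut <- upper.tri(S, diag = TRUE)
  (S * w)[ut]
}

#' @rdname tangent_vectorize
#' @param v vector of length `n(n+1)/2`.
#' @export
tangent_unvectorize <- function(v) {
  n <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop_eeg("vector length is not n(n+1)/2 for integer n", "shape")
  }
  n <- as.integer(round(n))
  S <- matrix(0, n, n)
  S[upper.tri(S, diag = TRUE)] <- v
  S <- S + t(S) - diag(diag(S))
  w <- matrix(1 / sqrt(2), n, n)
  diag(w) <- 1
  off <- upper.tri(S) | lower.tri(S)
  S[off] <- S[off] * w[off]
  S
}

#' Map a set of SPD matrices to tangent-space feature vectors
#'
#' Resolves the base point (Frechet mean when `base = "mean"`), whitens each
#' matrix at the base and vectorizes its matrix logarithm:
#' `v_i = vec(log(B^{-1/2} P_i B^{-1/2}))` with the isometric
#' [tangent_vectorize()] flattening, so `||v_i||` equals the Riemannian
#' distance of `P_i` from the base and Euclidean geometry in the feature
#' space locally matches the manifold. Row order follows the input order.
#'
#' @param plist non-empty list of SPD matrices.
#' @param base an SPD base point, or `"mean"` (default) for the Frechet mean.
#' @param tol,max_iter passed to [riemannian_mean()] when `base = "mean"`.
#' @return a `tangent_vectors` object: list with `base`, `vectors`
#'   (m x n(n+1)/2 matrix) and `dim` (n).
#' @export
tangent_space <- function(plist, base = "mean", tol = 1e-8, max_iter = 50) {
  if (length(plist) == 0) stop_eeg("empty set", "invalid_config")
  if (identical(base, "mean")) {
    base <- riemannian_mean(plist, tol = tol, max_iter = max_iter)
  }
  assert_spd(base, "base")
  Bw <- spd_invsqrt(base)
  vecs <- t(vapply(plist, function(P) {
    tangent_vectorize(spd_logm(Bw %*% P %*% Bw))
  }, numeric(nrow(base) * (nrow(base) + 1) / 2)))
  structure(list(base = base, vectors = vecs, dim = nrow(base)),
            class = "tangent_vectors")
}

#' Reconstruct SPD matrices from tangent-space rows
#'
#' @param tv a `tangent_vectors` object.
#' @return list of SPD matrices.
#' @export
tangent_space_inverse <- function(tv) {
  stopifnot(inherits(tv, "tangent_vectors"))
  Bh <- spd_sqrt(tv$base)
  lapply(seq_len(nrow(tv$vectors)), function(i) {
    S <- tangent_unvectorize(tv$vectors[i, ])
    Bh %*% sym_expm(S) %*% Bh
  })
}
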