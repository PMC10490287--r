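#' Fit xDawn-style spatial filters per class
#'
#' For each class, the evoked prototype is the mean epoch, and the spatial
#' filters are the top generalized eigenvectors maximizing the Rayleigh
#' quotient of prototype variance against total signal variance (solved by
#' Cholesky whitening of the total covariance). Filter rows are
#' unit-normalized.
#'
#' @param eps a labeled `eeg_epochs` object with at least `nfilter + 1`
#'   epochs per class.
#' @param nfilter filters per class (default 6, so that with 4 classes the
#'   augmented covariances come out 48 x 48).
#' @return an `xdawn_model`: per-class `prototypes` (channels x samples) and
#'   `filters` (nfilter x channels), plus the class order.
#' @export
fit_xdawn <- function(eps, nfilter = 6) {
  stopifnot(inherits(eps, "eeg_epochs"))
  labs <- state_factor(eps$labels)
  classes <- levels(labs)
  counts <- table(labs)
  if (any(counts < nfilter + 1)) {
    stop_eeg(sprintf("class '%s' has fewer than nfilter + 1 epochs",
                     names(counts)[which.min(counts)]), "degenerate_class")
  }
  d <- dim(eps$data)
  n_ch <- d[1]
  if (nfilter > n_ch) {
    stop_eeg("nfilter cannot exceed the channel count", "invalid_config")
  }
  # total signal covariance from all concatenated epochs
  Xall <- matrix(eps$data, nrow = n_ch)
  Cx <- spd_covariance(Xall, shrinkage = 1e-9)
  Cx <- Cx + diag(1e-10 * mean(diag(Cx)), n_ch)
  R <- chol(Cx)
  Ainv <- backsolve(R, diag(n_ch))            # R^{-1}; A' Cx A = I
  prototypes <- list()
  filters <- list()
  for (k in classes) {
    idx <- which(labs == k)
    Pk <- apply(eps$data[, , idx, drop = FALSE], c(1, 2), mean)
    Cp <- spd_covariance(Pk, shrinkage = 1e-12)
    M <- t(Ainv) %*% Cp %*% Ainv
    eigM <- eigen((M + t(M)) / 2, symmetric = TRUE)
    V <- Ainv %*% eigM$vectors[, seq_len(nfilter), drop = FALSE]
    W <- t(V) / sqrt(rowSums(t(V)^2))          # unit-norm rows
    prototypes[[k]] <- Pk
    filters[[k]] <- W
  }
  structure(list(prototypes = prototypes, filters = filters,
                 classes = classes, nfilter = nfilter,
                 channel_names = eps$channel_names),
            class = "xdawn_model")
}

#' Augmented (super-trial) covariance features
#'
#' For each epoch X, stacks the filtered class prototypes (for all K classes)
#' over the filtered epoch signal (through all K filter blocks), giving
#' `2 * K * nfilter` rows, and returns the shrunk covariance of the stack.
#' With the defaults (K = 4, nfilter = 6) the matrices are 48 x 48.
#'
#' @param eps an `eeg_epochs` object matching the model's channels.
#' @param model an `xdawn_model` from [fit_xdawn()].
#' @param shrinkage covariance shrinkage (default 0.05, guaranteeing SPD).
#' @return list of SPD matrices, one per epoch (input order preserved).
#' @export
augment_covariances <- function(eps, model, shrinkage = 0.05) {
  stopifnot(inherits(eps, "eeg_epochs"), inherits(model, "xdawn_model"))
  d <- dim(eps$data)
  L <- d[2]
  if (ncol(model$prototypes[[1]]) != L) {
    stop_eeg("epoch length does not match model prototypes", "shape")
  }
  if (!identical(model$channel_names, eps$channel_names)) {
    stop_eeg("epoch channels do not match the fitted model", "shape")
  }
  proto_block <- do.call(rbind, lapply(model$classes, function(k) {
    model$filters[[k]] %*% model$prototypes[[k]]
  }))
  Wall <- do.call(rbind, model$filters)
  lapply(seq_len(d[3]), function(e) {
    X <- eps$data[, , e]
    spd_covariance(rbind(proto_block, Wall %*% X), shrinkage = shrinkage)
  })
}

#' Fit Fisher geodesic discriminant filtering on tangent coordinates
#'
#' Fisher discriminant analysis in the tangent space of the SPD manifold:
#' between-class versus (ridge-regularized) within-class scatter of the
#' tangent rows; the top `r` (at most `K - 1`) discriminant directions are
#' orthonormalized into a projection basis. The filtering operator
#' [apply_fgda()] projects tangent rows onto the basis and back, discarding
#' non-discriminative directions while keeping the ambient coordinates.
#'
#' @param vectors m x d matrix of tangent rows (or a `tangent_vectors`
#'   object).
#' @param labels per-row class labels.
#' @param r number of discriminant components (default `K - 1`).
#' @param ridge within-scatter ridge as a fraction of its mean diagonal
#'   (default 1e-3); `0` requires a non-singular within-class scatter.
#' @return an `fgda_model` with the centering vector `mu` and orthonormal
#'   basis `B` (d x r).
#' @export
fit_fgda <- function(vectors, labels, r = NULL, ridge = 1e-3) {
  if (inherits(vectors, "tangent_vectors")) vectors <- vectors$vectors
  X <- as.matrix(vectors)
  labs <- state_factor(labels)
  classes <- levels(labs)
  K <- length(classes)
  if (K < 2) stop_eeg("need at least two classes", "invalid_config")
  if (nrow(X) <= K) stop_eeg("need more rows than classes", "invalid_config")
  r <- r %||% (K - 1)
  d <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (k in classes) {
    idx <- which(labs == k)
    mk <- colMeans(X[idx, , drop = FALSE])
    Xc <- sweep(X[idx, , drop = FALSE], 2, mk)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + length(idx) * tcrossprod(mk - mu)
  }
  Sw <- Sw / nrow(X)
  Sb <- Sb / nrow(X)
  if (ridge > 0) {
    Sw <- Sw + ridge * mean(diag(Sw)) * diag(d)
  } else if (rcond_sym(Sw) < 1e-12) {
    stop_eeg("within-class scatter is singular; use a positive ridge",
             "singular")
  }
  M <- solve(Sw, Sb)
  e <- eigen(M)
  B <- Re(e$vectors[, seq_len(r), drop = FALSE])
  B <- qr.Q(qr(B))
  structure(list(mu = mu, B = B, r = r, classes = classes, ridge = ridge),
            class = "fgda_model")
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' @rdname fit_fgda
#' @param model an `fgda_model`.
#' @export
apply_fgda <- function(model, vectors) {
  if (inherits(vectors, "tangent_vectors")) vectors <- vectors$vectors
  X <- sweep(as.matrix(vectors), 2, model$mu)
  sweep(X %*% model$B %*% t(model$B), 2, model$mu, `+`)
}

#' PCA + ANOVA feature selection
#'
#' Centers the rows, projects onto the top `n_pca` principal components,
#' scores each retained component with a one-way ANOVA F statistic across
#' classes, and keeps the `k_anova` highest-scoring components (in their
#' original PCA order, so `k_anova = n_pca` is the identity on the PCA
#' output). The fitted transform is reusable on held-out rows via
#' `predict()`.
#'
#' @param vectors m x d feature matrix (or `tangent_vectors`).
#' @param labels per-row class labels.
#' @param n_pca number of principal components (capped at `min(m - 1, d)`).
#' @param k_anova number of components kept; must not exceed `n_pca`.
#' @return list with `model` (a `feature_selector`) and `features`
#'   (the reduced m x k matrix).
#' @export
select_features <- function(vectors, labels, n_pca = 60, k_anova = 40) {
  if (inherits(vectors, "tangent_vectors")) vectors <- vectors$vectors
  X <- as.matrix(vectors)
  if (k_anova > n_pca) {
    stop_eeg("k_anova cannot exceed n_pca", "invalid_config")
  }
  labs <- state_factor(labels)
  pc <- fit_pca(X, n_pca)
  scores <- pc$scores
  sel <- anova_keep(scores, labs, min(k_anova, ncol(scores)))
  model <- structure(list(center = pc$center, rotation = pc$rotation,
                          f_scores = sel$f, kept = sel$kept),
                     class = "feature_selector")
  list(model = model, features = scores[, sel$kept, drop = FALSE])
}

# centered PCA basis capped at the available rank
fit_pca <- function(X, n_pca) {
  n_eff <- min(n_pca, nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_eff)
  list(center = pc$center, rotation = pc$rotation, scores = pc$x)
}

# one-way ANOVA F per column; returns the top-k column indices in their
# original order (so k = ncol is the identity)
anova_keep <- function(scores, labs, k) {
  f <- vapply(seq_len(ncol(scores)), function(j) {
    s <- scores[, j]
    if (sd(s) < 1e-12) return(0)
    unname(stats::oneway.test(s ~ labs, var.equal = TRUE)$statistic)
  }, numeric(1))
  f[!is.finite(f)] <- 0
  list(f = f, kept = sort(order(f, decreasing = TRUE)[seq_len(k)]))
}

#' @export
predict.feature_selector <- function(object, newdata, ...) {
  X <- sweep(as.matrix(newdata), 2, object$center)
  (X %*% object$rotation)[, object$kept, drop = FALSE]
}

#' Fit the full epoch-to-feature pipeline
#'
#' Order: xDawn filters and augmented covariances -> Frechet mean ->
#' tangent-space vectorization -> PCA projection -> Fisher geodesic
#' discriminant filtering (in the PCA score space, where the within-class
#' scatter is well-conditioned) -> ANOVA selection. Every stage is fitted on
#' the supplied (training) epochs only; [transform_features()] applies the
#' frozen transforms to new epochs, so cross-validation never leaks labels.
#'
#' @param eps labeled training `eeg_epochs`.
#' @param nfilter xDawn filters per class (default 6).
#' @param shrinkage covariance shrinkage for the augmented covariances.
#' @param use_fgda apply FGDA filtering (default TRUE).
#' @param n_pca,k_anova selection dimensions (defaults 60 / 40; capped at the
#'   effective rank).
#' @param fgda_ridge ridge for the FGDA within-class scatter.
#' @return a `feature_pipeline` object; element `features` holds the training
#'   feature matrix, `labels` the training labels.
#' @export
fit_feature_pipeline <- function(eps, nfilter = 6, shrinkage = 0.05,
                                 use_fgda = TRUE, n_pca = 60, k_anova = 40,
                                 fgda_ridge = 1e-3) {
  if (k_anova > n_pca) {
    stop_eeg("k_anova cannot exceed n_pca", "invalid_config")
  }
  xd <- fit_xdawn(eps, nfilter = nfilter)
  covs <- augment_covariances(eps, xd, shrinkage = shrinkage)
  tv <- tangent_space(covs, base = "mean")
  labs <- state_factor(eps$labels)
  pc <- fit_pca(tv$vectors, n_pca)
  X <- pc$scores
  fg <- NULL
  if (use_fgda) {
    fg <- fit_fgda(X, labs, ridge = fgda_ridge)
    X <- apply_fgda(fg, X)
  }
  sel <- anova_keep(X, labs, min(k_anova, ncol(X)))
  structure(list(xdawn = xd, base = tv$base, pca = pc[c("center", "rotation")],
                 fgda = fg, kept = sel$kept, f_scores = sel$f,
                 shrinkage = shrinkage,
                 features = X[, sel$kept, drop = FALSE], labels = eps$labels,
                 tangent_dim = ncol(tv$vectors)),
            class = "feature_pipeline")
}

#' @rdname fit_feature_pipeline
#' @param pipeline a fitted `feature_pipeline`.
#' @export
transform_features <- function(pipeline, eps) {
  stopifnot(inherits(pipeline, "feature_pipeline"))
  covs <- augment_covariances(eps, pipeline$xdawn,
                              shrinkage = pipeline$shrinkage)
  tv <- tangent_space(covs, base = pipeline$base)
  X <- sweep(tv$vectors, 2, pipeline$pca$center) %*% pipeline$pca$rotation
  if (!is.null(pipeline$fgda)) X <- apply_fgda(pipeline$fgda, X)
  X[, pipeline$kept, drop = FALSE]
}
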