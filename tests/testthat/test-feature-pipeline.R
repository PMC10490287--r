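test_that("xDawn filters recover a planted prototype direction", {
  n_ch <- 6
  L <- 64
  n_ep <- 200
  withr::with_seed(1, {
    v <- rnorm(n_ch)
    v <- v / sqrt(sum(v^2))
    template <- sin(2 * pi * 8 * seq_len(L) / L)
    # evoked template at per-epoch SNR ~ 0.5; averaging 100 epochs makes the
    # prototype direction dominate its Rayleigh problem
    arr <- array(rnorm(n_ch * L * n_ep, sd = 1), dim = c(n_ch, L, n_ep))
    for (e in seq_len(n_ep)) arr[, , e] <- arr[, , e] + outer(v, template)
  })
  eps <- eegstate:::new_eeg_epochs(arr, rep(c("NE", "CA"), each = n_ep / 2),
                                   64, make_montage(n_ch)$channel)
  xd <- fit_xdawn(eps, nfilter = 2)
  w1 <- xd$filters[["NE"]][1, ]
  expect_gt(abs(sum(w1 * v)), 0.99)
  # unit-norm rows
  for (k in xd$classes) {
    expect_equal(unname(rowSums(xd$filters[[k]]^2)), rep(1, 2),
                 tolerance = 1e-10)
  }
  # identical epochs in two classes give identical filter blocks
  half <- n_ep / 2
  eps2 <- eps
  eps2$data[, , (half + 1):n_ep] <- eps2$data[, , 1:half]
  xd2 <- fit_xdawn(eps2, nfilter = 2)
  expect_equal(xd2$filters[["NE"]], xd2$filters[["CA"]], tolerance = 1e-8)

  # full-rank filter bank spans the channel space
  xd3 <- fit_xdawn(eps, nfilter = n_ch)
  expect_equal(qr(do.call(rbind, xd3$filters))$rank, n_ch)

  few <- eegstate:::new_eeg_epochs(arr[, , 1:4], c("NE", "NE", "NE", "CA"),
                                   64, make_montage(n_ch)$channel)
  expect_error(fit_xdawn(few, nfilter = 2),
               class = "eegstate_degenerate_class")
})

test_that("augmented covariances have the super-trial dimension and are SPD", {
  eps <- toy_epochs(n_per_class = 8, n_ch = 8, L = 64, seed = 2)
  xd <- fit_xdawn(eps, nfilter = 6)
  covs <- augment_covariances(eps, xd, shrinkage = 0.05)
  expect_length(covs, n_epochs(eps))
  expect_equal(dim(covs[[1]]), c(48, 48))     # 2 * K * nfilter, K = 4
  ev_min <- vapply(covs, function(C) {
    min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  expect_true(all(ev_min > 0))

  # K = 2, nfilter = 1 -> 4 x 4
  two <- toy_epochs(n_per_class = 6, n_ch = 4, L = 32,
                    scales = c(NE = 1, CA = 2), seed = 3)
  covs2 <- augment_covariances(two, fit_xdawn(two, nfilter = 1))
  expect_equal(dim(covs2[[1]]), c(4, 4))
})

test_that("FGDA recovers the separating axis and filters idempotently", {
  withr::with_seed(4, {
    X <- matrix(rnorm(200 * 10), 200)
    X[101:200, 3] <- X[101:200, 3] + 6      # classes differ on axis 3 only
  })
  labels <- rep(c("NE", "CA"), each = 100)
  fg <- fit_fgda(X, labels)
  expect_equal(ncol(fg$B), 1)
  expect_gt(abs(fg$B[3, 1]), 0.95)
  # closed-form two-class Fisher direction as oracle
  sw <- (cov(X[1:100, ]) + cov(X[101:200, ])) / 2
  fisher <- solve(sw, colMeans(X[101:200, ]) - colMeans(X[1:100, ]))
  fisher <- fisher / sqrt(sum(fisher^2))
  expect_gt(abs(sum(fg$B[, 1] * fisher)), 0.99)
  # projector idempotence
  once <- apply_fgda(fg, X)
  twice <- apply_fgda(fg, once)
  expect_lt(max(abs(twice - once)), 1e-10)
  # shuffled labels: filtered class means become indistinguishable
  withr::with_seed(5, {
    sh <- sample(labels)
  })
  fg_null <- fit_fgda(X, sh)
  filt <- apply_fgda(fg_null, X)
  gap <- colMeans(filt[sh == "NE", ]) - colMeans(filt[sh == "CA", ])
  pooled <- apply(filt, 2, sd)
  expect_lt(max(abs(gap) / (pooled + 1e-12)), 0.5)
  expect_error(fit_fgda(X[1:2, ], labels[1:2]),
               class = "eegstate_invalid_config")
})

test_that("PCA/ANOVA selection recovers low rank and ranks by class separation", {
  withr::with_seed(6, {
    B <- matrix(rnorm(20 * 2), 20, 2)
    S <- matrix(rnorm(80 * 2), 80, 2)
    X <- S %*% t(B)                            # exact rank 2
  })
  labels <- rep(c("NE", "CA"), each = 40)
  sel <- select_features(X, labels, n_pca = 2, k_anova = 2)
  recon <- sel$features %*% t(sel$model$rotation[, sel$model$kept]) +
    matrix(sel$model$center, 80, 20, byrow = TRUE)
  expect_lt(norm(recon - X, "F") / norm(X, "F"), 1e-10)

  # a planted separating component ranks first by F
  withr::with_seed(7, {
    Y <- matrix(rnorm(120 * 5), 120)
    Y[61:120, 4] <- Y[61:120, 4] + 4
  })
  lab2 <- rep(c("NE", "SS"), each = 60)
  sel2 <- select_features(Y, lab2, n_pca = 5, k_anova = 1)
  j <- which.max(sel2$model$f_scores)
  expect_equal(sel2$model$kept, j)
  expect_gt(abs(sel2$model$rotation[4, j]), 0.9)
  # F-scores agree with the base one-way ANOVA oracle
  scores <- sweep(Y, 2, sel2$model$center) %*% sel2$model$rotation
  for (c_i in 1:5) {
    f_oracle <- unname(summary(stats::aov(scores[, c_i] ~ factor(lab2)))[[1]][
      "factor(lab2)", "F value"])
    expect_equal(sel2$model$f_scores[c_i], f_oracle, tolerance = 1e-8)
  }
  # k_anova = n_pca keeps the PCA output unchanged
  sel3 <- select_features(Y, lab2, n_pca = 4, k_anova = 4)
  expect_equal(sel3$features, scores[, 1:4], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(select_features(Y, lab2, n_pca = 2, k_anova = 3),
               class = "eegstate_invalid_config")
})

test_that("the fitted pipeline transforms held-out epochs consistently", {
  eps <- toy_epochs(n_per_class = 15, n_ch = 8, L = 64, seed = 8)
  tr_idx <- as.vector(sapply(0:3, function(k) k * 15 + 1:10))
  vl_idx <- setdiff(seq_len(60), tr_idx)
  pipe <- fit_feature_pipeline(subset_epochs(eps, tr_idx),
                               n_pca = 20, k_anova = 10)
  expect_equal(pipe$tangent_dim, 1176)
  expect_equal(nrow(pipe$features), 40)
  Xvl <- transform_features(pipe, subset_epochs(eps, vl_idx))
  expect_equal(dim(Xvl), c(20, ncol(pipe$features)))
  # deterministic given inputs
  pipe2 <- fit_feature_pipeline(subset_epochs(eps, tr_idx),
                                n_pca = 20, k_anova = 10)
  expect_identical(pipe$features, pipe2$features)
  expect_identical(transform_features(pipe2, subset_epochs(eps, vl_idx)), Xvl)
})
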