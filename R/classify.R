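#' Seeded stratified k-fold plan
#'
#' Shuffles each class's indices (seeded) and deals them round-robin into
#' `k` folds, so per-fold class counts differ by at most one from an even
#' split. Every sample is validation exactly once.
#'
#' @param labels per-sample class labels; every class needs at least `k`
#'   members.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a `cv_plan`: list with integer `fold` per sample, `k`, `seed`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1) {
  labs <- state_factor(labels)
  counts <- table(labs)
  if (any(counts < k)) {
    stop_eeg(sprintf("class '%s' has fewer than k = %d members",
                     names(counts)[which.min(counts)], k), "stratification")
  }
  fold <- integer(length(labs))
  withr::with_seed(seed, {
    for (cls in levels(labs)) {
      idx <- sample(which(labs == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(fold = fold, k = as.integer(k), seed = seed),
            class = "cv_plan")
}

check_features <- function(x) {
  bad <- which(!apply(is.finite(as.matrix(x)), 1, all))
  if (length(bad) > 0) {
    stop_eeg(paste("non-finite feature values in row(s):",
                   paste(head(bad, 10), collapse = ", ")), "data_quality")
  }
}

#' Fit one ensemble classifier family
#'
#' Families: `rf` (random forest, 200 trees), `ert` (extremely randomized
#' trees, 200 trees, whole-dataset training without bootstrap, one random
#' split threshold per candidate feature), `gtb` (gradient tree boosting,
#' 100 rounds, depth 3, learning rate 0.1, multinomial log-loss), `adaboost`
#' (SAMME.R boosting of shallow trees, 50 iterations). Tree growing is
#' delegated to ranger / xgboost / rpart; everything around them (CV, voting,
#' scoring) is native.
#'
#' @param x feature matrix (rows = samples).
#' @param y class labels.
#' @param family one of "rf", "ert", "gtb", "adaboost".
#' @param seed integer seed; fits are deterministic given the seed.
#' @return a `state_model`.
#' @export
fit_state_model <- function(x, y, family = c("rf", "ert", "gtb", "adaboost"),
                            seed = 1) {
  family <- match.arg(family)
  x <- as.matrix(x)
  check_features(x)
  labs <- state_factor(y)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- switch(
    family,
    rf = ranger::ranger(x = x, y = labs, num.trees = 200,
                        probability = TRUE, seed = seed, num.threads = 1),
    ert = ranger::ranger(x = x, y = labs, num.trees = 200,
                         probability = TRUE, splitrule = "extratrees",
                         num.random.splits = 1, replace = FALSE,
                         sample.fraction = 1, seed = seed, num.threads = 1),
    gtb = {
      withr::with_seed(seed, {
        xgboost::xgboost(x, labs, nrounds = 100, max_depth = 3,
                         learning_rate = 0.1, nthreads = 1, verbosity = 0)
      })
    },
    adaboost = samme_r_fit(x, labs, n_iter = 50, maxdepth = 2, seed = seed)
  )
  structure(list(fit = fit, family = family, levels = levels(labs)),
            class = "state_model")
}

#' @export
predict.state_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  prob <- switch(
    object$family,
    rf = ,
    ert = {
      p <- predict(object$fit, data = as.data.frame(newdata),
                   num.threads = 1)$predictions
      p[, object$levels, drop = FALSE]
    },
    gtb = {
      p <- predict(object$fit, newdata, type = "response")
      if (is.null(dim(p))) {                  # binary: P(second level)
        p <- cbind(1 - p, p)
        colnames(p) <- object$levels
      }
      p[, object$levels, drop = FALSE]
    },
    adaboost = samme_r_prob(object$fit, newdata)
  )
  colnames(prob) <- object$levels
  list(class = factor(object$levels[max.col(prob, ties.method = "first")],
                      levels = object$levels),
       prob = prob)
}

# --- SAMME.R boosting over rpart trees --------------------------------------

samme_r_fit <- function(x, y, n_iter = 50, maxdepth = 2, seed = 1,
                        eps = 1e-10) {
  n <- nrow(x)
  K <- nlevels(y)
  df <- data.frame(.y = y, x, check.names = FALSE)
  Y <- matrix(-1 / (K - 1), n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  w <- rep(1 / n, n)
  trees <- vector("list", n_iter)
  withr::with_seed(seed, {
    for (t in seq_len(n_iter)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w * n,
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = maxdepth, cp = 0, minsplit = 2,
                            minbucket = 1, xval = 0))
      p <- predict(fit, df, type = "prob")[, levels(y), drop = FALSE]
      p <- pmax(p, eps)
      p <- p / rowSums(p)
      trees[[t]] <- fit
      w <- w * exp(-((K - 1) / K) * rowSums(Y * log(p)))
      s <- sum(w)
      if (!is.finite(s) || s <= 0) break
      w <- w / s
    }
  })
  list(trees = trees[!vapply(trees, is.null, logical(1))],
       levels = levels(y), K = K, eps = eps)
}

samme_r_prob <- function(model, newdata) {
  nd <- as.data.frame(newdata)
  K <- model$K
  H <- matrix(0, nrow(nd), K)
  for (fit in model$trees) {
    p <- predict(fit, nd, type = "prob")[, model$levels, drop = FALSE]
    p <- pmax(p, model$eps)
    p <- p / rowSums(p)
    lp <- log(p)
    H <- H + (K - 1) * (lp - rowMeans(lp))
  }
  # softmax of the aggregated additive scores
  H <- H - apply(H, 1, max)
  P <- exp(H / ((K - 1) * max(1, length(model$trees))))
  P / rowSums(P)
}

#' Soft-voting combination of class-probability outputs
#'
#' Averages the per-model probability matrices (unweighted) and predicts the
#' argmax of the mean, breaking exact ties toward the lowest class index.
#'
#' @param prob_list list of m x K probability matrices with identical shape
#'   and column order; rows must sum to 1 (tolerance 1e-6).
#' @return factor of predicted labels (attribute `prob` holds the averaged
#'   matrix).
#' @export
soft_vote <- function(prob_list) {
  if (length(prob_list) == 0) stop_eeg("no probability matrices", "shape")
  dims <- lapply(prob_list, dim)
  if (length(unique(vapply(dims, paste, collapse = "x",
                           FUN.VALUE = character(1)))) != 1) {
    stop_eeg("probability matrices differ in shape", "shape")
  }
  for (p in prob_list) {
    if (max(abs(rowSums(p) - 1)) > 1e-6) {
      stop_eeg("rows of a probability matrix do not sum to 1", "shape")
    }
  }
  mean_p <- Reduce(`+`, prob_list) / length(prob_list)
  lv <- colnames(prob_list[[1]])
  pred <- factor(lv[max.col(mean_p, ties.method = "first")], levels = lv)
  attr(pred, "prob") <- mean_p
  pred
}

#' Cross-validated ensemble evaluation of an epoch set
#'
#' For each fold of the stratified plan, fits the full feature pipeline on
#' the training epochs, transforms the validation epochs with the frozen
#' transforms, trains every requested classifier family, and collects
#' validation predictions. A soft-voting hybrid over `vote` is added. Pooled
#' predictions are scored with [score_predictions()].
#'
#' @param eps labeled `eeg_epochs`.
#' @param plan a [stratified_kfold()] plan over the epochs (built from the
#'   labels and `seed` when `NULL`).
#' @param families classifier families to train.
#' @param vote families entering the soft vote (default rf, ert, gtb).
#' @param seed integer seed (folds and model fits).
#' @param ... passed to [fit_feature_pipeline()].
#' @return list with `reports` (one `state_report` per family and for
#'   `"voting"`), `predictions`, `probabilities` and the `plan`.
#' @export
crossval_pipeline <- function(eps, plan = NULL,
                              families = c("rf", "ert", "gtb", "adaboost"),
                              vote = c("rf", "ert", "gtb"), seed = 1, ...) {
  stopifnot(inherits(eps, "eeg_epochs"))
  labs <- state_factor(eps$labels)
  plan <- plan %||% stratified_kfold(labs, k = 5, seed = seed)
  k <- plan$k
  n <- n_epochs(eps)
  lv <- levels(labs)
  prob <- lapply(families, function(f) matrix(NA_real_, n, length(lv),
                                              dimnames = list(NULL, lv)))
  names(prob) <- families
  for (f in seq_len(k)) {
    tr <- which(plan$fold != f)
    vl <- which(plan$fold == f)
    pipe <- fit_feature_pipeline(subset_epochs(eps, tr), ...)
    Xtr <- pipe$features
    Xvl <- transform_features(pipe, subset_epochs(eps, vl))
    for (fam in families) {
      m <- fit_state_model(Xtr, labs[tr], family = fam, seed = seed + f)
      prob[[fam]][vl, ] <- predict(m, Xvl)$prob
    }
  }
  predictions <- lapply(prob, function(p) {
    factor(lv[max.col(p, ties.method = "first")], levels = lv)
  })
  if (length(vote) > 0 && all(vote %in% families)) {
    vp <- soft_vote(prob[vote])
    predictions$voting <- vp
    prob$voting <- attr(vp, "prob")
  }
  reports <- lapply(predictions, score_predictions, labels = labs,
                    fold = plan$fold)
  list(reports = reports, predictions = predictions, probabilities = prob,
       plan = plan)
}
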