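#' Learn per-channel peak-to-peak rejection thresholds by cross-validation
#'
#' For each channel, candidate thresholds from `grid` are scored fold-wise:
#' the mean time course of the training epochs passing the threshold on that
#' channel is compared (RMSE) to the pointwise median time course of the
#' validation epochs — the robust criterion behind data-driven rejection
#' thresholds. The threshold minimizing the cross-validated error is kept
#' (ties toward the smaller candidate). Folds are a seeded shuffle, so the
#' result is deterministic given the seed.
#'
#' @param eps an `eeg_epochs` object with at least `2 * cv_folds` epochs.
#' @param grid candidate thresholds in microvolts, shared by all channels;
#'   `NULL` (default) builds a per-channel grid from midpoints between
#'   consecutive quantiles of that channel's observed peak-to-peak values,
#'   plus a candidate 5% above the channel maximum so an all-clean channel
#'   can keep every epoch.
#' @param cv_folds number of folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @param kappa consensus fraction of bad channels above which an epoch is
#'   dropped rather than repaired (default 0.5).
#' @param rho maximum number of channels interpolated per epoch (default 4).
#' @return a `rejection_model`: per-channel `tau`, plus `kappa`, `rho`,
#'   the grid, fold count and seed.
#' @export
learn_thresholds <- function(eps, grid = NULL, cv_folds = 5, seed = 1,
                             kappa = 0.5, rho = 4) {
  stopifnot(inherits(eps, "eeg_epochs"))
  n_ep <- n_epochs(eps)
  if (n_ep < 2 * cv_folds) {
    stop_eeg("need at least 2 * cv_folds epochs to learn thresholds",
             "invalid_config")
  }
  if (!is.null(grid) && length(grid) == 0) {
    stop_eeg("empty threshold grid", "invalid_config")
  }
  ptp <- epoch_ptp(eps)                      # channels x epochs
  if (!is.null(grid)) grid <- sort(grid)
  folds <- withr::with_seed(seed, {
    sample(rep_len(seq_len(cv_folds), n_ep))
  })
  n_ch <- dim(eps$data)[1]
  tau <- numeric(n_ch)
  used_grid <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    X <- eps$data[ch, , ]                    # samples x epochs
    p <- ptp[ch, ]
    cand <- grid %||% {
      q <- quantile(p, probs = seq(0, 1, length.out = 21), names = FALSE)
      sort(unique(c((q[-1] + q[-21]) / 2, max(p) * 1.05)))
    }
    # fold-wise CV error of each candidate: RMSE between the mean of the
    # training epochs passing the threshold and the pointwise median of the
    # validation epochs (cumulative sums over ptp-sorted epochs make every
    # candidate an O(1) lookup)
    err <- numeric(length(cand))
    for (f in seq_len(cv_folds)) {
      tr <- which(folds != f)
      vl <- which(folds == f)
      ord <- tr[order(p[tr])]
      cs <- X[, ord, drop = FALSE]
      for (j in seq_len(ncol(cs))[-1]) cs[, j] <- cs[, j] + cs[, j - 1]
      m_val <- apply(X[, vl, drop = FALSE], 1, median)
      ks <- findInterval(cand, sort(p[tr]))
      err <- err + vapply(ks, function(k) {
        if (k == 0) return(Inf)
        sqrt(mean((cs[, k] / k - m_val)^2))
      }, numeric(1))
    }
    if (all(!is.finite(err))) {
      stop_eeg(sprintf("all candidate thresholds reject every epoch on channel %s",
                       eps$channel_names[ch]), "degenerate_threshold")
    }
    # the criterion is nearly flat (sample noise) across the clean bulk and
    # rises sharply once artifact epochs enter the mean: keep the most
    # permissive candidate whose error is within 2% of the minimum
    ok <- is.finite(err) & err <= min(err) * 1.02 + 1e-300
    tau[ch] <- max(cand[ok])
    used_grid[[ch]] <- cand
  }
  names(tau) <- eps$channel_names
  grid <- if (is.null(grid)) used_grid else grid
  structure(list(tau = tau, kappa = kappa, rho = rho, grid = grid,
                 cv_folds = cv_folds, seed = seed),
            class = "rejection_model")
}

#' @export
print.rejection_model <- function(x, ...) {
  cat(sprintf("<rejection_model> %d channels, kappa=%.2f, rho=%d\n",
              length(x$tau), x$kappa, x$rho))
  cat(sprintf("tau range: %.1f - %.1f uV\n", min(x$tau), max(x$tau)))
  invisible(x)
}

#' Interpolate one bad channel from its neighbors
#'
#' Replaces the bad channel's time course by the inverse-squared-distance
#' weighted combination of the good channels' time courses, using the montage
#' sensor positions. Other channels are untouched.
#'
#' @param epoch channels x samples matrix (rows named or ordered as
#'   `channels`).
#' @param bad name of the channel to rebuild.
#' @param montage an [make_montage()] result covering all channels.
#' @param channels channel names for the rows of `epoch`.
#' @return the repaired channels x samples matrix.
#' @export
interpolate_channel <- function(epoch, bad, montage,
                                channels = rownames(epoch)) {
  good <- setdiff(channels, bad)
  if (length(good) < 3) {
    stop_eeg("need at least 3 good channels to interpolate", "interpolation")
  }
  pos <- montage_positions(montage, channels)
  bi <- match(bad, channels)
  if (is.na(bi)) stop_eeg("bad channel not found in epoch", "montage")
  gi <- match(good, channels)
  d2 <- rowSums(sweep(pos[gi, , drop = FALSE], 2, pos[bi, ])^2)
  w <- 1 / d2
  w <- w / sum(w)
  out <- epoch
  out[bi, ] <- as.numeric(w %*% epoch[gi, , drop = FALSE])
  out
}

#' Apply a rejection model: repair or drop epochs
#'
#' Per epoch, channels whose peak-to-peak amplitude exceeds their learned
#' threshold are bad. If the bad fraction exceeds `kappa` the epoch is
#' dropped; otherwise the worst `min(n_bad, rho)` channels are interpolated
#' from their neighbors and the epoch kept. Every decision is logged.
#'
#' @param eps an `eeg_epochs` object.
#' @param model a `rejection_model` from [learn_thresholds()] whose channels
#'   match `eps`.
#' @param montage sensor montage for interpolation.
#' @return list with `epochs` (the repaired/kept set) and `log`, a tibble
#'   with one row per input epoch: `epoch_id`, `decision`
#'   (kept/repaired/dropped), `n_bad`, `channels_interpolated`.
#' @export
apply_reject <- function(eps, model, montage) {
  stopifnot(inherits(eps, "eeg_epochs"), inherits(model, "rejection_model"))
  if (!identical(names(model$tau), eps$channel_names)) {
    stop_eeg("model channels do not match epoch channels", "montage")
  }
  montage_positions(montage, eps$channel_names)   # validates coverage
  ptp <- epoch_ptp(eps)
  n_ch <- dim(eps$data)[1]
  n_ep <- n_epochs(eps)
  decision <- character(n_ep)
  n_bad_v <- integer(n_ep)
  interp <- character(n_ep)
  keep <- logical(n_ep)
  data <- eps$data
  for (e in seq_len(n_ep)) {
    bad <- which(ptp[, e] > model$tau)
    n_bad_v[e] <- length(bad)
    if (length(bad) == 0) {
      decision[e] <- "kept"; keep[e] <- TRUE; interp[e] <- ""
    } else if (length(bad) / n_ch > model$kappa) {
      decision[e] <- "dropped"; keep[e] <- FALSE; interp[e] <- ""
    } else {
      worst <- bad[order(ptp[bad, e], decreasing = TRUE)]
      worst <- worst[seq_len(min(length(worst), model$rho))]
      ep <- data[, , e]
      rownames(ep) <- eps$channel_names
      for (b in worst) {
        ep <- interpolate_channel(ep, eps$channel_names[b], montage)
      }
      data[, , e] <- ep
      decision[e] <- "repaired"; keep[e] <- TRUE
      interp[e] <- paste(eps$channel_names[worst], collapse = ";")
    }
  }
  log <- tibble::tibble(epoch_id = eps$epoch_ids, decision = decision,
                        n_bad = n_bad_v, channels_interpolated = interp)
  out <- eps
  out$data <- data
  out <- subset_epochs(out, which(keep), drop_reason = "rejected")
  repaired_ids <- eps$epoch_ids[decision == "repaired"]
  sel <- out$flags$epoch_id %in% repaired_ids
  out$flags$status[sel] <- "repaired"
  out$flags$reason[sel] <- "channels_interpolated"
  list(epochs = out, log = log)
}

#' Remove blink components by ICA with a frontal surrogate channel
#'
#' Concatenates the epochs, runs a seeded fast fixed-point ICA (as many
#' components as channels), zeroes every component whose absolute correlation
#' with the surrogate channel's time course is at least `r_thresh`, and
#' reconstructs and re-splits the epochs. The surrogate (default `Fp1`)
#' stands in for an electrooculogram.
#'
#' @param eps an `eeg_epochs` object.
#' @param surrogate surrogate ocular channel name (default "Fp1").
#' @param r_thresh absolute-correlation threshold for flagging a component as
#'   ocular (default 0.8).
#' @param seed seed for the ICA initialisation.
#' @param max_iter,tol ICA fixed-point iteration controls.
#' @return the cleaned `eeg_epochs`; attribute `n_removed` carries the count
#'   of zeroed components.
#' @export
remove_blinks <- function(eps, surrogate = "Fp1", r_thresh = 0.8, seed = 1,
                          max_iter = 500, tol = 1e-4) {
  stopifnot(inherits(eps, "eeg_epochs"))
  si <- match(surrogate, eps$channel_names)
  if (is.na(si)) {
    stop_eeg(sprintf("surrogate channel '%s' not present", surrogate),
             "missing_channel")
  }
  d <- dim(eps$data)
  X <- matrix(eps$data, nrow = d[1], ncol = d[2] * d[3])
  ica <- fast_ica(X, seed = seed, max_iter = max_iter, tol = tol)
  S <- ica$S                                   # components x time
  resid <- (X - ica$mean) - ica$A %*% S        # rank-reduction remainder
  r <- suppressWarnings(
    abs(apply(S, 1, function(s) stats::cor(s, X[si, ]))))
  r[is.na(r)] <- 0
  remove <- which(r >= r_thresh)
  S[remove, ] <- 0
  Xc <- ica$A %*% S + resid + ica$mean         # mixing back + channel means
  out <- eps
  out$data <- array(Xc, dim = d)
  attr(out, "n_removed") <- length(remove)
  out
}

#' Run the full repair sequence on gated epochs
#'
#' Order: learn/apply per-channel rejection thresholds, remove blink
#' components by ICA, then learn (or reuse) thresholds and reject once more.
#' A second pass never increases the epoch count.
#'
#' @param eps a gated `eeg_epochs` object (see [ptp_gate()]).
#' @param montage sensor montage.
#' @param grid,cv_folds,seed,kappa,rho threshold-learning controls, see
#'   [learn_thresholds()].
#' @param surrogate,r_thresh blink-removal controls, see [remove_blinks()].
#' @param relearn if `TRUE` (default) the second rejection pass re-learns
#'   thresholds on the blink-cleaned data; otherwise the first model is
#'   reused.
#' @return list with `epochs`, `log1`, `log2` (the two rejection logs) and
#'   `n_blink_components`.
#' @export
repair_pipeline <- function(eps, montage, grid = NULL, cv_folds = 5, seed = 1,
                            kappa = 0.5, rho = 4, surrogate = "Fp1",
                            r_thresh = 0.8, relearn = TRUE) {
  m1 <- learn_thresholds(eps, grid = grid, cv_folds = cv_folds, seed = seed,
                         kappa = kappa, rho = rho)
  r1 <- apply_reject(eps, m1, montage)
  cleaned <- remove_blinks(r1$epochs, surrogate = surrogate,
                           r_thresh = r_thresh, seed = seed)
  m2 <- if (relearn) {
    learn_thresholds(cleaned, grid = grid, cv_folds = cv_folds, seed = seed,
                     kappa = kappa, rho = rho)
  } else m1
  r2 <- apply_reject(cleaned, m2, montage)
  list(epochs = r2$epochs, log1 = r1$log, log2 = r2$log,
       n_blink_components = attr(cleaned, "n_removed"))
}

#' Serialize a repair log to JSON
#'
#' @param log the `log` tibble from [apply_reject()] (or `log1`/`log2` from
#'   [repair_pipeline()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_repair_log <- function(log, path) {
  jsonlite::write_json(log, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
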