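#' Fixed-length labeled epoch container
#'
#' Internal constructor. Epochs are stored as a channels x samples x epochs
#' array; `flags` is a provenance tibble that keeps one row for every epoch
#' ever seen (kept / dropped / repaired, with a reason), keyed by the stable
#' `epoch_id` assigned at segmentation time.
#'
#' @keywords internal
new_eeg_epochs <- function(array3d, labels, sample_rate, channel_names,
                           flags = NULL, epoch_ids = NULL) {
  stopifnot(length(dim(array3d)) == 3L)
  n_ep <- dim(array3d)[3]
  if (length(labels) != n_ep) {
    stop_eeg("label count must equal epoch count", "format_error")
  }
  epoch_ids <- epoch_ids %||% seq_len(n_ep)
  flags <- flags %||% tibble::tibble(epoch_id = epoch_ids, status = "kept",
                                     reason = NA_character_)
  structure(list(data = array3d, labels = as.character(labels),
                 sample_rate = sample_rate,
                 channel_names = channel_names,
                 epoch_ids = epoch_ids, flags = flags),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[3], d[1], d[2], x$sample_rate))
  tab <- table(state_factor(x$labels))
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  st <- table(x$flags$status)
  cat("flags: ", paste(sprintf("%s=%d", names(st), st), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param eps an `eeg_epochs` object.
#' @return integer count of retained epochs.
#' @export
n_epochs <- function(eps) dim(eps$data)[3]

#' Subset an epoch set by retained-epoch index
#'
#' Keeps labels, ids and the full provenance flag table aligned; `drop_reason`
#' marks the complement as dropped in the flags.
#'
#' @param eps an `eeg_epochs` object.
#' @param idx integer indices into the currently retained epochs.
#' @param drop_reason optional string recorded for epochs not in `idx`.
#' @return an `eeg_epochs` object.
#' @export
subset_epochs <- function(eps, idx, drop_reason = NULL) {
  idx <- as.integer(idx)
  flags <- eps$flags
  if (!is.null(drop_reason)) {
    dropped_ids <- eps$epoch_ids[setdiff(seq_len(n_epochs(eps)), idx)]
    sel <- flags$epoch_id %in% dropped_ids
    flags$status[sel] <- "dropped"
    flags$reason[sel] <- drop_reason
  }
  new_eeg_epochs(eps$data[, , idx, drop = FALSE], eps$labels[idx],
                 eps$sample_rate, eps$channel_names, flags,
                 eps$epoch_ids[idx])
}

# per-epoch, per-channel peak-to-peak amplitudes: channels x epochs matrix
epoch_ptp <- function(eps) {
  apply(eps$data, c(1, 3), function(v) max(v) - min(v))
}

#' Band-pass filter a recording with a zero-phase FIR filter
#'
#' Designs a linear-phase windowed-sinc (Hamming) band-pass filter and applies
#' it forward and backward (zero phase) with odd-symmetric edge padding, so
#' the filtered signal stays aligned with the per-sample labels. The filter
#' order follows a transition width of `max(low, 2)` Hz.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz (defaults 1 and 50).
#' @return the filtered [eeg_recording()], same shape and labels.
#' @export
bandpass_fir <- function(rec, low = 1, high = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  if (!(low > 0 && high > low)) {
    stop_eeg("need 0 < low < high", "invalid_config")
  }
  if (high >= fs / 2) {
    stop_eeg("high cutoff must be below the Nyquist frequency",
             "invalid_config")
  }
  tw <- max(low, 2)
  ord <- ceiling(3.3 * fs / tw)
  if (ord %% 2 == 1) ord <- ord + 1          # type-I (odd length) FIR
  b <- as.numeric(signal::fir1(ord, c(low, high) / (fs / 2), type = "pass"))
  nt <- length(b)
  out <- rec
  out$data <- t(apply(rec$data, 1, zero_phase_filter, b = b, nt = nt))
  rownames(out$data) <- rec$channel_names
  out
}

# odd-reflection padding + forward/backward FIR pass (zero phase)
zero_phase_filter <- function(x, b, nt) {
  n <- length(x)
  pad <- min(3L * nt, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filter(b, 1, xp))
  y <- rev(as.numeric(signal::filter(b, 1, rev(y))))
  y[pad + seq_len(n)]
}

#' Segment a labeled recording into fixed-length epochs
#'
#' Cuts consecutive non-overlapping windows of `length` seconds; a trailing
#' partial window is discarded. Each epoch's label is the majority per-sample
#' label inside the window, with ties broken toward the label that starts
#' earlier in the window.
#'
#' @param rec a labeled [eeg_recording()].
#' @param length window length in seconds (default 1); `length * sample_rate`
#'   must be an integer.
#' @param overlap fractional overlap between consecutive windows (default 0).
#' @return an `eeg_epochs` object.
#' @export
epoch_fixed <- function(rec, length = 1, overlap = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$labels)) {
    stop_eeg("recording has no labels; epoching requires a labeled recording",
             "missing_label")
  }
  L <- length * rec$sample_rate
  if (abs(L - round(L)) > 1e-9) {
    stop_eeg("length * sample_rate must be an integer", "invalid_config")
  }
  L <- as.integer(round(L))
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  n <- ncol(rec$data)
  starts <- seq.int(1L, n - L + 1L, by = step)
  arr <- array(0, dim = c(nrow(rec$data), L, length(starts)))
  labs <- character(length(starts))
  for (i in seq_along(starts)) {
    win <- starts[i] + seq_len(L) - 1L
    arr[, , i] <- rec$data[, win]
    wl <- rec$labels[win]
    counts <- table(wl)
    top <- names(counts)[counts == max(counts)]
    labs[i] <- if (length(top) == 1L) top else {
      # tie: earliest-starting label in the window wins
      wl[match(TRUE, wl %in% top)]
    }
  }
  new_eeg_epochs(arr, labs, rec$sample_rate, rec$channel_names)
}

#' Gate epochs by peak-to-peak amplitude
#'
#' Drops an epoch iff any channel's peak-to-peak amplitude exceeds `max_ptp`
#' (gross artifact) or any channel's falls below `min_ptp` (dead channel).
#' Decisions are recorded in the provenance flags.
#'
#' @param eps an `eeg_epochs` object.
#' @param max_ptp,min_ptp thresholds in microvolts (defaults 700 and 1).
#' @return the gated `eeg_epochs` object.
#' @export
ptp_gate <- function(eps, max_ptp = 700, min_ptp = 1) {
  stopifnot(inherits(eps, "eeg_epochs"))
  if (n_epochs(eps) == 0) stop_eeg("empty epoch set", "invalid_config")
  if (max_ptp <= min_ptp) {
    stop_eeg("max_ptp must exceed min_ptp", "invalid_config")
  }
  ptp <- epoch_ptp(eps)
  too_high <- apply(ptp, 2, max) > max_ptp
  too_low <- apply(ptp, 2, min) < min_ptp
  keep <- which(!too_high & !too_low)
  out <- subset_epochs(eps, keep, drop_reason = "ptp_gate")
  # refine the recorded reason for dropped epochs
  dropped_ids <- eps$epoch_ids[too_high | too_low]
  reason <- ifelse(too_high[too_high | too_low], "ptp_above_max",
                   "ptp_below_min")
  sel <- match(dropped_ids, out$flags$epoch_id)
  out$flags$reason[sel] <- reason
  out
}

#' Undersample epochs to balance class counts
#'
#' Downsamples every class uniformly at random (seeded) to the minority class
#' count; the relative order of the retained epochs is preserved.
#'
#' @param eps an `eeg_epochs` object with at least two classes.
#' @param seed integer seed for the subsampling.
#' @return a balanced `eeg_epochs` object.
#' @export
undersample_balance <- function(eps, seed = 1) {
  stopifnot(inherits(eps, "eeg_epochs"))
  counts <- table(eps$labels)
  if (length(counts) < 2) {
    stop_eeg("undersampling needs at least two classes present",
             "degenerate_class")
  }
  if (any(counts == 0)) stop_eeg("a class has zero epochs", "degenerate_class")
  m <- min(counts)
  keep <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(k) {
      idx <- which(eps$labels == k)
      if (length(idx) > m) sort(sample(idx, m)) else idx
    }))
  })
  subset_epochs(eps, sort(keep), drop_reason = "undersampled")
}

#' Write / read an epoch container as plain text
#'
#' The container is stored as a long CSV (epoch, sample, one column per
#' channel) plus a sidecar CSV with per-epoch labels and provenance flags,
#' and a small YAML key-value file with the sample rate and channel names.
#'
#' @param eps an `eeg_epochs` object.
#' @param prefix file path prefix; writes `<prefix>_data.csv`,
#'   `<prefix>_epochs.csv` and `<prefix>_meta.yaml`.
#' @return `prefix`, invisibly (for `write_epochs`); an `eeg_epochs`
#'   (for `read_epochs`).
#' @export
write_epochs <- function(eps, prefix) {
  d <- dim(eps$data)
  flat <- matrix(aperm(eps$data, c(2, 3, 1)), nrow = d[2] * d[3], ncol = d[1])
  colnames(flat) <- eps$channel_names
  df <- tibble::as_tibble(as.data.frame(flat))
  df <- dplyr::bind_cols(
    tibble::tibble(epoch = rep(seq_len(d[3]), each = d[2]),
                   sample = rep(seq_len(d[2]), times = d[3])), df)
  readr::write_csv(df, paste0(prefix, "_data.csv"))
  readr::write_csv(
    dplyr::left_join(
      tibble::tibble(epoch = seq_len(d[3]), epoch_id = eps$epoch_ids,
                     label = eps$labels),
      eps$flags, by = "epoch_id"),
    paste0(prefix, "_epochs.csv"))
  yaml::write_yaml(list(sample_rate = eps$sample_rate,
                        channels = eps$channel_names),
                   paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  df <- readr::read_csv(paste0(prefix, "_data.csv"), show_col_types = FALSE,
                        progress = FALSE)
  epdf <- readr::read_csv(paste0(prefix, "_epochs.csv"),
                          show_col_types = FALSE, progress = FALSE)
  chs <- unlist(meta$channels)
  n_ep <- max(df$epoch)
  L <- max(df$sample)
  arr <- aperm(array(as.matrix(df[, chs]), dim = c(L, n_ep, length(chs))),
               c(3, 1, 2))
  new_eeg_epochs(arr, epdf$label, meta$sample_rate, chs,
                 flags = tibble::tibble(epoch_id = epdf$epoch_id,
                                        status = epdf$status,
                                        reason = epdf$reason),
                 epoch_ids = epdf$epoch_id)
}
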