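#' Default class-conditional spatial covariances
#'
#' Builds one spatial covariance per mental state from a shared (deterministic)
#' orthogonal mixing matrix and class-specific source power profiles. The NE
#' state carries baseline unit log-powers; CA, DA and SS raise/lower source
#' log-powers by +/-0.5 along three distinct sign patterns, with a small
#' overall elevation for SS, so that (a) the non-NE states have elevated mean
#' power relative to NE and (b) the pairwise affine-invariant Riemannian
#' distances between class covariances are >= 1 (they come out around 2.2-3.2
#' for 20 channels), making the states separable by covariance alone.
#'
#' @param n_channels number of channels.
#' @param scale baseline source power in microvolt^2 (default 100, i.e. about
#'   10 uV channel standard deviation).
#' @return named list of `n_channels` x `n_channels` SPD matrices
#'   (NE, CA, DA, SS).
#' @export
default_class_covariances <- function(n_channels, scale = 100) {
  n <- as.integer(n_channels)
  A <- withr::with_seed(20230823,
                        qr.Q(qr(matrix(rnorm(n * n), n, n))))
  u1 <- rep(c(1, -1), length.out = n)
  u2 <- rep(c(1, 1, -1, -1), length.out = n)
  u3 <- rep(c(1, -1, -1, 1), length.out = n)
  delta <- list(NE = rep(0, n), CA = 0.5 * u1, DA = 0.5 * u2,
                SS = 0.5 * u3 + 0.2)
  lapply(delta, function(d) {
    S <- A %*% (scale * exp(d) * t(A))
    (S + t(S)) / 2
  })
}

#' Default artifact specification
#'
#' Per-epoch occurrence probabilities and amplitudes for the four injected
#' artifact families: frontal blinks (smooth 300 ms positive transients),
#' high-frequency muscle bursts, large amplitude spikes (above the 700 uV
#' gate), and near-flat channels (below the 1 uV gate).
#'
#' @param blink_prob,muscle_prob,spike_prob,flat_prob per-epoch probabilities.
#' @param blink_amp,muscle_amp,spike_amp amplitudes in microvolts.
#' @param flat_scale multiplicative attenuation of a flattened channel.
#' @return a named list understood by [sim_config()].
#' @export
artifact_spec <- function(blink_prob = 0.05, blink_amp = 200,
                          muscle_prob = 0.03, muscle_amp = 60,
                          spike_prob = 0.02, spike_amp = 900,
                          flat_prob = 0.01, flat_scale = 0.01) {
  list(blink = list(prob = blink_prob, amplitude = blink_amp),
       muscle = list(prob = muscle_prob, amplitude = muscle_amp),
       spike = list(prob = spike_prob, amplitude = spike_amp),
       flat = list(prob = flat_prob, scale = flat_scale))
}

#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulate_recording()].
#' The defaults emulate the structure of the pilot EEG recordings the
#' pipeline targets: 20 channels at 256 Hz, heavy class imbalance with the
#' NE state holding 80% of the samples, 1/f background spectra, and sporadic
#' blink/muscle/spike/flat artifacts.
#'
#' @param n_channels number of channels (>= 4).
#' @param sample_rate sampling rate in Hz.
#' @param class_durations named numeric vector, seconds of signal per state;
#'   names must be a subset of NE, CA, DA, SS. One epoch is one second.
#' @param class_covariances named list of SPD spatial covariances (uV^2), one
#'   per state in `class_durations`; `NULL` uses
#'   [default_class_covariances()].
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param artifacts an [artifact_spec()]; set the probabilities to zero for a
#'   clean recording.
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 20, sample_rate = 256,
                       class_durations = c(NE = 160, CA = 16, DA = 12, SS = 12),
                       class_covariances = NULL, noise_exponent = 1,
                       artifacts = artifact_spec(), seed = 1) {
  check_scalar_number(sample_rate, "sample_rate")
  check_scalar_number(seed, "seed", positive = FALSE)
  if (is.null(names(class_durations)) ||
      !all(names(class_durations) %in% STATE_LEVELS)) {
    stop_eeg("class_durations must be named with states among NE, CA, DA, SS",
             "invalid_config")
  }
  if (any(class_durations < 1)) {
    stop_eeg("each class duration must be at least one second",
             "invalid_config")
  }
  if (is.null(class_covariances)) {
    class_covariances <- default_class_covariances(n_channels)[
      names(class_durations)]
  }
  if (!setequal(names(class_covariances), names(class_durations))) {
    stop_eeg("class_covariances must cover exactly the states in class_durations",
             "invalid_config")
  }
  for (k in names(class_covariances)) {
    S <- class_covariances[[k]]
    if (!is.matrix(S) || nrow(S) != n_channels || ncol(S) != n_channels ||
        max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))) ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop_eeg(sprintf("class covariance '%s' is not a %d x %d SPD matrix",
                       k, n_channels, n_channels), "invalid_config")
    }
  }
  structure(list(n_channels = as.integer(n_channels),
                 sample_rate = sample_rate,
                 class_durations = class_durations,
                 class_covariances = class_covariances,
                 noise_exponent = noise_exponent,
                 artifacts = artifacts, seed = seed),
            class = "sim_config")
}

# 1/f^alpha noise by spectral shaping of white Gaussian noise, standardized
# to zero mean and unit variance. Frequencies below 1 Hz share the 1 Hz gain
# so the DC region does not blow up.
shaped_noise <- function(n, alpha, fs) {
  w <- rnorm(n)
  if (alpha == 0) return((w - mean(w)) / sd(w))
  f <- fs * seq(0, n - 1) / n
  f <- pmin(f, fs - f)            # two-sided frequency axis
  g <- pmax(f, 1)^(-alpha / 2)
  g[1] <- 0
  x <- Re(fft(fft(w) * g, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

interleave_blocks <- function(class_epochs) {
  runs <- list()
  chunks <- lapply(class_epochs, function(n) {
    nb <- min(4L, n)
    diff(round(seq(0, n, length.out = nb + 1)))
  })
  for (r in seq_len(max(vapply(chunks, length, 1L)))) {
    for (k in names(chunks)) {
      if (r <= length(chunks[[k]]) && chunks[[k]][r] > 0) {
        runs[[length(runs) + 1L]] <- list(state = k, n = chunks[[k]][r])
      }
    }
  }
  runs
}

#' Simulate a labeled EEG recording with artifact ground truth
#'
#' Generates class-covariance-shaped signal (independent 1/f^alpha unit
#' variance sources mixed through the Cholesky factor of the state's spatial
#' covariance), splits each state's duration into interleaved blocks, and
#' injects annotated artifacts epoch by epoch. The returned ground truth
#' carries the per-epoch state labels, an artifact annotation table, and the
#' unit-amplitude blink time course used downstream to verify blink removal.
#'
#' @param config a [sim_config()].
#' @return list with elements `recording` (an [eeg_recording()] with
#'   per-sample labels) and `truth` (class `eeg_ground_truth`: `epoch_labels`,
#'   `annotations` tibble with columns epoch/type/channels/onset,
#'   `blink_trace`, `montage`, `config`).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  L <- as.integer(round(fs))
  montage <- make_montage(config$n_channels)
  channels <- montage$channel
  n_ch <- config$n_channels
  class_epochs <- round(config$class_durations)
  runs <- interleave_blocks(class_epochs)
  epoch_labels <- unlist(lapply(runs, function(r) rep(r$state, r$n)))
  n_ep <- length(epoch_labels)
  total <- n_ep * L
  chol_f <- lapply(config$class_covariances, function(S) t(chol(S)))
  bw <- blink_weights(montage, channels)
  spec <- config$artifacts

  out <- withr::with_seed(config$seed, {
    data <- matrix(0, n_ch, total)
    blink_trace <- numeric(total)
    ann <- list()
    ep0 <- 0L
    for (run in runs) {
      Tn <- run$n * L
      Z <- t(vapply(seq_len(n_ch),
                    function(i) shaped_noise(Tn, config$noise_exponent, fs),
                    numeric(Tn)))
      seg <- chol_f[[run$state]] %*% Z
      data[, ep0 * L + seq_len(Tn)] <- seg
      ep0 <- ep0 + run$n
    }
    for (e in seq_len(n_ep)) {
      idx <- (e - 1L) * L + seq_len(L)
      if (runif(1) < spec$blink$prob) {
        blen <- max(2L, as.integer(round(0.3 * fs)))
        onset <- sample.int(L - blen, 1)
        tt <- seq_len(blen) / blen
        kern <- sin(pi * tt)^2
        data[, idx[onset + seq_len(blen) - 1L]] <-
          data[, idx[onset + seq_len(blen) - 1L]] +
          spec$blink$amplitude * outer(bw, kern)
        blink_trace[idx[onset + seq_len(blen) - 1L]] <-
          blink_trace[idx[onset + seq_len(blen) - 1L]] + kern
        ann[[length(ann) + 1L]] <- tibble::tibble(
          epoch = e, type = "blink", channels = list(channels[bw > 0.5]),
          onset = (onset - 1) / fs)
      }
      if (runif(1) < spec$muscle$prob) {
        mlen <- max(2L, as.integer(round(0.2 * fs)))
        onset <- sample.int(L - mlen, 1)
        chs <- sample.int(n_ch, sample.int(3, 1))
        env <- sin(pi * seq_len(mlen) / mlen)^2
        for (c_i in chs) {
          data[c_i, idx[onset + seq_len(mlen) - 1L]] <-
            data[c_i, idx[onset + seq_len(mlen) - 1L]] +
            spec$muscle$amplitude * env * rnorm(mlen)
        }
        ann[[length(ann) + 1L]] <- tibble::tibble(
          epoch = e, type = "muscle", channels = list(channels[chs]),
          onset = (onset - 1) / fs)
      }
      if (runif(1) < spec$spike$prob) {
        slen <- max(4L, as.integer(round(0.04 * fs)))
        onset <- sample.int(L - slen, 1)
        ch <- sample.int(n_ch, 1)
        half <- slen %/% 2
        pulse <- c(rep(spec$spike$amplitude / 2, half),
                   rep(-spec$spike$amplitude / 2, slen - half))
        data[ch, idx[onset + seq_len(slen) - 1L]] <-
          data[ch, idx[onset + seq_len(slen) - 1L]] + pulse
        ann[[length(ann) + 1L]] <- tibble::tibble(
          epoch = e, type = "spike", channels = list(channels[ch]),
          onset = (onset - 1) / fs)
      }
      if (runif(1) < spec$flat$prob) {
        ch <- sample.int(n_ch, 1)
        data[ch, idx] <- data[ch, idx] * spec$flat$scale
        ann[[length(ann) + 1L]] <- tibble::tibble(
          epoch = e, type = "flat", channels = list(channels[ch]), onset = 0)
      }
    }
    list(data = data, blink_trace = blink_trace, ann = ann)
  })

  annotations <- if (length(out$ann) > 0) {
    dplyr::bind_rows(out$ann)
  } else {
    tibble::tibble(epoch = integer(), type = character(),
                   channels = list(), onset = numeric())
  }
  rec <- eeg_recording(out$data, channels, fs, rep(epoch_labels, each = L))
  truth <- structure(list(epoch_labels = epoch_labels,
                          annotations = annotations,
                          blink_trace = out$blink_trace,
                          montage = montage, config = config),
                     class = "eeg_ground_truth")
  list(recording = rec, truth = truth)
}

#' Write a ground-truth annotation table to CSV
#'
#' @param truth the `truth` element returned by [simulate_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  ann <- truth$annotations
  ann$channels <- vapply(ann$channels, paste, collapse = ";",
                         FUN.VALUE = character(1))
  readr::write_csv(ann, path)
  invisible(path)
}
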