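# Canonical EEG frequency bands (Hz): lower edge inclusive, upper exclusive.
EEG_BANDS <- list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12),
                  beta = c(12, 30), gamma = c(30, 45))

# Hann-windowed one-sided Welch PSD, averaging one segment per epoch.
# x: samples x epochs matrix for one channel. Returns psd over freqs 0..fs/2.
welch_psd <- function(x, fs) {
  L <- nrow(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (e in seq_len(ncol(x))) {
    X <- fft(w * x[, e])
    acc <- acc + Mod(X[seq_len(nf)])^2
  }
  psd <- acc / (ncol(x) * fs * U)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (L %% 2 == 0) scale2[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / L, psd = psd * scale2)
}

#' Per-channel band power for one mental state
#'
#' Averages the Hann-windowed periodogram over the state's epochs (Welch
#' estimate with one segment per epoch, no overlap), integrates the PSD over
#' the five canonical bands — delta 0-4, theta 4-8, alpha 8-12, beta 12-30,
#' gamma 30-45 Hz — and reports each band's power in microvolt^2 and in dB
#' (10 log10, reference 1 microvolt^2).
#'
#' @param eps a labeled `eeg_epochs` object.
#' @param state state label to select epochs by.
#' @return a tibble of class `band_power_map` with columns `channel`, `band`,
#'   `power` (uV^2) and `power_db`.
#' @export
band_power <- function(eps, state) {
  stopifnot(inherits(eps, "eeg_epochs"))
  idx <- which(eps$labels == state)
  if (length(idx) == 0) {
    stop_eeg(sprintf("no epochs with label '%s'", state), "empty_selection")
  }
  fs <- eps$sample_rate
  L <- dim(eps$data)[2]
  df <- fs / L
  rows <- purrr::map_dfr(seq_along(eps$channel_names), function(ch) {
    x <- matrix(eps$data[ch, , idx], nrow = L)
    ps <- welch_psd(x, fs)
    purrr::map_dfr(names(EEG_BANDS), function(b) {
      lim <- EEG_BANDS[[b]]
      sel <- ps$freq >= lim[1] & ps$freq < lim[2]
      p <- sum(ps$psd[sel]) * df
      tibble::tibble(channel = eps$channel_names[ch], band = b,
                     power = p, power_db = 10 * log10(p))
    })
  })
  rows$band <- factor(rows$band, levels = names(EEG_BANDS))
  attr(rows, "state") <- state
  class(rows) <- c("band_power_map", class(rows))
  rows
}

#' Total 0-Nyquist power per channel for one state
#'
#' Companion to [band_power()]: integral of the same Welch PSD over the full
#' one-sided axis, in microvolt^2.
#'
#' @inheritParams band_power
#' @return tibble with columns `channel`, `total_power`.
#' @export
total_power <- function(eps, state) {
  idx <- which(eps$labels == state)
  if (length(idx) == 0) {
    stop_eeg(sprintf("no epochs with label '%s'", state), "empty_selection")
  }
  fs <- eps$sample_rate
  L <- dim(eps$data)[2]
  purrr::map_dfr(seq_along(eps$channel_names), function(ch) {
    x <- matrix(eps$data[ch, , idx], nrow = L)
    ps <- welch_psd(x, fs)
    tibble::tibble(channel = eps$channel_names[ch],
                   total_power = sum(ps$psd) * fs / L)
  })
}

#' @export
autoplot.band_power_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$band, y = .data$channel,
                               fill = .data$power_db)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "Band", y = "Channel",
                  title = paste("Band power,", attr(object, "state"))) +
    ggplot2::theme_minimal()
}
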