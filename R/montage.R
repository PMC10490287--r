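# Approximate 10-20 positions: inclination theta from the vertex and signed
# azimuth phi from the front midline (positive = left hemisphere), degrees.
TEN_TWENTY <- data.frame(
  channel = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
              "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2", "Oz"),
  theta = c(72, 72, 72, 48, 36, 48, 72, 72, 36, 0,
            36, 72, 72, 48, 36, 48, 72, 72, 72, 72),
  phi = c(18, -18, 54, 36, 0, -36, -54, 90, 90, 0,
          -90, -90, 126, 144, 180, -144, -126, 162, -162, 180),
  stringsAsFactors = FALSE
)

#' Build a synthetic sensor montage
#'
#' Maps `n_channels` sensors to distinct unit-sphere positions. The first 20
#' channels use standard 10-20 names and approximate 10-20 scalp positions
#' (the head points along +y, the vertex along +z); additional channels are
#' placed deterministically on an upper-hemisphere Fibonacci spiral. The
#' frontal channel `Fp1` is always present, as downstream blink handling uses
#' it as a surrogate ocular channel.
#'
#' @param n_channels number of sensors, at least 4.
#' @return a tibble of class `eeg_montage` with columns `channel`, `x`, `y`,
#'   `z` (unit-norm positions).
#' @export
make_montage <- function(n_channels) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 4 || n_channels != round(n_channels)) {
    stop_eeg("`n_channels` must be an integer >= 4", "invalid_config")
  }
  n_channels <- as.integer(n_channels)
  n_std <- min(n_channels, nrow(TEN_TWENTY))
  th <- TEN_TWENTY$theta[seq_len(n_std)] * pi / 180
  ph <- TEN_TWENTY$phi[seq_len(n_std)] * pi / 180
  pos <- cbind(x = -sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
  names_out <- TEN_TWENTY$channel[seq_len(n_std)]
  if (n_channels > n_std) {
    k <- seq_len(n_channels - n_std)
    golden <- pi * (3 - sqrt(5))
    # upper hemisphere spiral, offset so no point collides with 10-20 sites
    z <- 0.15 + 0.7 * (k - 0.5) / length(k)
    r <- sqrt(pmax(0, 1 - z^2))
    ang <- golden * k + 0.37
    pos <- rbind(pos, cbind(x = r * cos(ang), y = r * sin(ang), z = z))
    names_out <- c(names_out, sprintf("Ch%02d", n_std + k))
  }
  out <- tibble::tibble(channel = names_out, x = pos[, "x"], y = pos[, "y"],
                        z = pos[, "z"])
  class(out) <- c("eeg_montage", class(out))
  out
}

montage_positions <- function(montage, channels) {
  idx <- match(channels, montage$channel)
  if (anyNA(idx)) {
    stop_eeg(paste("montage is missing channel(s):",
                   paste(channels[is.na(idx)], collapse = ", ")), "montage")
  }
  as.matrix(montage[idx, c("x", "y", "z")])
}

# Spatial weight of an ocular (blink) source at each sensor: strongest at the
# front of the scalp, decaying with distance from a point just above the nasion.
blink_weights <- function(montage, channels) {
  pos <- montage_positions(montage, channels)
  nasion <- c(0, 0.985, 0.174)
  d2 <- rowSums(sweep(pos, 2, nasion)^2)
  w <- exp(-1.5 * d2)
  w / max(w)
}
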