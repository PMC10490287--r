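#' Run the full preprocessing chain on a raw recording
#'
#' Convenience wrapper for the deterministic front half plus repair:
#' band-pass FIR filter (1-50 Hz), one-second epoching, peak-to-peak gating
#' (700 / 1 uV), cross-validated rejection with interpolation, ICA blink
#' removal, a second rejection pass, and (optionally) class rebalancing by
#' undersampling.
#'
#' @param rec a labeled [eeg_recording()].
#' @param montage sensor montage (default built from the channel count).
#' @param low,high band-pass edges in Hz.
#' @param max_ptp,min_ptp gate thresholds in microvolts.
#' @param balance undersample to balanced classes at the end (default TRUE).
#' @param seed integer seed for threshold folds, ICA and undersampling.
#' @param ... passed to [repair_pipeline()].
#' @return list with `epochs` (cleaned, optionally balanced), `gated`
#'   (pre-repair epochs), and the repair logs.
#' @export
preprocess_recording <- function(rec, montage = NULL, low = 1, high = 50,
                                 max_ptp = 700, min_ptp = 1, balance = TRUE,
                                 seed = 1, ...) {
  montage <- montage %||% make_montage(length(rec$channel_names))
  filtered <- bandpass_fir(rec, low = low, high = high)
  eps <- epoch_fixed(filtered, length = 1)
  gated <- ptp_gate(eps, max_ptp = max_ptp, min_ptp = min_ptp)
  rep <- repair_pipeline(gated, montage, seed = seed, ...)
  out <- rep$epochs
  if (balance) out <- undersample_balance(out, seed = seed)
  list(epochs = out, gated = gated, log1 = rep$log1, log2 = rep$log2,
       n_blink_components = rep$n_blink_components)
}
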