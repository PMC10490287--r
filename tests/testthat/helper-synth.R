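# shared fixture builders (all generated in code, seeded)

random_spd <- function(n, seed = NULL) {
  gen <- function() {
    A <- matrix(rnorm(n * n), n, n)
    S <- A %*% t(A) + 0.5 * diag(n)
    (S + t(S)) / 2
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# epochs with known per-class signal scale; channels x L x n
toy_epochs <- function(n_per_class = 12, n_ch = 6, L = 64, fs = 64,
                       scales = c(NE = 1, CA = 2, DA = 3, SS = 4),
                       seed = 1) {
  withr::with_seed(seed, {
    n_ep <- n_per_class * length(scales)
    arr <- array(rnorm(n_ch * L * n_ep), dim = c(n_ch, L, n_ep))
    labels <- rep(names(scales), each = n_per_class)
    for (e in seq_len(n_ep)) arr[, , e] <- arr[, , e] * scales[labels[e]]
    eegstate:::new_eeg_epochs(arr, labels, fs,
                              make_montage(n_ch)$channel[seq_len(n_ch)])
  })
}

# brute-force ptp classification used as the independent oracle for ptp_gate
brute_force_gate <- function(arr, max_ptp, min_ptp) {
  vapply(seq_len(dim(arr)[3]), function(e) {
    ptps <- vapply(seq_len(dim(arr)[1]), function(c_i) {
      v <- arr[c_i, , e]
      max(v) - min(v)
    }, numeric(1))
    !(any(ptps > max_ptp) || any(ptps < min_ptp))
  }, logical(1))
}
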