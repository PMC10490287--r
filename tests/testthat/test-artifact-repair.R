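# epochs with a known clean/artifact peak-to-peak gap on chosen channels
gap_epochs <- function(n_clean = 40, n_art = 10, n_ch = 5, L = 32,
                      clean_ptp = 80, art_ptp = 600, seed = 1) {
  withr::with_seed(seed, {
    n_ep <- n_clean + n_art
    arr <- array(rnorm(n_ch * L * n_ep, sd = 5), dim = c(n_ch, L, n_ep))
    for (e in seq_len(n_ep)) {
      for (c_i in seq_len(n_ch)) {       # pin every channel's ptp
        v <- arr[c_i, , e]
        target <- if (e > n_clean && c_i <= 2) art_ptp else clean_ptp
        target <- target * runif(1, 0.5, 1)
        arr[c_i, , e] <- (v - min(v)) / (max(v) - min(v)) * target
      }
    }
    eegstate:::new_eeg_epochs(arr, rep("NE", n_ep), 32,
                              make_montage(n_ch)$channel[seq_len(n_ch)])
  })
}

test_that("learned thresholds fall in the clean/artifact gap", {
  eps <- gap_epochs(clean_ptp = 100, art_ptp = 1000, seed = 2)
  # clean epochs have ptp <= 100, artifact epochs >= 500 on channels 1-2
  m <- learn_thresholds(eps, seed = 3)
  expect_gt(m$tau[1], 100)
  expect_lt(m$tau[1], 500)
  expect_gt(m$tau[2], 100)
  expect_lt(m$tau[2], 500)
  # independent exhaustive check: any threshold in the gap keeps exactly the
  # clean epochs on those channels
  ptp <- eegstate:::epoch_ptp(eps)
  expect_identical(which(ptp[1, ] <= m$tau[1]), which(ptp[1, ] <= 300))
})

test_that("all-clean homogeneous data learns permissive thresholds", {
  withr::with_seed(4, {
    arr <- array(rnorm(4 * 32 * 30, sd = 10), dim = c(4, 32, 30))
  })
  eps <- eegstate:::new_eeg_epochs(arr, rep("NE", 30), 32,
                                   make_montage(4)$channel)
  m <- learn_thresholds(eps, seed = 5)
  ptp <- eegstate:::epoch_ptp(eps)
  expect_true(all(m$tau >= apply(ptp, 1, max)))
  res <- apply_reject(eps, m, make_montage(4))
  expect_equal(n_epochs(res$epochs), 30)
  expect_true(all(res$log$decision == "kept"))
  # determinism
  m2 <- learn_thresholds(eps, seed = 5)
  expect_identical(m$tau, m2$tau)
  expect_error(learn_thresholds(eps, grid = numeric(0)),
               class = "eegstate_invalid_config")
})

test_that("rejection follows the consensus/interpolation rule and logs it", {
  mont <- make_montage(20)
  withr::with_seed(6, {
    arr <- array(rnorm(20 * 32 * 12, sd = 10), dim = c(20, 32, 12))
  })
  arr[1, , 1] <- arr[1, , 1] * 50          # 1 bad channel in epoch 1
  arr[1:15, , 2] <- arr[1:15, , 2] * 50    # 15/20 bad channels in epoch 2
  eps <- eegstate:::new_eeg_epochs(arr, rep("NE", 12), 32, mont$channel)
  model <- structure(list(tau = stats::setNames(rep(150, 20), mont$channel),
                          kappa = 0.5, rho = 2, grid = NULL,
                          cv_folds = 5, seed = 1),
                     class = "rejection_model")
  res <- apply_reject(eps, model, mont)
  expect_equal(res$log$decision[1], "repaired")
  expect_equal(res$log$channels_interpolated[1], mont$channel[1])
  expect_equal(res$log$decision[2], "dropped")
  expect_setequal(res$log$decision[3:12], "kept")
  # decisions are exhaustive and mutually exclusive
  expect_equal(nrow(res$log), 12)
  expect_true(all(res$log$decision %in% c("kept", "repaired", "dropped")))
  expect_equal(n_epochs(res$epochs), 11)
})

test_that("inverse-distance interpolation reproduces consistent fields", {
  mont <- make_montage(6)
  chs <- mont$channel
  withr::with_seed(7, {
    ep <- matrix(rnorm(6 * 16), 6, dimnames = list(chs, NULL))
  })
  # fixed point: channel set to the exact inverse-distance combination
  pos <- as.matrix(mont[, c("x", "y", "z")])
  d2 <- rowSums(sweep(pos[-1, ], 2, pos[1, ])^2)
  w <- (1 / d2) / sum(1 / d2)
  ep[1, ] <- as.numeric(w %*% ep[-1, ])
  out <- interpolate_channel(ep, chs[1], mont)
  expect_lt(max(abs(out[1, ] - ep[1, ])) / max(abs(ep[1, ])), 1e-10)
  expect_identical(out[-1, ], ep[-1, ])

  # constant field reproduced exactly
  const <- matrix(3.2, 6, 16, dimnames = list(chs, NULL))
  out2 <- interpolate_channel(const, chs[2], mont)
  expect_equal(out2[2, ], rep(3.2, 16), ignore_attr = TRUE)

  # smooth field: interpolation beats zero replacement
  smooth <- matrix(rep(pos[, 3], 16), 6, dimnames = list(chs, NULL)) +
    outer(pos[, 2], seq(0, 1, length.out = 16))
  truth <- smooth[3, ]
  broken <- smooth
  broken[3, ] <- 999
  out3 <- interpolate_channel(broken, chs[3], mont)
  expect_lt(sum((out3[3, ] - truth)^2), sum(truth^2))

  expect_error(interpolate_channel(ep[1:3, ], chs[1], mont),
               class = "eegstate_interpolation")
})

test_that("ICA blink removal cleans frontal channels but keeps brain sources", {
  fs <- 128
  n_ep <- 60
  L <- fs
  mont <- make_montage(8)
  chs <- mont$channel
  bw <- eegstate:::blink_weights(mont, chs)
  withr::with_seed(8, {
    arr <- array(rnorm(8 * L * n_ep, sd = 10), dim = c(8, L, n_ep))
    blink_trace <- numeric(L * n_ep)
    tt <- seq_len(round(0.3 * fs)) / round(0.3 * fs)
    kern <- sin(pi * tt)^2
    blink_eps <- sort(sample(n_ep, 12))
    for (e in blink_eps) {
      onset <- sample.int(L - length(kern), 1) + (e - 1) * L
      blink_trace[onset + seq_along(kern) - 1] <- kern
    }
    alpha_ref <- sin(2 * pi * 10 * seq_len(L * n_ep) / fs)
  })
  flat <- matrix(arr, nrow = 8)
  flat <- flat + 150 * outer(bw, blink_trace)
  flat[match("T7", chs), ] <- flat[match("T7", chs), ] + 35 * alpha_ref
  eps <- eegstate:::new_eeg_epochs(array(flat, dim = dim(arr)),
                                   rep("NE", n_ep), fs, chs)
  cleaned <- remove_blinks(eps, seed = 9)
  expect_gte(attr(cleaned, "n_removed"), 1)
  out <- matrix(cleaned$data, nrow = 8)
  for (ch in c("Fp1", "Fp2", "F7")) {
    expect_lt(abs(cor(out[match(ch, chs), ], blink_trace)), 0.2)
  }
  expect_gt(cor(out[match("T7", chs), ], alpha_ref), 0.9)
})

test_that("blink removal is a no-op without matching components and zeroes all at r_thresh 0", {
  eps <- toy_epochs(n_per_class = 8, n_ch = 5, L = 64, seed = 10)
  out <- remove_blinks(eps, surrogate = eps$channel_names[1], r_thresh = 2)
  expect_lt(norm(matrix(out$data - eps$data, 5), "F") /
              norm(matrix(eps$data, 5), "F"), 1e-6)
  expect_equal(attr(out, "n_removed"), 0)

  # removing everything leaves only the channel means (plus rank residue)
  all_removed <- remove_blinks(eps, surrogate = eps$channel_names[1],
                               r_thresh = 0)
  expect_lt(sd(all_removed$data), 0.05 * sd(eps$data))

  expect_error(remove_blinks(eps, surrogate = "Nope"),
               class = "eegstate_missing_channel")
})

test_that("repair pipeline recovers annotated artifacts on synthetic data", {
  cfg <- sim_config(seed = 33)
  sim <- simulate_recording(cfg)
  eps <- epoch_fixed(bandpass_fir(sim$recording))
  gated <- ptp_gate(eps)
  rp <- repair_pipeline(gated, make_montage(20), seed = 33)
  fl <- rp$epochs$flags
  ann <- sim$truth$annotations
  strong <- unique(ann$epoch[ann$type %in% c("blink", "spike")])
  clean <- setdiff(seq_along(sim$truth$epoch_labels), unique(ann$epoch))
  touched <- fl$epoch_id[fl$status %in% c("dropped", "repaired")]
  expect_gte(mean(strong %in% touched), 0.9)
  expect_gte(mean(!(clean %in% touched)), 0.9)
  # the second rejection pass never increases the epoch count
  expect_lte(n_epochs(rp$epochs),
             sum(rp$log1$decision %in% c("kept", "repaired")))
  # decisions cover every gated epoch exactly once
  expect_setequal(rp$log1$epoch_id, gated$epoch_ids)
})
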