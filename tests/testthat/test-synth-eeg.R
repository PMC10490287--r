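test_that("montage construction places distinct unit-sphere sensors with Fp1", {
  m <- make_montage(20)
  expect_equal(nrow(m), 20)
  expect_true("Fp1" %in% m$channel)
  pos <- as.matrix(m[, c("x", "y", "z")])
  expect_equal(unname(sqrt(rowSums(pos^2))), rep(1, 20), tolerance = 1e-8)
  expect_gt(min(dist(pos)), 0)

  m4 <- make_montage(4)
  expect_equal(nrow(m4), 4)
  expect_gt(min(dist(as.matrix(m4[, c("x", "y", "z")]))), 0)

  expect_error(make_montage(3), class = "eegstate_invalid_config")

  m30 <- make_montage(30)
  expect_equal(anyDuplicated(m30$channel), 0)
  expect_gt(min(dist(as.matrix(m30[, c("x", "y", "z")]))), 0)
})

test_that("simulation is bit-identical under a fixed seed and config", {
  cfg <- sim_config(n_channels = 6,
                    class_durations = c(NE = 8, CA = 4, DA = 4, SS = 4),
                    seed = 42)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$annotations, b$truth$annotations)
  c <- simulate_recording(sim_config(n_channels = 6,
                                     class_durations = cfg$class_durations,
                                     seed = 43))
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("label proportions match the configured class durations exactly", {
  cfg <- sim_config(n_channels = 5,
                    class_durations = c(NE = 40, CA = 4, DA = 3, SS = 3),
                    seed = 3)
  sim <- simulate_recording(cfg)
  tab <- table(sim$truth$epoch_labels)
  expect_equal(unname(tab[c("NE", "CA", "DA", "SS")]),
               unname(table(c(rep("NE", 40), rep("CA", 4), rep("DA", 3),
                              rep("SS", 3)))[c("NE", "CA", "DA", "SS")]))
  # per-sample labels follow epochs
  expect_equal(length(sim$recording$labels), 50 * 256)
  expect_equal(mean(sim$recording$labels == "NE"), 0.8)
})

test_that("non-SPD class covariance is rejected", {
  bad <- diag(4)
  bad[1, 1] <- -1
  expect_error(
    sim_config(n_channels = 4,
               class_durations = c(NE = 4, CA = 4),
               class_covariances = list(NE = bad, CA = diag(4))),
    class = "eegstate_invalid_config")
})

test_that("annotated spikes exceed the 700 uV gate on the affected channel", {
  cfg <- sim_config(n_channels = 6,
                    class_durations = c(NE = 30, CA = 10, DA = 10, SS = 10),
                    artifacts = artifact_spec(blink_prob = 0, muscle_prob = 0,
                                              spike_prob = 0.2,
                                              spike_amp = 900,
                                              flat_prob = 0),
                    seed = 5)
  sim <- simulate_recording(cfg)
  ann <- sim$truth$annotations
  spikes <- ann[ann$type == "spike", ]
  expect_gt(nrow(spikes), 3)
  for (i in seq_len(nrow(spikes))) {
    e <- spikes$epoch[i]
    ci <- match(spikes$channels[[i]], sim$recording$channel_names)
    seg <- sim$recording$data[ci, (e - 1) * 256 + 1:256]
    expect_gt(max(seg) - min(seg), 700)
  }
})

test_that("annotations reference only existing epochs and channels", {
  cfg <- sim_config(n_channels = 6,
                    class_durations = c(NE = 20, CA = 10, DA = 10, SS = 10),
                    seed = 8)
  sim <- simulate_recording(cfg)
  ann <- sim$truth$annotations
  n_ep <- length(sim$truth$epoch_labels)
  expect_true(all(ann$epoch >= 1 & ann$epoch <= n_ep))
  expect_true(all(unlist(ann$channels) %in% sim$recording$channel_names))
  expect_true(all(ann$onset >= 0 & ann$onset < 1))
})

test_that("empirical class covariances converge to the configured ones", {
  # artifact-free generation; 300 s per class, small montage
  covs <- default_class_covariances(6)
  cfg <- sim_config(n_channels = 6,
                    class_durations = c(NE = 300, CA = 300),
                    class_covariances = covs[c("NE", "CA")],
                    artifacts = artifact_spec(0, 0, 0, 0, 0, 0, 0, 1),
                    seed = 21)
  sim <- simulate_recording(cfg)
  for (k in c("NE", "CA")) {
    sel <- sim$recording$labels == k
    emp <- spd_covariance(sim$recording$data[, sel])
    rel <- norm(emp - covs[[k]], "F") / norm(covs[[k]], "F")
    expect_lt(rel, 0.10)
  }
})

test_that("with artifacts disabled no epoch exceeds the amplitude envelope", {
  cfg <- sim_config(n_channels = 8,
                    class_durations = c(NE = 30, CA = 10, DA = 10, SS = 10),
                    artifacts = artifact_spec(0, 0, 0, 0, 0, 0, 0, 1),
                    seed = 13)
  sim <- simulate_recording(cfg)
  max_sd <- sqrt(max(vapply(cfg$class_covariances,
                            function(S) max(diag(S)), numeric(1))))
  # Gaussian extremes over 1 s epochs: ptp stays within 8 channel SDs
  expect_lt(max(sim$recording$data) - min(sim$recording$data), 8 * max_sd)
})

test_that("recordings and ground truth round-trip through delimited text", {
  cfg <- sim_config(n_channels = 4,
                    class_durations = c(NE = 4, CA = 2, DA = 2, SS = 2),
                    seed = 2)
  sim <- simulate_recording(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(sim$recording, path, meta = list(seed = 2))
  back <- read_recording(path)
  expect_equal(back$data, sim$recording$data, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$labels, sim$recording$labels)
  expect_equal(back$sample_rate, sim$recording$sample_rate)
  gt_path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, gt_path)
  expect_true(file.exists(gt_path))
})
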