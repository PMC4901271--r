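# Synthetic-data generator: determinism, target fidelity, noise images,
# toy meshes.

test_that("identical seeds produce bit-identical outputs across all generators", {
  gt <- ground_truth(6, 3, seed = 77)
  gt2 <- ground_truth(6, 3, seed = 77)
  expect_identical(gt$layer_target_sim, gt2$layer_target_sim)
  a1 <- simulate_layer_activations(gt, 12)
  a2 <- simulate_layer_activations(gt2, 12)
  expect_identical(a1$layers, a2$layers)
  m1 <- simulate_meg_subject(gt, n_sensors = 8, n_trials = 4,
                             times_ms = seq(100, 160, 20), subject = 2)
  m2 <- simulate_meg_subject(gt2, n_sensors = 8, n_trials = 4,
                             times_ms = seq(100, 160, 20), subject = 2)
  expect_identical(m1$data, m2$data)
  expect_identical(generate_noise_images(2, size = 16, seed = 5),
                   generate_noise_images(2, size = 16, seed = 5))
  # different subjects share the signal but not the noise
  m3 <- simulate_meg_subject(gt, n_sensors = 8, n_trials = 4,
                             times_ms = seq(100, 160, 20), subject = 3)
  expect_false(identical(m1$data, m3$data))
})

test_that("layer activations have the configured geometry and realise their targets", {
  gt <- ground_truth(118, 8, seed = 3)
  acts <- simulate_layer_activations(gt, 130)
  expect_length(acts$layers, 8)
  expect_true(all(vapply(acts$layers, nrow, 0L) == 118L))
  expect_error(ground_truth(2, 8), "at least 3 conditions")
  expect_error(simulate_layer_activations(gt, 1), "at least 2 units")
  # noiseless activations: per-layer correlation RDM vs its target
  gts <- ground_truth(12, 8, noise_sd = 0, seed = 9)
  lr <- layer_rdms(simulate_layer_activations(gts, 300), quiet = TRUE)
  tg <- target_rdms(gts)
  for (l in 1:8)
    expect_gte(compare_rdms(lr[[l]], tg[[l]]), 0.95)
  # successive layers' targets are distinct
  for (l in 1:7)
    expect_lt(compare_rdms(tg[[l]], tg[[l + 1]]), 0.9)
})

test_that("identical layer targets yield exactly identical layer RDMs", {
  gt <- ground_truth(8, 3, noise_sd = 0, seed = 13)
  gt$layer_target_sim <- rep(gt$layer_target_sim[1], 3)
  lr <- layer_rdms(simulate_layer_activations(gt, 40), quiet = TRUE)
  expect_identical(lr[[1]]$values, lr[[2]]$values)
  expect_identical(lr[[1]]$values, lr[[3]]$values)
  expect_equal(compare_rdms(lr[[1]], lr[[2]]), 1)
})

test_that("fmri regions realise their weighted layer structure", {
  w <- rbind(IT = c(0, 0, 1), noise = c(0, 0, 0))
  gt <- ground_truth(12, 3, layer_region_weights = w, noise_sd = 0, seed = 21)
  pats <- simulate_fmri_subject(gt, n_voxels_per_region = 100)
  expect_identical(ncol(pats$IT$data), 100L)
  tg <- target_rdms(gt)
  expect_gte(compare_rdms(correlation_rdm(pats$IT, quiet = TRUE), tg[[3]]), 0.95)
  expect_error(simulate_fmri_subject(gt, regions = "V9"), "not defined")
  expect_error(simulate_fmri_subject(gt, n_voxels_per_region = 0), "positive")
})

test_that("a pure-noise region has no systematic similarity to any layer", {
  w <- rbind(ctrl = c(0, 0, 0))
  gt <- ground_truth(10, 3, layer_region_weights = w, noise_sd = 1, seed = 4)
  tg <- target_rdms(gt)
  sims <- vapply(1:100, function(s) {
    p <- simulate_fmri_subject(gt, n_voxels_per_region = 40, subject = s)
    compare_rdms(correlation_rdm(p$ctrl, quiet = TRUE), tg[[1]])
  }, numeric(1))
  expect_lt(abs(mean(sims)), 0.05)
})

test_that("noise images have the right shape and smoothing raises spatial autocorrelation", {
  imgs <- generate_noise_images(2, size = 32, channels = 3, seed = 8)
  expect_identical(dim(imgs[[1]]), c(32L, 32L, 3L))
  expect_true(all(vapply(imgs, function(x) all(is.finite(x)), TRUE)))
  expect_error(generate_noise_images(0), "positive")
  expect_error(generate_noise_images(1, size = 4, filter_size = 10), "at least")
  for (s in 1:10) {
    raw <- generate_noise_images(1, size = 32, channels = 1, filter_size = 0, seed = s)[[1]]
    sm <- generate_noise_images(1, size = 32, channels = 1, seed = s)[[1]]
    expect_gt(lag1_autocorrelation(sm[, , 1]), lag1_autocorrelation(raw[, , 1]))
    expect_gt(lag1_autocorrelation(sm[, , 1]), 0)
  }
  # identity filter returns the raw uniform field itself (same substream)
  raw <- generate_noise_images(1, size = 16, channels = 1, filter_size = 0, seed = 3)[[1]]
  expect_true(all(raw >= 0 & raw <= 1))
})

test_that("the toy mesh has grid geometry: counts, spacing, voxel mapping", {
  mesh <- build_toy_mesh(5, 5, 3)
  expect_identical(nrow(mesh$vertex_coords), 25L)
  expect_identical(nrow(mesh$faces), 32L)         # 2 * (rows-1) * (cols-1)
  expect_identical(anyDuplicated(mesh$vertex_to_voxel), 0L)
  # geodesic distance between grid neighbours equals the spacing
  d <- geodesic_distances(mesh, source = 7)
  expect_equal(unname(d[c("6", "8", "2", "12")]), rep(3, 4))
  expect_equal(unname(d["7"]), 0)
  expect_error(build_toy_mesh(1, 5), "at least 2")
  expect_error(build_toy_mesh(5, 5, 0), "positive")
})

test_that("the MEG tensor has the stated axes and pure noise decodes at chance", {
  gt <- ground_truth(3, 2, layer_latency_ms = c(100, 110), noise_sd = 1,
                     signal_amplitude = 0, seed = 2)
  meg <- simulate_meg_subject(gt, n_sensors = 306, n_trials = 4,
                              times_ms = seq(-100, 1000, by = 1))
  expect_identical(dim(meg$data), c(3L, 4L, 306L, 1101L))
  expect_error(simulate_meg_subject(gt, times_ms = seq(0, 50, 10)), "inside the simulated epoch")
  # all structure weights zero (amplitude 0): expected pairwise accuracy 50%
  gt2 <- ground_truth(4, 2, layer_latency_ms = c(10, 20), noise_sd = 1,
                      signal_amplitude = 0, seed = 6)
  accs <- vapply(1:10, function(s) {
    m <- simulate_meg_subject(gt2, n_sensors = 6, n_trials = 10,
                              times_ms = c(0, 10, 20, 30), subject = s)
    mean(decoding_rdm(m, t = 20, k = 5, n_reps = 10, seed = s)$values)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 5)
})
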