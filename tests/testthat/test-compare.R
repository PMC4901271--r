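# Similarity time courses, latencies, hierarchy statistics, contrasts.

make_series <- function(rdms, times) structure(rdms, times_ms = times, class = "rdm_series")

test_that("timecourse correlates brain RDMs with a model RDM over time", {
  set.seed(41)
  rdms <- lapply(1:4, function(i) correlation_rdm(matrix(rnorm(5 * 8), 5, 8)))
  ser <- make_series(rdms, c(0, 10, 20, 30))
  # model equal to the brain RDM at each t -> similarity 1 at that t
  tc <- timecourse(ser, rdms[[3]])
  expect_equal(unname(tc$values[1, 3]), 1)
  for (i in 1:4) expect_equal(unname(timecourse(ser, rdms[[i]])$values[1, i]), 1)
  expect_identical(tc$times_ms, c(0, 10, 20, 30))
  # 8 model RDMs -> 8 time courses
  models <- lapply(1:8, function(i) correlation_rdm(matrix(rnorm(5 * 8), 5, 8)))
  tcs <- lapply(models, function(m) timecourse(ser, m))
  expect_length(tcs, 8)
})

test_that("peak latency takes the earliest maximum inside the window", {
  tm <- seq(-100, 300, by = 10)
  v <- rep(0, length(tm)); v[tm == 120] <- 1
  tc <- similarity_timecourse(v, tm)
  expect_identical(unname(peak_latency(tc)), 120)
  # plateau 100..110 -> earliest tie
  v2 <- rep(0, length(tm)); v2[tm >= 100 & tm <= 110] <- 0.8
  expect_identical(unname(peak_latency(similarity_timecourse(v2, tm))), 100)
  # pre-stimulus values are excluded by the default window
  v3 <- v; v3[tm == -50] <- 2 / 2
  expect_identical(unname(peak_latency(similarity_timecourse(v3, tm))), 120)
  # explicit window is honoured and validated
  expect_identical(unname(peak_latency(similarity_timecourse(v3, tm), c(-100, 300))), -50)
  expect_error(peak_latency(tc, c(-200, 300)), "inside the epoch")
  # all-missing course -> NA
  expect_true(is.na(peak_latency(similarity_timecourse(rep(NA_real_, length(tm)), tm))))
})

test_that("peak latency is invariant to strictly monotone transforms of the course", {
  set.seed(55)
  tm <- seq(0, 200, by = 5)
  v <- stats::runif(length(tm), -0.5, 0.5)
  a <- peak_latency(similarity_timecourse(v, tm))
  b <- peak_latency(similarity_timecourse(tanh(3 * v), tm))
  expect_identical(a, b)
})

test_that("onset latency is the first timepoint of the earliest post-onset cluster", {
  tm <- seq(-100, 300, by = 20)
  tc <- similarity_timecourse(rep(0.1, length(tm)), tm)
  mask <- tm >= 80 & tm <= 200
  expect_identical(onset_latency(tc, mask), 80)
  expect_true(is.na(onset_latency(tc, rep(FALSE, length(tm)))))
  # pre-stimulus significance does not count as onset
  mask2 <- tm <= -40 | (tm >= 120 & tm <= 160)
  expect_identical(onset_latency(tc, mask2), 120)
})

test_that("hierarchy statistic recovers perfect, reversed, and absent ordering", {
  lat_up <- matrix(rep(c(100, 110, 120, 130), each = 5), nrow = 5)
  up <- hierarchy_statistic(lat_up, n_perm = 500, seed = 1)
  expect_true(all(up$per_subject_R == 1))
  expect_equal(up$group_R, 1)
  down <- hierarchy_statistic(lat_up[, 4:1], n_perm = 500, seed = 1)
  expect_true(all(down$per_subject_R == -1))
  # NA latencies are excluded pairwise; subjects below 2 valid layers drop
  m <- rbind(c(100, 110, 120), c(NA, NA, 130), c(100, 105, 205))
  expect_message(h <- hierarchy_statistic(m, n_perm = 100, seed = 4), "dropped 1")
  expect_identical(h$n_subjects, 2L)
  expect_equal(h$group_R, 1)
  expect_error(hierarchy_statistic(matrix(100, 3, 1)), "at least 2 layers")
})

test_that("hierarchy statistic on shuffled layer labels is centred on zero", {
  set.seed(67)
  lat <- matrix(100 + 10 * rep(1:6, each = 8) + rnorm(48, sd = 5), nrow = 8)
  rs <- replicate(1000, {
    perm <- sample(6)
    mean(apply(lat[, perm], 1, function(v) cor(1:6, v, method = "spearman")))
  })
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("hierarchy contrast and its exhaustive-enumeration p-value", {
  lat_up <- matrix(rep(c(100, 110, 120, 130), each = 10), nrow = 10) +
    matrix(rnorm(40, sd = 1), 10)
  a <- hierarchy_statistic(lat_up, n_perm = 200, seed = 2)
  b <- hierarchy_statistic(lat_up[, 4:1], n_perm = 200, seed = 2)
  self <- hierarchy_contrast(a, a, n_perm = 200, seed = 3)
  expect_equal(self$delta_R, 0)
  opp <- hierarchy_contrast(a, b, exact = TRUE)
  expect_gt(opp$delta_R, 1.9)            # opposite-sign hierarchies: |dR| near 2
  # exact-mode p equals the brute 2^10 oracle
  d <- a$per_subject_R - b$per_subject_R + rnorm(10, sd = 0.01)
  aa <- a; bb <- b
  aa$per_subject_R <- d; bb$per_subject_R <- rep(0, 10)
  got <- hierarchy_contrast(aa, bb, exact = TRUE)
  expect_identical(got$p_value, exhaustive_sign_p(d, tail = "two.sided"))
})

test_that("model difference time courses subtract subjectwise", {
  tm <- seq(0, 50, 10)
  a <- similarity_timecourse(matrix(runif(12, -1, 1), 2), tm, "a")
  z <- model_difference_timecourse(a, a)
  expect_true(all(z$values == 0))
  b <- similarity_timecourse(matrix(0.25, 2, 6), tm, "b")
  d <- model_difference_timecourse(a, b)
  expect_equal(d$values, a$values - 0.25)
  expect_identical(d$label, "a - b")
  expect_error(model_difference_timecourse(a, similarity_timecourse(matrix(0, 2, 3), tm[1:3])),
               "time axes differ")
})

test_that("ROI layer profiles peak at the matching layer and recover the gradient sign", {
  gt <- ground_truth(10, 8, noise_sd = 0, seed = 31)
  lr <- layer_rdms(simulate_layer_activations(gt, 200), quiet = TRUE)
  prof <- roi_layer_profile(lr[[8]], lr)
  expect_length(prof$similarity, 8)
  expect_identical(which.max(prof$similarity), 8L)
  # monotone synthetic profile -> positive R
  mono <- roi_layer_profile(lr[[8]], lr[c(1, 4, 6, 8)])
  expect_gt(mono$R, 0)
})
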