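# Occlusion-based receptive-field mapping with constructed extractors.

# Extractor whose single unit reads the mean of a fixed box; insensitive to
# everything outside the box.
box_extractor <- function(top, left, size) {
  function(images) {
    matrix(vapply(images, function(im) {
      m <- if (length(dim(im)) == 3L) im[, , 1] else im
      mean(m[top:(top + size - 1), left:(left + size - 1)])
    }, numeric(1)), ncol = 1)
  }
}

test_that("top_k_images ranks by activation with a sort oracle, K = 1 is the argmax", {
  set.seed(3)
  imgs <- lapply(1:30, function(i) matrix(runif(64), 8, 8))
  brightness <- function(images) matrix(vapply(images, mean, numeric(1)), ncol = 1)
  got <- top_k_images(brightness, imgs, unit = 1, K = 25)
  oracle <- order(-vapply(imgs, mean, numeric(1)))[1:25]
  expect_identical(got, oracle)
  expect_length(got, 25)
  expect_identical(top_k_images(brightness, imgs, 1, K = 1),
                   which.max(vapply(imgs, mean, numeric(1))))
})

test_that("discrepancy map localises the sensitive box and is ~0 elsewhere", {
  img <- matrix(1, 32, 32)
  ex <- box_extractor(11, 16, 10)
  dm <- discrepancy_map(ex, img, unit = 1, occluder_size = 6, stride = 1,
                        occluder_value = 0)
  peak <- arrayInd(which.max(dm), dim(dm))
  expect_true(peak[1] %in% 11:20 && peak[2] %in% 16:25)
  # pixels farther than one occluder footprint from the box are untouched:
  # discrepancy is attributed to every pixel under an occluder, so a border
  # of occluder_size - 1 around the box may pick up spillover
  outside <- unclass(dm); outside[6:25, 11:30] <- NA
  expect_lt(max(abs(outside), na.rm = TRUE), 1e-12)
  # occluding with the image's own content changes nothing
  dm0 <- discrepancy_map(ex, img, unit = 1, occluder_size = 6, occluder_value = 1)
  expect_lt(max(abs(dm0), na.rm = TRUE), 1e-12)
})

test_that("dense stride-1 sweep equals an exhaustive occlusion oracle", {
  set.seed(9)
  img <- matrix(runif(32 * 32), 32, 32)
  w <- matrix(rnorm(32 * 32), 32, 32)
  ex <- function(images) matrix(vapply(images, function(im) sum(im * w), numeric(1)), ncol = 1)
  os <- 5
  dm <- discrepancy_map(ex, img, unit = 1, occluder_size = os, occluder_value = 0.5)
  # oracle: loop occluder positions, accumulate drops per covered pixel
  base <- sum(img * w)
  acc <- matrix(0, 32, 32); cov <- matrix(0, 32, 32)
  for (top in 1:(32 - os + 1)) for (left in 1:(32 - os + 1)) {
    occ <- img
    occ[top:(top + os - 1), left:(left + os - 1)] <- 0.5
    drp <- base - sum(occ * w)
    acc[top:(top + os - 1), left:(left + os - 1)] <-
      acc[top:(top + os - 1), left:(left + os - 1)] + drp
    cov[top:(top + os - 1), left:(left + os - 1)] <-
      cov[top:(top + os - 1), left:(left + os - 1)] + 1
  }
  expect_equal(unclass(dm), acc / cov, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("random occluder sampling is seeded and respects image bounds", {
  img <- matrix(runif(16 * 16), 16, 16)
  ex <- box_extractor(5, 5, 4)
  d1 <- discrepancy_map(ex, img, 1, occluder_size = 4, n_samples = 50, seed = 7)
  d2 <- discrepancy_map(ex, img, 1, occluder_size = 4, n_samples = 50, seed = 7)
  expect_identical(unclass(d1), unclass(d2))
  expect_error(discrepancy_map(ex, img, 1, occluder_size = 20), "fit inside")
})

test_that("receptive field re-centres and averages: shifted bumps collapse to one", {
  bump <- matrix(0, 21, 21); bump[9:13, 9:13] <- outer(c(1,2,3,2,1), c(1,2,3,2,1))
  shift <- neurorsa:::shift_matrix
  m1 <- structure(shift(bump, 3, 0), class = "discrepancy_map")
  m2 <- structure(shift(bump, -4, 2), class = "discrepancy_map")
  m0 <- structure(bump, class = "discrepancy_map")
  rf_one <- receptive_field(list(m0))
  expect_equal(rf_one, bump)                     # already centred at (11, 11)
  rf <- receptive_field(list(m1, m2))
  expect_equal(rf, bump)                         # re-centring removes the shifts
  # identical maps -> RF equals the re-centred map
  expect_equal(receptive_field(list(m1, m1)), bump)
})

test_that("RF width grows with the extractor's pooling extent", {
  img <- matrix(1, 24, 24)
  width_of <- function(size) {
    ex <- box_extractor(8, 8, size)
    dm <- discrepancy_map(ex, img, 1, occluder_size = 4, occluder_value = 0)
    rf <- receptive_field(list(dm))
    sum(rf > 0.5 * max(rf))
  }
  expect_lt(width_of(4), width_of(10))
})

test_that("selectivity region thresholds the RF-weighted contribution map at 50%", {
  fm <- matrix(0, 15, 15); fm[4, 11] <- 1          # single-peak feature map
  rf <- matrix(0, 5, 5); rf[3, 3] <- 2; rf[2:4, 2:4] <- rf[2:4, 2:4] + 1
  reg <- selectivity_region(fm, rf, threshold_frac = 0.5)
  expect_true(reg$region[4, 11])                   # contains the argmax
  expect_identical(which.max(reg$contribution), which.max(fm * 1))
  # uniform contribution map -> everything selected
  regu <- selectivity_region(matrix(1, 8, 8), matrix(1, 1, 1), 0.5)
  expect_true(all(regu$region))
})

test_that("extractor failures propagate with position context", {
  img <- matrix(1, 12, 12)
  bad <- function(images) stop("boom")
  expect_error(discrepancy_map(bad, img, 1, occluder_size = 4), "boom")
})
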