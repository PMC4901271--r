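# RDM container, correlation-distance construction, voxel restriction.

test_that("condensed/square round trip is lossless and uses lexicographic pair order", {
  set.seed(1)
  n <- 7
  vals <- runif(n * (n - 1) / 2, 0, 2)
  x <- rdm(vals, n)
  sq <- rdm_square(x)
  expect_true(all(is.na(diag(sq))))
  expect_identical(sq, t(sq))
  back <- rdm_condense(sq)
  expect_identical(back$values, vals)
  # entry (i, j) of the square form must sit at pair_index(i, j, n)
  for (probe in list(c(1, 2), c(2, 5), c(6, 7)))
    expect_identical(sq[probe[1], probe[2]], vals[pair_index(probe[1], probe[2], n)])
})

test_that("rdm validates length, bounds and metric", {
  expect_error(rdm(1:5, 4), "expected 6")
  expect_error(rdm(rep(3, 6), 4), "outside")
  expect_error(rdm(rep(150, 6), 4, metric = "decoding_accuracy_percent"), "outside")
  expect_silent(r <- rdm(rep(50, 6), 4, metric = "decoding_accuracy_percent"))
  expect_error(rdm(numeric(1), 2), "at least 3")
})

test_that("correlation_rdm handles perfect correlation, anticorrelation, and matches the oracle", {
  base <- c(0.3, 1.2, -0.5, 2.0, 0.1)
  x <- rbind(base, base + 5, -base)          # monotone copy and exact negation
  r <- correlation_rdm(x)
  expect_equal(r$values[pair_index(1, 2, 3)], 0)       # identical ranks
  expect_equal(r$values[pair_index(1, 3, 3)], 2)       # reversed ranks
  set.seed(7)
  for (rep in 1:20) {
    y <- matrix(rnorm(4 * 5), 4, 5)
    expect_equal(correlation_rdm(y)$values, correlation_rdm_oracle(y), tolerance = 1e-12)
  }
  # with ties (average ranks) the oracle must still agree
  y <- matrix(sample(1:3, 24, replace = TRUE), 4, 6)
  y[1, ] <- y[1, ] + 0.5 * seq_len(6)        # avoid constant rows
  expect_equal(correlation_rdm(y)$values, correlation_rdm_oracle(y), tolerance = 1e-12)
})

test_that("correlation_rdm is invariant to strictly monotone transforms of each pattern", {
  set.seed(11)
  x <- matrix(rnorm(5 * 8), 5, 8)
  y <- x
  y[2, ] <- exp(x[2, ])                       # monotone per-vector transforms
  y[4, ] <- x[4, ]^3 + 10
  expect_equal(correlation_rdm(x)$values, correlation_rdm(y)$values, tolerance = 1e-12)
})

test_that("constant pattern vectors yield flagged missing entries, not zeros", {
  x <- rbind(c(1, 2, 3, 4), c(2, 2, 2, 2), c(4, 3, 1, 2))
  expect_message(r <- correlation_rdm(x), "2 of 3 entries undefined")
  expect_true(is.na(r$values[pair_index(1, 2, 3)]))
  expect_true(is.na(r$values[pair_index(2, 3, 3)]))
  expect_false(is.na(r$values[pair_index(1, 3, 3)]))
  expect_identical(attr(r, "n_missing"), 2L)
})

test_that("compare_rdms matches the rank oracle, is symmetric, and honours missing entries", {
  set.seed(3)
  for (rep in 1:10) {
    a <- rdm(runif(10, 0, 2), 5)
    b <- rdm(runif(10, 0, 2), 5)
    expect_equal(compare_rdms(a, b), spearman_oracle(a$values, b$values), tolerance = 1e-12)
    expect_identical(compare_rdms(a, b), compare_rdms(b, a))
  }
  a <- rdm(c(0.1, 0.4, 0.3, 1.1, 0.9, 0.2), 4)
  expect_equal(compare_rdms(a, a), 1)
  mono <- rdm(sqrt(a$values / 2) * 2, 4)     # strictly monotone transform
  expect_equal(compare_rdms(a, mono), 1)
  # missing entries are excluded pairwise
  b <- a; b$values[2] <- NA
  keep <- setdiff(1:6, 2)
  expect_equal(compare_rdms(a, b),
               spearman_oracle(a$values[keep], a$values[keep]))
  # fewer than 3 valid pairs -> undefined, flagged
  c1 <- a; c1$values[1:4] <- NA
  expect_warning(res <- compare_rdms(a, c1), "undefined")
  expect_true(is.na(res))
})

test_that("compare_rdms is invariant under a common condition reordering", {
  set.seed(5)
  n <- 6
  x <- matrix(rnorm(n * 10), n, 10)
  y <- matrix(rnorm(n * 10), n, 10)
  perm <- sample(n)
  r0 <- compare_rdms(correlation_rdm(x), correlation_rdm(y))
  r1 <- compare_rdms(correlation_rdm(x[perm, ]), correlation_rdm(y[perm, ]))
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("restrict_to_top_voxels keeps the n largest statistics with id-order tie breaking", {
  p <- spatial_patterns(matrix(rnorm(3 * 5), 3, 5))
  stat <- c(3, 1, 4, 1, 5)
  top2 <- restrict_to_top_voxels(p, stat, 2)
  expect_identical(top2$voxel_ids, c("vox3", "vox5"))   # statistics 4 and 5
  expect_identical(restrict_to_top_voxels(p, stat, 5)$data, p$data)  # identity
  tie <- restrict_to_top_voxels(p, c(1, 1, 1, 1, 1), 2)
  expect_identical(tie$voxel_ids, c("vox1", "vox2"))    # earlier ids win ties
  expect_error(restrict_to_top_voxels(p, stat, 0), "positive")
  expect_error(restrict_to_top_voxels(p, stat, 6), "exceeds")
  # 100 of 200, as in a functional ROI restriction
  p200 <- spatial_patterns(matrix(rnorm(3 * 200), 3, 200))
  expect_identical(ncol(restrict_to_top_voxels(p200, rnorm(200), 100)$data), 100L)
})
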