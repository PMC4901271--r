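# Sign-permutation tests, cluster-extent correction, FDR, bootstrap.

test_that("exact sign-permutation p equals the exhaustive 2^10 oracle", {
  set.seed(101)
  for (rep in 1:5) {
    x <- rnorm(10, mean = 0.4)
    for (tail in c("greater", "two.sided", "less")) {
      got <- sign_permutation_test(matrix(x, ncol = 1), tail = tail, exact = TRUE)
      expect_identical(got, exhaustive_sign_p(x, tail = tail))
    }
  }
  # exact mode is invariant to subject ordering
  x <- rnorm(10, 0.3)
  expect_identical(sign_permutation_test(matrix(x, ncol = 1), exact = TRUE),
                   sign_permutation_test(matrix(rev(x), ncol = 1), exact = TRUE))
})

test_that("Monte-Carlo p-values are close to exact, reproducible, and never zero", {
  set.seed(5)
  x <- matrix(rnorm(12 * 4, mean = 0.3), 12, 4)
  p1 <- sign_permutation_test(x, n_perm = 4000, seed = 9)
  p2 <- sign_permutation_test(x, n_perm = 4000, seed = 9)
  expect_identical(p1, p2)
  pe <- sapply(1:4, function(j) exhaustive_sign_p(x[, j]))
  expect_lt(max(abs(p1 - pe)), 0.03)
  expect_true(all(p1 >= 1 / 4001))
  big <- matrix(abs(rnorm(12, 5)) + 5, ncol = 1)
  expect_equal(sign_permutation_test(big, n_perm = 999, seed = 1), 1 / 1000)
  expect_error(sign_permutation_test(matrix(1, 1, 2)), "at least 2 subjects")
  expect_error(sign_permutation_test(x, n_perm = 0), "at least 1")
})

test_that("null data produce approximately uniform p-values", {
  set.seed(7)
  x <- matrix(rnorm(15 * 120), 15, 120)
  p <- sign_permutation_test(x, n_perm = 500, seed = 3)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster extent weighting lets a long effect survive where a blip does not", {
  set.seed(19)
  n <- 14; np <- 60
  x <- matrix(rnorm(n * np, sd = 1), n, np)
  x[, 20:34] <- x[, 20:34] + 1.3        # 15-point effect
  x[, 50] <- x[, 50] + 1.3              # single-point blip of equal height
  res <- cluster_extent_correct(x, n_perm = 1000, seed = 11)
  expect_true(all(res$significant_mask[20:34]))
  expect_false(res$significant_mask[50])
  # conservativeness: never more significant points than uncorrected threshold
  expect_true(all(res$significant_mask <= (res$point_p < res$cluster_def_p)))
  # no supra-threshold points -> empty, valid result
  res0 <- cluster_extent_correct(matrix(rnorm(n * 10, mean = -5), n, 10),
                                 n_perm = 200, seed = 1)
  expect_length(res0$clusters, 0)
  expect_false(any(res0$significant_mask))
})

test_that("cluster correction respects mesh adjacency for surface maps", {
  set.seed(29)
  mesh <- build_toy_mesh(5, 5, 3)
  adj <- neurorsa:::mesh_edges(mesh$faces, mesh$vertex_coords)$edges
  patch <- c(7, 8, 12, 13)                  # a connected 2x2 block
  x <- matrix(rnorm(12 * 25), 12, 25)
  x[, patch] <- x[, patch] + 1.6
  res <- cluster_extent_correct(x, n_perm = 500, seed = 2, adjacency = adj)
  expect_true(all(res$significant_mask[patch]))
  ext <- vapply(res$clusters, function(cl) cl$extent, 0L)
  expect_true(any(vapply(res$clusters, function(cl) all(patch %in% cl$members), TRUE)))
})

test_that("permutation inference is reproducible and ties to its seed", {
  x <- matrix(rnorm(10 * 30, 0.2), 10, 30)
  r1 <- cluster_extent_correct(x, n_perm = 300, seed = 8)
  r2 <- cluster_extent_correct(x, n_perm = 300, seed = 8)
  expect_identical(r1$point_p, r2$point_p)
  expect_identical(r1$null_max_extent, r2$null_max_extent)
})

test_that("FDR correction matches a hand step-up oracle and is monotone", {
  p <- c(0.001, 0.01, 0.02, 0.9)
  expect_identical(fdr_correct(p, 0.05), bh_oracle(p, 0.05))
  expect_identical(fdr_correct(p, 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdr_correct(rep(1, 6), 0.05), rep(FALSE, 6))
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(15)
    expect_identical(fdr_correct(p, 0.05), bh_oracle(p, 0.05))
    # shrinking any p never removes discoveries
    p2 <- p; i <- sample(15, 1); p2[i] <- p2[i] / 10
    expect_true(all(fdr_correct(p, 0.05) <= fdr_correct(p2, 0.05) |
                      !fdr_correct(p, 0.05)))
    expect_true(sum(fdr_correct(p2, 0.05)) >= sum(fdr_correct(p, 0.05)))
  }
})

test_that("bootstrap SE is zero for identical subjects and tracks sigma/sqrt(n)", {
  expect_identical(bootstrap_se(rep(3.2, 12), n_boot = 200, seed = 1), 0)
  # averaged over replicate samples, SE of the mean of n normals ~ sigma/sqrt(n)
  set.seed(13)
  n <- 15; sigma <- 2
  ratio <- mean(replicate(40, {
    x <- rnorm(n, sd = sigma)
    bootstrap_se(x, n_boot = 400, seed = sample.int(1e6, 1)) / (sigma / sqrt(n))
  }))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("bootstrap difference CI covers the truth and contains 0 for identical inputs", {
  set.seed(17)
  a <- rnorm(15, 100, 5)
  ci0 <- bootstrap_ci_difference(a, a, n_boot = 300, seed = 2)
  expect_identical(ci0$estimate, 0)
  expect_true(ci0$ci[1] <= 0 && ci0$ci[2] >= 0)
  # a 40 ms shift is inside the 95% interval in most replicates
  cover <- mean(replicate(40, {
    b <- rnorm(15, 140, 10); a2 <- rnorm(15, 100, 10)
    ci <- bootstrap_ci_difference(b, a2, n_boot = 300, seed = sample.int(1e6, 1))
    ci$ci[1] <= 40 && 40 <= ci$ci[2]
  }))
  expect_gte(cover, 0.8)
})

test_that("permutation signs are applied jointly across points, preserving structure", {
  # two perfectly correlated points must always receive identical permuted means
  x <- cbind(rnorm(10), 0)
  x[, 2] <- x[, 1]
  s <- neurorsa:::sign_matrix(10, 200, seed = 4)
  pm <- (s %*% x) / 10
  expect_identical(pm[, 1], pm[, 2])
})
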