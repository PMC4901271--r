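# Nonparametric group inference: sign-permutation tests, cluster-extent
# multiple-comparison correction, Benjamini-Hochberg FDR and subject-pool
# bootstrap.

# Sign matrix for permutation tests: rows are permutations, the first row is
# the identity (so p-values can never be zero).  In exact mode all 2^n sign
# patterns are enumerated.
sign_matrix <- function(n_subjects, n_perm, seed, exact = FALSE) {
  if (exact) {
    if (n_subjects > 20L) stop("exact enumeration is limited to 20 subjects")
    b <- as.matrix(expand.grid(rep(list(c(1, -1)), n_subjects)))
    # put the identity (all +1) first; order of the rest is irrelevant
    idx <- order(rowSums(b == 1), decreasing = TRUE)
    return(unname(b[idx, , drop = FALSE]))
  }
  if (n_perm < 1L) stop("n_perm must be at least 1")
  s <- with_seed(seed,
    matrix(sample(c(1, -1), n_subjects * n_perm, replace = TRUE), n_perm, n_subjects))
  rbind(rep(1, n_subjects), s)
}

#' Sign-permutation test across subjects
#'
#' Tests, at every point (timepoint, vertex, ...), whether the group mean of
#' a per-subject statistic differs from zero, by randomly flipping the sign
#' of each subject's values.  Signs are drawn per subject and applied across
#' all points jointly, preserving each subject's spatial/temporal
#' correlation structure.  The identity permutation is always included, so
#' `p >= 1 / (n_perm + 1)`.
#'
#' @param subject_values subjects x points numeric matrix; a plain vector is
#'   treated as a single point (one value per subject).
#' @param n_perm number of random sign draws (default 10000); ignored in
#'   exact mode.
#' @param seed integer seed.
#' @param tail `"greater"` (right tail, default: directional similarity
#'   hypotheses), `"less"`, or `"two.sided"`.
#' @param exact enumerate all `2^n` sign patterns (exact p-values; feasible
#'   up to 20 subjects).
#' @return numeric vector of per-point p-values.
#' @export
sign_permutation_test <- function(subject_values, n_perm = 10000L, seed = 1L,
                                  tail = c("greater", "two.sided", "less"),
                                  exact = FALSE) {
  tail <- match.arg(tail)
  x <- as.matrix(subject_values)
  n <- nrow(x)
  if (n < 2L) stop("at least 2 subjects are required")
  s <- sign_matrix(n, n_perm, seed, exact)
  pm <- (s %*% x) / n                     # permutation group means, B x points
  obs <- pm[1, ]
  stat <- switch(tail, greater = pm, less = -pm, two.sided = abs(pm))
  ostat <- switch(tail, greater = obs, less = -obs, two.sided = abs(obs))
  p <- colMeans(stat >= matrix(ostat, nrow(stat), ncol(stat), byrow = TRUE))
  unname(p)
}

# Per-row p-value maps for every permutation: p[b, j] = fraction of
# permutations whose statistic at point j is >= permutation b's.  Used to
# build the max-cluster-extent null with the same thresholding as the
# observed map.
perm_p_maps <- function(stat) {
  B <- nrow(stat)
  out <- apply(stat, 2L, function(col) (B - rank(col, ties.method = "min") + 1) / B)
  matrix(out, nrow = B)     # apply drops to a vector for a single point
}

# Contiguous clusters of TRUE entries: 1-D runs, or connected components of
# the adjacency graph restricted to the supra-threshold points.
find_clusters <- function(mask, adjacency = NULL) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  if (is.null(adjacency)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lapply(which(r$values), function(k) starts[k]:ends[k])
  } else {
    sub <- adjacency[adjacency[, 1] %in% idx & adjacency[, 2] %in% idx, , drop = FALSE]
    g <- igraph::make_graph(t(matrix(match(sub, idx), ncol = 2)), n = length(idx),
                            directed = FALSE)
    comp <- igraph::components(g)$membership
    lapply(seq_len(max(comp)), function(k) sort(idx[comp == k]))
  }
}

max_cluster_extent <- function(mask, adjacency = NULL) {
  cl <- find_clusters(mask, adjacency)
  if (!length(cl)) 0L else max(lengths(cl))
}

#' Cluster-extent corrected sign-permutation inference
#'
#' Corrects for multiple comparisons over ordered points (timepoints or mesh
#' vertices) by cluster extent, with every data point weighted equally:
#' per-point sign-permutation p-values are thresholded at `cluster_def_p`,
#' contiguous supra-threshold points form clusters scored by their extent
#' (number of points), and each observed cluster is compared with the null
#' distribution of the maximal cluster extent over sign permutations (each
#' permutation thresholded exactly like the observed data).  A cluster is
#' significant when its corrected p-value is below
#' `cluster_p / bonferroni_factor` (the Bonferroni factor accommodates
#' families of maps, for example 8 layers x 2 hemispheres = 16).
#'
#' @inheritParams sign_permutation_test
#' @param cluster_def_p cluster definition threshold (default 0.05).
#' @param cluster_p cluster extent threshold (default 0.05).
#' @param bonferroni_factor Bonferroni correction factor applied to
#'   `cluster_p` (default 1).
#' @param adjacency `NULL` for 1-D (consecutive points are neighbours) or a
#'   two-column matrix of neighbouring point indices (for example mesh
#'   edges) for surface maps.
#' @return An object of class `"cluster_result"`: `clusters` (list of
#'   `members`, `extent`, `p_corrected`), `point_p` (uncorrected per-point
#'   p), `significant_mask` (points in significant clusters),
#'   `null_max_extent`, and the thresholds used.
#' @export
cluster_extent_correct <- function(subject_values, cluster_def_p = 0.05,
                                   cluster_p = 0.05, n_perm = 10000L,
                                   bonferroni_factor = 1L, seed = 1L,
                                   tail = c("greater", "two.sided", "less"),
                                   adjacency = NULL, exact = FALSE) {
  tail <- match.arg(tail)
  x <- as.matrix(subject_values)
  n <- nrow(x)
  if (n < 2L) stop("at least 2 subjects are required")
  s <- sign_matrix(n, n_perm, seed, exact)
  pm <- (s %*% x) / n
  stat <- switch(tail, greater = pm, less = -pm, two.sided = abs(pm))
  pmaps <- perm_p_maps(stat)              # B x points
  obs_p <- pmaps[1, ]
  null_max <- apply(pmaps < cluster_def_p, 1L, max_cluster_extent, adjacency = adjacency)
  clusters <- find_clusters(obs_p < cluster_def_p, adjacency)
  clusters <- lapply(clusters, function(memb) {
    extent <- length(memb)
    list(members = memb, extent = extent,
         p_corrected = mean(null_max >= extent))
  })
  alpha <- cluster_p / bonferroni_factor
  sig <- vapply(clusters, function(cl) cl$p_corrected < alpha, TRUE)
  mask <- rep(FALSE, ncol(x))
  for (cl in clusters[sig]) mask[cl$members] <- TRUE
  structure(list(clusters = clusters, point_p = obs_p, significant_mask = mask,
                 null_max_extent = null_max, cluster_def_p = cluster_def_p,
                 cluster_p = cluster_p, bonferroni_factor = bonferroni_factor,
                 tail = tail, n_perm = nrow(s) - 1L),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  nsig <- sum(x$significant_mask)
  cat(sprintf(paste0("cluster_result: %d cluster(s), %d significant point(s)\n",
                     "  cluster_def_p %g, cluster_p %g / bonferroni %d, %s tail, %d permutations\n"),
              length(x$clusters), nsig, x$cluster_def_p, x$cluster_p,
              x$bonferroni_factor, x$tail, x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  extent %d (points %d..%d), corrected p = %.4g\n",
                cl$extent, min(cl$members), max(cl$members), cl$p_corrected))
  invisible(x)
}

#' Benjamini-Hochberg FDR significance mask
#'
#' @param p_values numeric p-values.
#' @param q FDR level (default 0.05).
#' @return logical mask of discoveries (BH-adjusted p <= q).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Bootstrap standard error over the subject pool
#'
#' Resamples subjects with replacement, recomputes the group statistic on
#' every resample, and returns the standard deviation of the bootstrap
#' distribution as the standard error of the statistic.
#'
#' @param subject_statistics per-subject values: a vector, or a matrix with
#'   one row per subject.
#' @param statistic function mapping the resampled rows to the group
#'   statistic (default: the mean over subjects, per column).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return standard error (scalar, or vector if `statistic` returns one).
#' @export
bootstrap_se <- function(subject_statistics, statistic = NULL,
                         n_boot = 1000L, seed = 1L) {
  x <- as.matrix(subject_statistics)
  n <- nrow(x)
  if (is.null(statistic)) statistic <- function(m) colMeans(m)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      as.numeric(statistic(x[idx, , drop = FALSE]))
    }, numeric(length(statistic(x))))
  })
  if (is.matrix(boot)) apply(boot, 1L, stats::sd) else stats::sd(boot)
}

#' Bootstrap percentile confidence interval for a group difference
#'
#' Resamples the subject pool with replacement and computes the percentile
#' interval of a difference statistic between two paired per-subject
#' measurements (for example peak latencies under two models, or a
#' divergence-time statistic).
#'
#' @param a,b paired per-subject values (same subjects, same order).
#' @param statistic function of the resampled `(a, b)` vectors returning a
#'   scalar (default: mean difference `mean(a - b)`).
#' @param n_boot number of resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `estimate` (statistic on the full sample), `ci`
#'   (length-2 interval), `level`.
#' @export
bootstrap_ci_difference <- function(a, b, statistic = NULL, n_boot = 1000L,
                                    level = 0.95, seed = 1L) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (is.null(statistic)) statistic <- function(a, b) mean(a - b)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      statistic(a[idx], b[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  list(estimate = statistic(a, b),
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
       level = level)
}
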