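# Independent brute-force oracles, deliberately implemented without the
# package's (or base R's high-level) machinery, used to pin down expected
# values.

# Average ranks via the counting formula: rank_i = #(x < x_i) + (#(x == x_i) + 1)/2.
rank_oracle <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Spearman's R as Pearson on explicitly computed average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank_oracle(x); ry <- rank_oracle(y)
  dx <- rx - sum(rx) / length(rx); dy <- ry - sum(ry) / length(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Condensed correlation-distance RDM by looping over pairs with the oracle.
correlation_rdm_oracle <- function(x) {
  n <- nrow(x)
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out <- c(out, 1 - spearman_oracle(x[i, ], x[j, ]))
  out
}

# All-pairs shortest paths by Floyd-Warshall on a dense edge-weight matrix.
floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- w
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Dense edge-weight matrix (Inf where no edge) of a surface mesh.
mesh_weight_matrix <- function(mesh) {
  nv <- nrow(mesh$vertex_coords)
  w <- matrix(Inf, nv, nv)
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(1, 3)])
  len <- sqrt(rowSums((mesh$vertex_coords[e[, 1], , drop = FALSE] -
                         mesh$vertex_coords[e[, 2], , drop = FALSE])^2))
  for (r in seq_len(nrow(e))) {
    w[e[r, 1], e[r, 2]] <- min(w[e[r, 1], e[r, 2]], len[r])
    w[e[r, 2], e[r, 1]] <- min(w[e[r, 2], e[r, 1]], len[r])
  }
  w
}

# Exhaustive sign-permutation p-value for one point.  The observed value is
# the identity row of the enumeration itself, so the identity permutation is
# counted even when a separately computed mean would differ in the last ulp.
exhaustive_sign_p <- function(x, tail = "greater") {
  n <- length(x)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  pm <- as.vector(signs %*% x) / n
  obs <- pm[1]                      # expand.grid's first row is all +1
  if (tail == "two.sided") { pm <- abs(pm); obs <- abs(obs) }
  if (tail == "less") { pm <- -pm; obs <- -obs }
  mean(pm >= obs)
}

# Benjamini-Hochberg step-up by hand.
bh_oracle <- function(p, q) {
  n <- length(p)
  ord <- order(p)
  thresh <- q * seq_len(n) / n
  passed <- which(p[ord] <= thresh)
  mask <- rep(FALSE, n)
  if (length(passed)) mask[ord[seq_len(max(passed))]] <- TRUE
  mask
}

# Small deterministic trial tensor: conditions with distinct mean patterns
# plus Gaussian noise.
make_test_tensor <- function(n_cond = 3, n_trials = 10, n_sensors = 6,
                             times_ms = c(0, 10, 20), signal = 1, noise = 1,
                             seed = 42) {
  set.seed(seed)
  mu <- matrix(rnorm(n_cond * n_sensors, sd = signal), n_cond, n_sensors)
  x <- array(0, dim = c(n_cond, n_trials, n_sensors, length(times_ms)))
  for (cc in seq_len(n_cond)) for (m in seq_len(n_trials))
    x[cc, m, , ] <- mu[cc, ] + matrix(rnorm(n_sensors * length(times_ms), sd = noise),
                                      n_sensors, length(times_ms))
  trial_tensor(x, times_ms)
}
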