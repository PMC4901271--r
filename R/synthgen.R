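# Synthetic multi-subject MEG/fMRI/model-activation generator.  Every
# downstream stage of the pipeline (RDM construction, searchlight mapping,
# latency statistics, group inference) is testable against known ground
# truth because the generator injects a controllable representational
# structure: each model layer has a target RDM, a latency at which its
# structure peaks in the simulated sensor signal, and per-region mixing
# weights for the simulated voxel patterns.

#' Ground truth for the synthetic experiment
#'
#' Bundles everything the generator needs: per-layer target similarity
#' structures, the latency (ms) at which each layer's structure peaks in the
#' simulated MEG signal, per-region layer mixing weights for simulated fMRI
#' patterns, the temporal kernel width, the trial/voxel noise level, and the
#' master seed from which all substreams are derived.
#'
#' Default latencies follow `100 + 10 * l` ms for layer `l` when
#' `hierarchy_sign = +1` (deeper layers peak later), the reversed order for
#' `-1`, and a common latency for `0`.  Layer target RDMs are drawn from
#' low-dimensional latent condition embeddings (3 latent dimensions), which
#' yields widely spread pairwise correlations and mutually distinct targets.
#'
#' @param n_conditions number of conditions (stimuli).
#' @param n_layers number of model layers.
#' @param layer_latency_ms per-layer latency in ms; default per
#'   `hierarchy_sign` as described above.
#' @param layer_region_weights optional region x layer matrix of mixing
#'   weights in `[0, 1]` with rows named by region; row sums must be <= 1.
#' @param hierarchy_sign `+1`, `-1` or `0`; used only to build default
#'   latencies.
#' @param noise_sd trial/voxel noise standard deviation (signal patterns
#'   have unit per-sensor variance; see the methods vignette).
#' @param kernel_sd_ms width (SD, ms) of the Gaussian temporal kernel with
#'   which each layer's structure enters the sensor signal.
#' @param signal_amplitude peak amplitude of each layer's structured signal.
#' @param latent_dim latent dimensionality of the target-RDM embeddings.
#' @param seed master integer seed.
#' @return An object of class `"ground_truth"` with element
#'   `layer_target_sim` (list of condition x condition target similarity
#'   matrices) among the fields above.
#' @export
ground_truth <- function(n_conditions, n_layers,
                         layer_latency_ms = NULL,
                         layer_region_weights = NULL,
                         hierarchy_sign = +1,
                         noise_sd = 10,
                         kernel_sd_ms = 20,
                         signal_amplitude = 1,
                         latent_dim = 3L,
                         seed = 1L) {
  n <- as.integer(n_conditions)
  if (n < 3L) stop("at least 3 conditions are required (the RDM is degenerate otherwise)")
  nl <- as.integer(n_layers)
  if (nl < 1L) stop("at least one layer is required")
  if (!hierarchy_sign %in% c(-1, 0, 1)) stop("hierarchy_sign must be -1, 0 or +1")
  if (is.null(layer_latency_ms)) {
    asc <- 100 + 10 * seq_len(nl)
    layer_latency_ms <- switch(as.character(hierarchy_sign),
                               "1" = asc, "-1" = rev(asc),
                               "0" = rep(100 + 10 * (nl + 1) / 2, nl))
  }
  if (length(layer_latency_ms) != nl) stop("one latency per layer required")
  if (!is.null(layer_region_weights)) {
    layer_region_weights <- as.matrix(layer_region_weights)
    if (ncol(layer_region_weights) != nl) stop("one weight column per layer required")
    if (any(layer_region_weights < 0 | layer_region_weights > 1))
      stop("region weights must lie in [0, 1]")
    if (any(rowSums(layer_region_weights) > 1 + 1e-9))
      stop("region weight rows must sum to at most 1")
  }
  targets <- lapply(seq_len(nl), function(l)
    with_seed(derive_seed(seed, "target", l), {
      z <- matrix(stats::rnorm(n * latent_dim), n, latent_dim)
      s <- stats::cor(t(z))
      diag(s) <- 1
      s
    }))
  structure(list(n_conditions = n, n_layers = nl,
                 layer_target_sim = targets,
                 layer_latency_ms = as.numeric(layer_latency_ms),
                 layer_region_weights = layer_region_weights,
                 hierarchy_sign = hierarchy_sign,
                 noise_sd = noise_sd, kernel_sd_ms = kernel_sd_ms,
                 signal_amplitude = signal_amplitude, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("ground_truth: %d conditions, %d layers, latencies %s ms,\n",
                     "  hierarchy_sign %+d, noise_sd %g, kernel_sd %g ms, seed %d\n"),
              x$n_conditions, x$n_layers,
              paste(x$layer_latency_ms, collapse = ", "),
              x$hierarchy_sign, x$noise_sd, x$kernel_sd_ms, x$seed))
  invisible(x)
}

#' Target RDMs implied by the ground truth
#'
#' @param gt a [ground_truth()].
#' @return list of [rdm()] objects (`1 -` target similarity, clipped to `[0, 2]`).
#' @export
target_rdms <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  lapply(gt$layer_target_sim, function(s) rdm_condense(1 - s))
}

# Content hash of a target similarity matrix, used to key pattern
# substreams so that equal targets map to equal draws.
target_key <- function(S) {
  h <- 0
  for (cc in utf8ToInt(paste(sprintf("%.12g", S), collapse = ",")))
    h <- (h * 31 + cc) %% 2147483647
  sprintf("t%.0f", h)
}

# Draw a conditions x n_features pattern matrix whose rows have *exactly*
# the pairwise Pearson correlations S (zero row means, unit row norms):
# rows of Q are an orthonormal, zero-mean basis; P = S^{1/2} Q.  Requires
# n_features >= n_conditions + 1; below that an approximate Gaussian draw
# with row covariance S is returned.
pattern_with_similarity <- function(S, n_features, seed) {
  n <- nrow(S)
  e <- eigen(S, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  with_seed(seed, {
    if (n_features >= n + 1L) {
      g <- matrix(stats::rnorm(n * n_features), n, n_features)
      g <- g - rowMeans(g)                 # rows orthogonal to the constant
      q <- qr.Q(qr(t(g)))[, seq_len(n), drop = FALSE]  # zero-mean orthonormal basis
      A %*% t(q)
    } else {
      (A %*% matrix(stats::rnorm(n * n_features), n, n_features)) / sqrt(n_features)
    }
  })
}

#' Simulate layered model activations
#'
#' Draws, for each layer, a conditions-by-units activation matrix whose
#' condition-pattern correlation structure realises that layer's target
#' similarity matrix (exactly, per-sensor-rescaled, when `noise_sd = 0` and
#' `units >= n_conditions + 1`), plus i.i.d. Gaussian unit noise of standard
#' deviation `gt$noise_sd * noise_scale`.
#'
#' @param gt a [ground_truth()].
#' @param units_per_layer integer vector (recycled) of units per layer;
#'   each must be at least 2.
#' @param noise_scale multiplier applied to `gt$noise_sd` for unit noise
#'   (model activations are typically far less noisy than single trials;
#'   default 0).
#' @return a [layer_activations()].
#' @export
simulate_layer_activations <- function(gt, units_per_layer = 1000L, noise_scale = 0) {
  stopifnot(inherits(gt, "ground_truth"))
  units <- rep_len(as.integer(units_per_layer), gt$n_layers)
  if (any(units < 2L)) stop("each layer needs at least 2 units")
  layers <- lapply(seq_len(gt$n_layers), function(l) {
    # substream keyed on the target's content: identical targets yield
    # identical activations (and hence exactly identical layer RDMs)
    p <- pattern_with_similarity(gt$layer_target_sim[[l]], units[l],
                                 derive_seed(gt$seed, "acts",
                                             target_key(gt$layer_target_sim[[l]])))
    p <- p * sqrt(units[l])                # unit per-feature signal variance
    if (noise_scale > 0 && gt$noise_sd > 0)
      p <- p + with_seed(derive_seed(gt$seed, "acts_noise", l),
                         matrix(stats::rnorm(length(p), sd = gt$noise_sd * noise_scale),
                                nrow(p), ncol(p)))
    p
  })
  layer_activations(layers)
}

#' Simulate one subject's MEG trial tensor
#'
#' The condition-pattern geometry of the noiseless sensor signal at time `t`
#' is a mixture of the layers' target structures, each weighted by a
#' Gaussian temporal kernel of SD `gt$kernel_sd_ms` centred on that layer's
#' latency; every trial adds i.i.d. Gaussian sensor noise of SD
#' `gt$noise_sd`.  Decoding-RDM similarity to a given layer's RDM therefore
#' peaks near that layer's latency, which is the recovery property the
#' pipeline is validated against.
#'
#' The layer-specific sensor patterns are drawn once per ground truth (they
#' represent the condition structure, shared across subjects); noise is
#' subject-specific.
#'
#' Trial time series are smoothed with a centred sliding-window average of
#' width `smooth_ms` (default 20 ms), emulating the standard preprocessing
#' of evoked sensor data; this leaves the latency structure intact (the
#' window is symmetric) while giving the noise the temporal correlation of
#' real preprocessed recordings.  Set `smooth_ms = 0` for raw white noise.
#'
#' @param gt a [ground_truth()]; all latencies must lie inside `times_ms`.
#' @param n_sensors number of sensors.
#' @param n_trials trials per condition (>= 2).
#' @param times_ms strictly increasing time axis in ms.
#' @param subject subject index (integer) or label; selects the noise
#'   substream.
#' @param smooth_ms sliding-window width in ms (default 20).
#' @return a [trial_tensor()].
#' @export
simulate_meg_subject <- function(gt, n_sensors = 306L, n_trials = 30L,
                                 times_ms = seq(-100, 1000, by = 1),
                                 subject = 1L, smooth_ms = 20) {
  stopifnot(inherits(gt, "ground_truth"))
  if (any(gt$layer_latency_ms < min(times_ms) | gt$layer_latency_ms > max(times_ms)))
    stop("all layer latencies must lie inside the simulated epoch")
  if (n_trials < 2L) stop("at least 2 trials per condition required")
  nc <- gt$n_conditions; nl <- gt$n_layers
  ns <- as.integer(n_sensors); nt <- length(times_ms)
  pats <- lapply(seq_len(nl), function(l)
    pattern_with_similarity(gt$layer_target_sim[[l]], ns,
                            derive_seed(gt$seed, "meg_pattern", l)) * sqrt(ns))
  kern <- vapply(seq_len(nl), function(l)
    exp(-0.5 * ((times_ms - gt$layer_latency_ms[l]) / gt$kernel_sd_ms)^2),
    numeric(nt))                                   # nt x nl, peak value 1
  signal <- array(0, dim = c(nc, ns, nt))
  for (l in seq_len(nl)) {
    contrib <- outer(as.vector(pats[[l]]), kern[, l])   # (nc*ns) x nt
    signal <- signal + array(contrib, dim = c(nc, ns, nt))
  }
  signal <- signal * gt$signal_amplitude
  data <- array(0, dim = c(nc, n_trials, ns, nt))
  noise_seed <- derive_seed(gt$seed, "meg_noise", subject)
  taps <- if (smooth_ms > 0) {
    dt <- stats::median(diff(times_ms))
    max(1L, round(smooth_ms / dt))
  } else 1L
  with_seed(noise_seed, {
    for (m in seq_len(n_trials)) {
      trial <- signal +
        array(stats::rnorm(nc * ns * nt, sd = gt$noise_sd), dim = c(nc, ns, nt))
      if (taps > 1L)
        trial <- array(apply(trial, c(1, 2), sliding_average, taps = taps),
                       dim = c(nt, nc, ns))  # apply returns time first
      data[, m, , ] <- if (taps > 1L) aperm(trial, c(2, 3, 1)) else trial
    }
  })
  trial_tensor(data, times_ms, subject_id = paste0("s", subject))
}

# Centred moving average with shrinking windows at the edges.
sliding_average <- function(x, taps) {
  n <- length(x)
  half <- taps %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (taps - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Simulate one subject's region-wise fMRI patterns
#'
#' Each region's conditions-by-voxels pattern matrix is a weighted sum of
#' layer-specific voxel patterns (weights from `gt$layer_region_weights`)
#' plus i.i.d. Gaussian voxel noise of SD `gt$noise_sd * noise_scale`.  A
#' region weighting only low layers emulates an early visual area, one
#' weighting high layers an inferior-temporal-like area; all-zero weights
#' give a pure-noise control region.
#'
#' @param gt a [ground_truth()] with `layer_region_weights` rows covering
#'   `regions`.
#' @param regions character vector of region names (default: all rows of
#'   the weight matrix).
#' @param n_voxels_per_region voxels per region (> 0); a vector is recycled
#'   across regions.
#' @param subject subject index or label (noise substream).
#' @param noise_scale multiplier on `gt$noise_sd` for voxel noise
#'   (default 1).
#' @return named list of [spatial_patterns()], one per region.
#' @export
simulate_fmri_subject <- function(gt, regions = NULL, n_voxels_per_region = 100L,
                                  subject = 1L, noise_scale = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.null(gt$layer_region_weights))
    stop("ground truth has no layer_region_weights")
  w <- gt$layer_region_weights
  if (is.null(regions)) regions <- rownames(w)
  if (!all(regions %in% rownames(w)))
    stop("region weights are not defined for every requested region")
  nvs <- rep_len(as.integer(n_voxels_per_region), length(regions))
  if (any(nvs <= 0L)) stop("n_voxels_per_region must be positive")
  names(nvs) <- regions
  nc <- gt$n_conditions
  out <- lapply(regions, function(rg) {
    nv <- nvs[[rg]]
    p <- matrix(0, nc, nv)
    for (l in seq_len(gt$n_layers)) {
      if (w[rg, l] == 0) next
      p <- p + w[rg, l] *
        pattern_with_similarity(gt$layer_target_sim[[l]], nv,
                                derive_seed(gt$seed, "fmri_pattern", rg, l)) * sqrt(nv)
    }
    if (gt$noise_sd > 0 && noise_scale > 0)
      p <- p + with_seed(derive_seed(gt$seed, "fmri_noise", rg, subject),
                         matrix(stats::rnorm(nc * nv, sd = gt$noise_sd * noise_scale),
                                nc, nv))
    spatial_patterns(p, voxel_ids = paste0(rg, "_v", seq_len(nv)))
  })
  names(out) <- regions
  out
}

#' Smoothed uniform-noise images
#'
#' Generates images in which every channel and pixel is first drawn
#' independently from a uniform `[0, 1]` distribution and then convolved
#' with a 2-D Gaussian filter of size `filter_size x filter_size` pixels and
#' standard deviation `filter_sd` pixels (with reflective border padding).
#' With the default 10-pixel filter and 80-pixel SD the kernel is nearly
#' flat, producing noise images with small but perceptible spatial
#' gradients, i.e. positive lag-1 spatial autocorrelation.  `filter_size =
#' 0` skips smoothing and returns the raw uniform field.
#'
#' @param n number of images (> 0).
#' @param size image side length in pixels (>= `filter_size`).
#' @param channels number of colour channels.
#' @param filter_size Gaussian filter side length in pixels (default 10).
#' @param filter_sd Gaussian filter SD in pixels (default 80).
#' @param seed integer seed.
#' @return list of `size x size x channels` arrays.
#' @export
generate_noise_images <- function(n, size = 256L, channels = 3L,
                                  filter_size = 10L, filter_sd = 80,
                                  seed = 1L) {
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  if (filter_size > 0L && size < filter_size)
    stop("image size must be at least the filter size")
  kern <- if (filter_size > 0L) {
    off <- seq_len(filter_size) - (filter_size + 1) / 2
    k <- exp(-0.5 * (off / filter_sd)^2)
    k / sum(k)
  } else 1
  lapply(seq_len(n), function(im)
    with_seed(derive_seed(seed, "image", im), {
      arr <- array(stats::runif(size * size * channels), dim = c(size, size, channels))
      if (filter_size > 0L)
        for (ch in seq_len(channels))
          arr[, , ch] <- conv2_separable(arr[, , ch], kern)
      arr
    }))
}

# Separable 2-D convolution with reflective padding.
conv2_separable <- function(img, kern) {
  img <- conv_rows_reflect(img, kern)
  t(conv_rows_reflect(t(img), kern))
}

conv_rows_reflect <- function(img, kern) {
  kl <- length(kern)
  if (kl == 1L) return(img * kern)
  # offsets of the kernel taps relative to the output pixel; for even-sized
  # kernels the window sits half a pixel towards the start
  off <- seq_len(kl) - (kl %/% 2 + 1L)
  nr <- nrow(img)
  idx <- outer(seq_len(nr), off, `+`)
  idx[idx < 1L] <- 1L - idx[idx < 1L] + 1L       # reflect at the top edge
  idx[idx > nr] <- 2L * nr - idx[idx > nr]       # reflect at the bottom edge
  out <- matrix(0, nr, ncol(img))
  for (tap in seq_len(kl))
    out <- out + kern[tap] * img[idx[, tap], , drop = FALSE]
  out
}

#' Lag-1 spatial autocorrelation of an image channel
#'
#' Correlation between horizontally (and vertically) adjacent pixel values,
#' averaged over the two directions; used to verify that smoothing induces
#' spatial gradients.
#'
#' @param img numeric matrix (one channel).
#' @return scalar autocorrelation.
#' @export
lag1_autocorrelation <- function(img) {
  img <- as.matrix(img)
  h <- stats::cor(as.vector(img[, -ncol(img)]), as.vector(img[, -1]))
  v <- stats::cor(as.vector(img[-nrow(img), ]), as.vector(img[-1, ]))
  (h + v) / 2
}

#' Null similarity time courses
#'
#' Simulates per-subject similarity time courses under the global null
#' hypothesis (no brain-model correspondence): zero-mean Gaussian values
#' smoothed along time with the same centred sliding window the MEG
#' generator applies to trials, so the null carries the temporal
#' correlation of real similarity curves.  Used to calibrate the
#' familywise error of cluster-corrected group inference.
#'
#' @param n_subjects number of subjects.
#' @param times_ms time axis in ms.
#' @param smooth_ms sliding-window width in ms (default 20).
#' @param sd noise standard deviation before smoothing.
#' @param seed integer seed.
#' @return a [similarity_timecourse()] (values are similarity-scale,
#'   clipped to `[-1, 1]`).
#' @export
simulate_null_timecourses <- function(n_subjects, times_ms = seq(-50, 300, by = 5),
                                      smooth_ms = 20, sd = 0.2, seed = 1L) {
  nt <- length(times_ms)
  dt <- stats::median(diff(times_ms))
  taps <- if (smooth_ms > 0) max(1L, round(smooth_ms / dt)) else 1L
  vals <- with_seed(seed, matrix(stats::rnorm(n_subjects * nt, sd = sd), n_subjects, nt))
  if (taps > 1L) vals <- t(apply(vals, 1L, sliding_average, taps = taps))
  vals <- pmin(pmax(vals, -1), 1)
  similarity_timecourse(vals, times_ms, label = "null")
}

#' Flat triangulated grid mesh
#'
#' Builds a `rows x cols` planar grid of vertices with `spacing_mm` between
#' neighbours, triangulated with two triangles per grid cell
#' (`2 * (rows-1) * (cols-1)` faces), each vertex mapped to one synthetic
#' voxel.  On this mesh geodesic and Euclidean distances coincide along grid
#' paths, which makes searchlight geometry testable against a Euclidean
#' oracle.
#'
#' @param rows,cols grid dimensions (>= 2).
#' @param spacing_mm grid spacing in mm (> 0).
#' @return a [surface_mesh()].
#' @export
build_toy_mesh <- function(rows, cols, spacing_mm = 3) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L) stop("rows and cols must be at least 2")
  if (spacing_mm <= 0) stop("spacing must be positive")
  vid <- function(r, c0) (r - 1L) * cols + c0
  coords <- cbind(x = rep(seq_len(cols) - 1L, times = rows) * spacing_mm,
                  y = rep(seq_len(rows) - 1L, each = cols) * spacing_mm,
                  z = 0)
  faces <- matrix(0L, 0L, 3L)
  for (r in seq_len(rows - 1L)) for (c0 in seq_len(cols - 1L)) {
    a <- vid(r, c0); b <- vid(r, c0 + 1L); d <- vid(r + 1L, c0); e <- vid(r + 1L, c0 + 1L)
    faces <- rbind(faces, c(a, b, d), c(b, e, d))
  }
  surface_mesh(coords, faces, vertex_to_voxel = paste0("vox", seq_len(rows * cols)))
}
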