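# Correlation-distance RDMs from spatial patterns and model activations.

#' Correlation-distance RDM
#'
#' For every pair of conditions, computes `1 -` Spearman's rank correlation
#' (average ranks for ties) between the two pattern vectors, yielding a
#' dissimilarity bounded between 0 (no dissimilarity) and 2 (complete
#' dissimilarity).  A constant pattern vector makes Spearman's correlation
#' undefined; the affected entries are stored as `NA`, counted in the
#' `n_missing` attribute and reported, never silently zeroed.
#'
#' @param patterns a [spatial_patterns()] object or a plain conditions-by-
#'   features numeric matrix (for example one layer's activation matrix).
#' @param quiet suppress the message reporting missing entries.
#' @return an [rdm()] with metric `"correlation_distance"`.  Attribute
#'   `n_missing` holds the number of undefined entries.
#' @export
correlation_rdm <- function(patterns, quiet = FALSE) {
  x <- if (inherits(patterns, "spatial_patterns")) patterns$data else as.matrix(patterns)
  n <- nrow(x)
  if (n < 3L) stop("at least 3 conditions are required")
  if (ncol(x) < 2L) stop("at least 2 features are required")
  constant <- apply(x, 1L, function(r) max(r) == min(r))
  # Spearman = Pearson on average ranks; rank rows once, then one crossprod.
  rk <- t(apply(x, 1L, rank))              # ties -> average ranks
  rk <- rk - (ncol(x) + 1) / 2             # ranks are centred by construction
  ss <- sqrt(rowSums(rk^2))
  ss[constant] <- NA_real_
  cm <- tcrossprod(rk / ifelse(is.na(ss), 1, ss))
  cm[constant, ] <- NA_real_
  cm[, constant] <- NA_real_
  pg <- pair_grid(n)
  d <- 1 - cm[pg]
  d[!is.na(d)] <- pmin(pmax(d[!is.na(d)], 0), 2)  # clip fp noise at the bounds
  nmiss <- sum(is.na(d))
  if (nmiss && !quiet)
    message(sprintf("correlation_rdm: %d of %d entries undefined (constant pattern vectors)",
                    nmiss, length(d)))
  labs <- if (inherits(patterns, "spatial_patterns")) patterns$condition_labels else rownames(x)
  out <- rdm(d, n, metric = "correlation_distance", condition_labels = labs)
  attr(out, "n_missing") <- nmiss
  out
}

#' Layer-resolved RDMs
#'
#' Applies [correlation_rdm()] to every layer's activation matrix, yielding
#' one RDM per model layer.
#'
#' @param acts a [layer_activations()].
#' @inheritParams correlation_rdm
#' @return a list of [rdm()] objects, one per layer, named by layer index.
#' @export
layer_rdms <- function(acts, quiet = FALSE) {
  stopifnot(inherits(acts, "layer_activations"))
  out <- lapply(acts$layers, correlation_rdm, quiet = quiet)
  names(out) <- paste0("layer", acts$layer_index)
  out
}

# PCA scores with deterministic orientation: features centred across
# conditions (no whitening), components ordered by decreasing variance, the
# sign of each component fixed so its largest-magnitude loading is positive.
pca_scores <- function(x, ncomp) {
  x <- as.matrix(x)
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc, nu = min(ncomp, min(dim(xc))), nv = min(ncomp, min(dim(xc))))
  k <- min(ncomp, length(sv$d))
  sc <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (c0 in seq_len(k)) {
    ld <- sv$v[, c0]
    s <- sign(ld[which.max(abs(ld))])
    if (s < 0) sc[, c0] <- -sc[, c0]
  }
  sc
}

#' PCA-balanced summary RDM over all layers
#'
#' Layers differ by orders of magnitude in unit count, so concatenating raw
#' activations would let the largest layer dominate a whole-model RDM.  To
#' balance the contribution of each layer, every layer's conditions-by-units
#' matrix is first reduced by principal component analysis to
#' `n_conditions - 1` score dimensions per condition; the per-condition score
#' vectors are then concatenated across layers (giving, for 118 conditions
#' and 8 layers, a `117 * 8 = 936`-dimensional summary vector per condition)
#' and a correlation-distance RDM is computed on the concatenated vectors.
#'
#' Each layer's score block is rescaled by a single scalar to unit root
#' mean square before concatenation, so the summary RDM is invariant to
#' rescaling any layer's activations by a positive constant (activation
#' units are arbitrary and differ between layers).  A layer with fewer
#' units than `n_conditions - 1` contributes `min(units, n_conditions - 1)`
#' components and is zero-padded to the fixed per-layer width, keeping the
#' concatenated dimensionality independent of unit counts.
#'
#' @param acts a [layer_activations()].
#' @param return_vectors also return the concatenated summary vectors.
#' @return an [rdm()]; if `return_vectors`, a list with elements `rdm` and
#'   `vectors` (conditions x `(n_conditions - 1) * n_layers`).
#' @export
summary_rdm <- function(acts, return_vectors = FALSE) {
  stopifnot(inherits(acts, "layer_activations"))
  n <- nrow(acts$layers[[1]])
  if (n < 3L) stop("at least 3 conditions are required")
  width <- n - 1L
  blocks <- lapply(acts$layers, function(x) {
    sc <- pca_scores(x, width)
    rms <- sqrt(mean(sc^2))
    if (rms > 0) sc <- sc / rms
    if (ncol(sc) < width)
      sc <- cbind(sc, matrix(0, n, width - ncol(sc)))
    sc
  })
  vectors <- do.call(cbind, blocks)
  out <- correlation_rdm(vectors)
  if (return_vectors) list(rdm = out, vectors = vectors) else out
}
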