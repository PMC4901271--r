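#' Condition-wise spatial activation patterns
#'
#' A conditions-by-voxels matrix of activation estimates (t-value-like,
#' unitless), as produced by a condition-vs-baseline contrast in each voxel
#' of a region of interest, together with voxel identifiers.
#'
#' @param data numeric matrix, conditions in rows, voxels in columns.
#' @param voxel_ids unique voxel identifiers, one per column.
#' @param condition_labels optional condition labels, one per row.
#' @return An object of class `"spatial_patterns"`.
#' @export
spatial_patterns <- function(data, voxel_ids = NULL, condition_labels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("pattern values must be finite")
  if (is.null(voxel_ids)) voxel_ids <- paste0("vox", seq_len(ncol(data)))
  if (anyDuplicated(voxel_ids)) stop("duplicated voxel ids")
  if (length(voxel_ids) != ncol(data)) stop("one voxel id per column required")
  if (is.null(condition_labels)) condition_labels <- paste0("cond", seq_len(nrow(data)))
  dimnames(data) <- list(condition_labels, voxel_ids)
  structure(list(data = data, voxel_ids = as.character(voxel_ids),
                 condition_labels = as.character(condition_labels)),
            class = "spatial_patterns")
}

#' @export
print.spatial_patterns <- function(x, ...) {
  cat(sprintf("spatial_patterns: %d conditions x %d voxels\n",
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Per-condition trial recordings
#'
#' A 4-dimensional array of sensor recordings: conditions x trials x sensors
#' x timepoints, with the time axis in milliseconds.  This is the
#' preprocessed, epoch-extracted representation from which decoding RDMs are
#' built.
#'
#' @param data 4-d numeric array `[condition, trial, sensor, time]`.
#' @param times_ms strictly increasing numeric time axis (ms), one entry per
#'   slice of the fourth dimension.
#' @param subject_id subject label.
#' @return An object of class `"trial_tensor"`.
#' @export
trial_tensor <- function(data, times_ms, subject_id = "s01") {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (dim(data)[2] < 2L) stop("at least 2 trials per condition required")
  if (length(times_ms) != dim(data)[4]) stop("times_ms must match time dimension")
  if (any(diff(times_ms) <= 0)) stop("time axis must be strictly increasing")
  if (!all(is.finite(data))) stop("trial data must be finite")
  structure(list(data = data, times_ms = as.numeric(times_ms),
                 subject_id = as.character(subject_id)),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "trial_tensor [%s]: %d conditions x %d trials x %d sensors x %d timepoints (%g..%g ms)\n",
    x$subject_id, d[1], d[2], d[3], d[4], min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Layered model activations
#'
#' Condition-by-unit activation matrices for an ordered stack of model
#' layers, all sharing the condition axis.
#'
#' @param layers list of numeric matrices (conditions x units), in layer
#'   order.
#' @param layer_index optional strictly increasing integer layer indices;
#'   defaults to `1:length(layers)`.
#' @return An object of class `"layer_activations"`.
#' @export
layer_activations <- function(layers, layer_index = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  layers <- lapply(layers, as.matrix)
  nc <- vapply(layers, nrow, 0L)
  if (length(unique(nc)) != 1L) stop("all layers must share the condition axis")
  if (is.null(layer_index)) layer_index <- seq_along(layers)
  if (any(diff(layer_index) <= 0)) stop("layer indices must be strictly increasing")
  structure(list(layers = layers, layer_index = as.integer(layer_index)),
            class = "layer_activations")
}

#' @export
print.layer_activations <- function(x, ...) {
  cat(sprintf("layer_activations: %d layers, %d conditions; units: %s\n",
              length(x$layers), nrow(x$layers[[1]]),
              paste(vapply(x$layers, ncol, 0L), collapse = ", ")))
  invisible(x)
}

#' Restrict patterns to the most strongly activated voxels
#'
#' Keeps the `n` voxels with the largest grand-average statistic (for example
#' the t-value of an all-conditions-vs-baseline contrast), emulating the
#' functional restriction of an anatomical region of interest to its most
#' responsive voxels.  Ties are broken by voxel id order (earlier columns
#' win), so the selection is deterministic.
#'
#' @param patterns a [spatial_patterns()].
#' @param grand_average numeric per-voxel statistic, one value per voxel.
#' @param n number of voxels to keep, `1 <= n <= ncol`.
#' @return a [spatial_patterns()] with `n` columns, in original column order.
#' @export
restrict_to_top_voxels <- function(patterns, grand_average, n) {
  stopifnot(inherits(patterns, "spatial_patterns"))
  nv <- ncol(patterns$data)
  if (length(grand_average) != nv) stop("one grand-average value per voxel required")
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  if (n > nv) stop("n exceeds the number of voxels")
  keep <- order(-grand_average, seq_len(nv))[seq_len(n)]
  keep <- sort(keep)  # preserve original voxel order among the retained
  spatial_patterns(patterns$data[, keep, drop = FALSE],
                   voxel_ids = patterns$voxel_ids[keep],
                   condition_labels = patterns$condition_labels)
}
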