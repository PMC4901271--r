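# Occlusion-based receptive-field estimation for units of an arbitrary
# feature extractor.  The extractor contract is a pure function: it takes a
# list of images (matrices or height x width x channel arrays) and returns a
# numeric matrix of activations with one row per image and one column per
# unit.

check_extractor_output <- function(act, n_images, context) {
  if (!is.matrix(act) || nrow(act) != n_images)
    stop(sprintf("extractor must return an images x units matrix (%s)", context))
  if (!all(is.finite(act)))
    stop(sprintf("extractor returned non-finite activations (%s)", context))
  act
}

#' Most strongly activating images for a unit
#'
#' Ranks a stimulus set by the activation it evokes in one unit and returns
#' the indices of the `K` strongest, the image set from which occlusion
#' discrepancy maps are built.
#'
#' @param extractor function: list of images -> images x units activation
#'   matrix.
#' @param images list of images.
#' @param unit unit (column) index.
#' @param K number of images to return (default 25).
#' @return integer vector of image indices, strongest first; ties keep the
#'   earlier image.
#' @export
top_k_images <- function(extractor, images, unit, K = 25L) {
  act <- check_extractor_output(extractor(images), length(images), "top_k_images")
  K <- min(as.integer(K), length(images))
  order(-act[, unit], seq_along(images))[seq_len(K)]
}

#' Occlusion discrepancy map
#'
#' Slides (or randomly samples) a small gray-fill square occluder over the
#' image, records the activation drop of one unit for every occluder
#' position, and aggregates the drops into a per-pixel map: each pixel's
#' value is the mean discrepancy (original activation minus occluded
#' activation) over all sampled occluders covering it.  High values mark the
#' image region that drives the unit.
#'
#' @param extractor function: list of images -> images x units matrix.
#' @param image a matrix or height x width x channels array.
#' @param unit unit (column) index.
#' @param occluder_size occluder side length in pixels (default 8; must fit
#'   inside the image).
#' @param stride grid stride in pixels for a dense sweep (default 1).
#'   Ignored when `n_samples` is given.
#' @param n_samples if non-`NULL`, number of uniformly random occluder
#'   positions instead of the dense grid.
#' @param occluder_value fill value of the occluder (default 0.5, mid-gray
#'   for images in `[0, 1]`).
#' @param seed seed for random positions.
#' @return An object of class `"discrepancy_map"`: a height x width matrix
#'   with attributes `unit` and `n_occluders`.  Pixels never covered by an
#'   occluder are `NA`.
#' @export
discrepancy_map <- function(extractor, image, unit, occluder_size = 8L,
                            stride = 1L, n_samples = NULL,
                            occluder_value = 0.5, seed = 1L) {
  dims <- dim(image)
  h <- dims[1]; w <- dims[2]
  os <- as.integer(occluder_size)
  if (os > h || os > w) stop("occluder must fit inside the image")
  base_act <- check_extractor_output(extractor(list(image)), 1L, "unoccluded image")[1, unit]
  if (is.null(n_samples)) {
    tops <- seq(1L, h - os + 1L, by = as.integer(stride))
    lefts <- seq(1L, w - os + 1L, by = as.integer(stride))
    pos <- cbind(top = rep(tops, times = length(lefts)),
                 left = rep(lefts, each = length(tops)))
  } else {
    pos <- with_seed(seed, cbind(top = sample.int(h - os + 1L, n_samples, replace = TRUE),
                                 left = sample.int(w - os + 1L, n_samples, replace = TRUE)))
  }
  occluded <- lapply(seq_len(nrow(pos)), function(p) {
    img <- image
    rr <- pos[p, 1]:(pos[p, 1] + os - 1L)
    cc <- pos[p, 2]:(pos[p, 2] + os - 1L)
    if (length(dims) == 2L) img[rr, cc] <- occluder_value else img[rr, cc, ] <- occluder_value
    img
  })
  act <- tryCatch(check_extractor_output(extractor(occluded), nrow(pos), "occluded batch"),
                  error = function(e)
                    stop(sprintf("extractor failed on occluded images (occluder %dpx): %s",
                                 os, conditionMessage(e))))
  drop_ <- base_act - act[, unit]
  acc <- matrix(0, h, w); cover <- matrix(0L, h, w)
  for (p in seq_len(nrow(pos))) {
    rr <- pos[p, 1]:(pos[p, 1] + os - 1L)
    cc <- pos[p, 2]:(pos[p, 2] + os - 1L)
    acc[rr, cc] <- acc[rr, cc] + drop_[p]
    cover[rr, cc] <- cover[rr, cc] + 1L
  }
  out <- acc / cover            # NaN where never covered
  out[cover == 0L] <- NA_real_
  structure(out, unit = unit, n_occluders = nrow(pos), class = "discrepancy_map")
}

#' @export
print.discrepancy_map <- function(x, ...) {
  cat(sprintf("discrepancy_map: %d x %d, unit %d, %d occluders, max %.4g\n",
              nrow(x), ncol(x), attr(x, "unit"), attr(x, "n_occluders"),
              max(x, na.rm = TRUE)))
  invisible(x)
}

# Translate a matrix so that (pr, pc) lands on the center pixel; vacated
# cells are zero-filled.
recenter_matrix <- function(m, pr, pc) {
  h <- nrow(m); w <- ncol(m)
  ctr <- c((h + 1L) %/% 2L, (w + 1L) %/% 2L)
  out <- matrix(0, h, w)
  dr <- ctr[1] - pr; dc <- ctr[2] - pc
  src_r <- seq_len(h) - dr; src_c <- seq_len(w) - dc
  okr <- src_r >= 1L & src_r <= h; okc <- src_c >= 1L & src_c <= w
  out[okr, okc] <- m[src_r[okr], src_c[okc]]
  out
}

#' Empirical receptive field from discrepancy maps
#'
#' Re-centres every discrepancy map on its peak (ties resolved to the first
#' position in column-major scan order) and averages the re-centred maps:
#' shifts of the same underlying sensitivity profile cancel and the average
#' estimates the unit's receptive field.
#'
#' @param maps list of [discrepancy_map()]s (equal sizes).
#' @return a height x width numeric matrix (the RF estimate).
#' @export
receptive_field <- function(maps) {
  stopifnot(length(maps) >= 1L)
  dims <- dim(maps[[1]])
  acc <- matrix(0, dims[1], dims[2])
  for (m in maps) {
    stopifnot(all(dim(m) == dims))
    mm <- unclass(m)
    mm[is.na(mm)] <- 0
    peak <- arrayInd(which.max(mm), dims)  # which.max: first in scan order
    acc <- acc + recenter_matrix(mm, peak[1], peak[2])
  }
  acc / length(maps)
}

#' Selectivity region of a unit
#'
#' Weights the receptive field by the unit's feature-map value at every
#' location (placing the RF at each location scaled by the response there
#' and summing contributions across pixels, i.e. a cross-correlation of the
#' feature map with the RF) and thresholds the resulting contribution map at
#' a fraction of its maximum.  The default 50%-of-maximum threshold yields
#' the image region primarily driving the unit.
#'
#' @param feature_map numeric matrix of unit responses across locations
#'   (same grid as the image, or any grid the RF should be spread over).
#' @param rf receptive-field matrix from [receptive_field()].
#' @param threshold_frac threshold as a fraction of the contribution map's
#'   maximum (default 0.5).
#' @return list with `region` (logical matrix) and `contribution` (numeric
#'   matrix).
#' @export
selectivity_region <- function(feature_map, rf, threshold_frac = 0.5) {
  fm <- as.matrix(feature_map)
  rf <- as.matrix(rf)
  contrib <- matrix(0, nrow(fm), ncol(fm))
  ctr <- c((nrow(rf) + 1L) %/% 2L, (ncol(rf) + 1L) %/% 2L)
  for (i in seq_len(nrow(rf))) for (j in seq_len(ncol(rf))) {
    if (rf[i, j] == 0) next
    contrib <- contrib + rf[i, j] * shift_matrix(fm, i - ctr[1], j - ctr[2])
  }
  region <- contrib >= threshold_frac * max(contrib)
  list(region = region, contribution = contrib)
}

# Shift with zero fill: result[r, c] = m[r + dr, c + dc] where defined.
shift_matrix <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) + dr; src_c <- seq_len(w) + dc
  okr <- src_r >= 1L & src_r <= h; okc <- src_c >= 1L & src_c <= w
  out[okr, okc] <- m[src_r[okr], src_c[okc]]
  out
}
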