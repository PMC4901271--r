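# Comparison of model RDMs with time-resolved and spatial brain RDMs:
# similarity time courses, peak/onset latencies, hierarchy statistics and
# model contrasts.

#' Similarity time course
#'
#' Per-subject RDM-similarity values (Spearman's R) over time for one model
#' RDM (for example one network layer).
#'
#' @param values numeric subjects x timepoints matrix of similarities in
#'   `[-1, 1]` (`NA` allowed for undefined values).
#' @param times_ms time axis in ms.
#' @param label model/layer label.
#' @return An object of class `"similarity_timecourse"`.
#' @export
similarity_timecourse <- function(values, times_ms, label = "model") {
  values <- rbind(values)  # a single subject may come in as a vector
  if (ncol(values) != length(times_ms))
    stop("one column per timepoint required")
  fin <- values[is.finite(values)]
  if (length(fin) && (min(fin) < -1 - 1e-9 || max(fin) > 1 + 1e-9))
    stop("similarities must lie in [-1, 1]")
  rownames(values) <- paste0("s", seq_len(nrow(values)))
  structure(list(values = values, times_ms = as.numeric(times_ms),
                 label = as.character(label)),
            class = "similarity_timecourse")
}

#' @export
print.similarity_timecourse <- function(x, ...) {
  gm <- colMeans(x$values, na.rm = TRUE)
  pk <- x$times_ms[which.max(gm)]
  cat(sprintf("similarity_timecourse '%s': %d subjects, %g..%g ms; group peak %.3f at %g ms\n",
              x$label, nrow(x$values), min(x$times_ms), max(x$times_ms),
              max(gm, na.rm = TRUE), pk))
  invisible(x)
}

#' @export
plot.similarity_timecourse <- function(x, ...) {
  gm <- colMeans(x$values, na.rm = TRUE)
  graphics::matplot(x$times_ms, t(x$values), type = "l", lty = 1,
                    col = grDevices::grey(0.8), xlab = "time (ms)",
                    ylab = "similarity (Spearman R)", main = x$label, ...)
  graphics::lines(x$times_ms, gm, lwd = 2)
  graphics::abline(v = 0, col = "grey40", lty = 2)
  invisible(x)
}

#' Similarity time course of brain RDMs against a model RDM
#'
#' Correlates (Spearman, lower triangle, missing entries excluded pairwise)
#' the time-resolved RDMs of one subject with a model RDM, yielding that
#' subject's similarity time course.
#'
#' @param brain_rdms an `rdm_series` (see [decoding_rdm_timeseries()]).
#' @param model_rdm an [rdm()].
#' @param label label for the resulting course (default the model's metric).
#' @return a [similarity_timecourse()] with one row.
#' @export
timecourse <- function(brain_rdms, model_rdm, label = "model") {
  stopifnot(inherits(brain_rdms, "rdm_series"))
  vals <- vapply(brain_rdms, function(r)
    suppressWarnings(compare_rdms(r, model_rdm)), numeric(1))
  similarity_timecourse(matrix(vals, nrow = 1), attr(brain_rdms, "times_ms"), label)
}

#' Stack per-subject similarity time courses
#'
#' @param courses list of single-subject [similarity_timecourse()]s sharing
#'   a time axis and label.
#' @return a [similarity_timecourse()] with one row per subject.
#' @export
stack_timecourses <- function(courses) {
  stopifnot(length(courses) >= 1L)
  tm <- courses[[1]]$times_ms
  for (cc in courses) stopifnot(identical(cc$times_ms, tm))
  similarity_timecourse(do.call(rbind, lapply(courses, function(cc) cc$values)),
                        tm, courses[[1]]$label)
}

#' Peak latency of a similarity time course
#'
#' The time of the maximal similarity value within a search window, per
#' subject.  Ties are resolved to the earliest timepoint, and the window
#' defaults to the post-stimulus epoch (pre-stimulus peaks are noise).
#'
#' @param tc a [similarity_timecourse()].
#' @param window_ms length-2 numeric window (inclusive), default
#'   `c(0, max(times))`.
#' @return numeric vector of per-subject latencies (ms); `NA` for a subject
#'   whose course is all-missing inside the window.
#' @export
peak_latency <- function(tc, window_ms = NULL) {
  stopifnot(inherits(tc, "similarity_timecourse"))
  if (is.null(window_ms)) window_ms <- c(0, max(tc$times_ms))
  if (window_ms[1] < min(tc$times_ms) || window_ms[2] > max(tc$times_ms))
    stop("window must lie inside the epoch")
  inw <- tc$times_ms >= window_ms[1] & tc$times_ms <= window_ms[2]
  tmw <- tc$times_ms[inw]
  apply(tc$values[, inw, drop = FALSE], 1L, function(v) {
    if (all(!is.finite(v))) return(NA_real_)
    tmw[which.max(v)]   # which.max takes the first (earliest) maximum
  })
}

#' Onset latency from a significance mask
#'
#' The first timepoint of the earliest significant cluster at or after
#' stimulus onset (t = 0).  The mask typically comes from cluster-corrected
#' group inference on the time course.
#'
#' @param tc a [similarity_timecourse()] (provides the time axis).
#' @param significant_mask logical vector over timepoints.
#' @return onset latency in ms, or `NA` if no significant cluster exists at
#'   or after onset.
#' @export
onset_latency <- function(tc, significant_mask) {
  stopifnot(inherits(tc, "similarity_timecourse"),
            length(significant_mask) == length(tc$times_ms))
  post <- significant_mask & tc$times_ms >= 0
  if (!any(post, na.rm = TRUE)) return(NA_real_)
  tc$times_ms[which(post)[1]]
}

#' Hierarchy statistic: layer number vs peak latency
#'
#' For each subject, Spearman's correlation between model layer index and
#' that subject's per-layer peak latencies.  A positive correlation means
#' deeper layers peak later, i.e. the model's processing hierarchy maps onto
#' the temporal hierarchy of the measured signal.  The group statistic is
#' the mean of the per-subject correlations, tested with a sign-permutation
#' test across subjects.
#'
#' @param peak_latencies subjects x layers matrix of latencies (ms); `NA`
#'   latencies are excluded pairwise, and subjects with fewer than 2 valid
#'   layers are dropped (with a message).
#' @param layer_index layer indices (default `1:n_layers`).
#' @param n_perm permutations for the group test (default 10000).
#' @param seed permutation seed.
#' @param tail test tail, default two-sided (the hierarchy may run either
#'   way).
#' @param exact use exhaustive sign enumeration (see
#'   [sign_permutation_test()]).
#' @return An object of class `"hierarchy_result"`: `per_subject_R`,
#'   `group_R` (mean), `p_value`, `n_subjects`.
#' @export
hierarchy_statistic <- function(peak_latencies, layer_index = NULL,
                                n_perm = 10000L, seed = 1L,
                                tail = c("two.sided", "greater", "less"),
                                exact = FALSE) {
  tail <- match.arg(tail)
  pl <- rbind(peak_latencies)
  if (ncol(pl) < 2L) stop("at least 2 layers are required")
  if (is.null(layer_index)) layer_index <- seq_len(ncol(pl))
  rs <- apply(pl, 1L, function(v) {
    ok <- is.finite(v)
    if (sum(ok) < 2L) return(NA_real_)
    stats::cor(layer_index[ok], v[ok], method = "spearman")
  })
  dropped <- sum(is.na(rs))
  if (dropped)
    message(sprintf("hierarchy_statistic: dropped %d subject(s) with < 2 valid layers", dropped))
  rs <- rs[!is.na(rs)]
  if (!length(rs)) stop("no subject with at least 2 valid layers")
  p <- sign_permutation_test(matrix(rs, ncol = 1), n_perm = n_perm, seed = seed,
                             tail = tail, exact = exact)
  structure(list(per_subject_R = rs, group_R = mean(rs), p_value = unname(p),
                 n_subjects = length(rs), tail = tail),
            class = "hierarchy_result")
}

#' @export
print.hierarchy_result <- function(x, ...) {
  cat(sprintf("hierarchy_result: n = %d, group R = %.3f, P = %.4g (%s sign permutation)\n",
              x$n_subjects, x$group_R, x$p_value, x$tail))
  invisible(x)
}

#' Contrast of two hierarchy statistics
#'
#' Per-subject differences of the layer-vs-latency (or layer-vs-similarity)
#' correlations of two models, with the group difference tested by sign
#' permutation (two-sided by default: a contrast has no privileged
#' direction).
#'
#' @param a,b [hierarchy_statistic()] results over the same subjects.
#' @inheritParams hierarchy_statistic
#' @return list with `per_subject_dR`, `delta_R` (mean difference),
#'   `p_value`.
#' @export
hierarchy_contrast <- function(a, b, n_perm = 10000L, seed = 1L,
                               tail = c("two.sided", "greater", "less"),
                               exact = FALSE) {
  stopifnot(inherits(a, "hierarchy_result"), inherits(b, "hierarchy_result"))
  tail <- match.arg(tail)
  if (a$n_subjects != b$n_subjects)
    stop("contrasts require the same subjects in both results")
  d <- a$per_subject_R - b$per_subject_R
  p <- sign_permutation_test(matrix(d, ncol = 1), n_perm = n_perm, seed = seed,
                             tail = tail, exact = exact)
  list(per_subject_dR = d, delta_R = mean(d), p_value = unname(p), tail = tail)
}

#' Difference of two similarity time courses
#'
#' Subtracts course `b` from course `a` subject-by-subject and
#' timepoint-by-timepoint, the construct behind model-comparison curves
#' ("model A explains the signal better than model B after t ms").
#'
#' @param a,b [similarity_timecourse()]s over the same subjects and times.
#' @return a `"similarity_timecourse"`-like object of class
#'   `"difference_timecourse"` (differences lie in `[-2, 2]`).
#' @export
model_difference_timecourse <- function(a, b) {
  stopifnot(inherits(a, "similarity_timecourse"), inherits(b, "similarity_timecourse"))
  if (!identical(a$times_ms, b$times_ms)) stop("time axes differ")
  if (nrow(a$values) != nrow(b$values)) stop("subject counts differ")
  out <- list(values = a$values - b$values, times_ms = a$times_ms,
              label = paste0(a$label, " - ", b$label))
  class(out) <- c("difference_timecourse", "similarity_timecourse")
  out
}

#' Region-of-interest layer profile
#'
#' Similarity of one ROI RDM to each layer's RDM, plus Spearman's
#' correlation between layer number and similarity.  A non-zero correlation
#' indicates a hierarchical relationship: positive means the region's
#' representation matches deeper layers better.
#'
#' @param roi_rdm an [rdm()].
#' @param layer_rdm_list list of per-layer [rdm()]s.
#' @param layer_index layer indices (default `1:n_layers`).
#' @return list with `similarity` (per layer), `layer_index`, and `R`
#'   (layer-vs-similarity Spearman correlation).
#' @export
roi_layer_profile <- function(roi_rdm, layer_rdm_list, layer_index = NULL) {
  if (is.null(layer_index)) layer_index <- seq_along(layer_rdm_list)
  sim <- vapply(layer_rdm_list, function(l)
    suppressWarnings(compare_rdms(roi_rdm, l)), numeric(1))
  ok <- is.finite(sim)
  r <- if (sum(ok) >= 2L)
    stats::cor(layer_index[ok], sim[ok], method = "spearman") else NA_real_
  list(similarity = unname(sim), layer_index = layer_index, R = r)
}
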