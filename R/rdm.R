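#' Representational dissimilarity matrix (RDM)
#'
#' An RDM stores the pairwise dissimilarities between the activation patterns
#' evoked by `n_conditions` experimental conditions.  Only the lower triangle
#' is stored, as a condensed vector of length `n * (n - 1) / 2`; the diagonal
#' is undefined by construction and never stored.  Pairs are ordered
#' lexicographically by `(i, j)` with `i < j`, i.e. the same order used by
#' [stats::dist()], so condensed vectors from different sources are directly
#' comparable entry-for-entry.
#'
#' Two metrics are supported:
#' \describe{
#'   \item{`correlation_distance`}{`1 - ` Spearman's rank correlation between
#'     the two condition patterns; bounded in `[0, 2]`.}
#'   \item{`decoding_accuracy_percent`}{cross-validated pairwise decoding
#'     accuracy of a linear SVM, in percent; bounded in `[0, 100]`.}
#' }
#' Entries may be `NA` when the underlying dissimilarity is undefined (for
#' example a constant pattern vector makes Spearman's correlation undefined);
#' such entries are flagged, carried through, and excluded pairwise by
#' downstream comparisons.
#'
#' @param values numeric condensed vector of length `n_conditions * (n_conditions - 1) / 2`.
#' @param n_conditions number of conditions `n`.
#' @param metric `"correlation_distance"` or `"decoding_accuracy_percent"`.
#' @param condition_labels optional character vector of length `n_conditions`.
#' @return An object of class `"rdm"`.
#' @seealso [correlation_rdm()], [decoding_rdm()], [compare_rdms()],
#'   [rdm_square()], [rdm_condense()]
#' @export
rdm <- function(values, n_conditions,
                metric = c("correlation_distance", "decoding_accuracy_percent"),
                condition_labels = NULL) {
  metric <- match.arg(metric)
  n <- as.integer(n_conditions)
  if (n < 3L)
    stop("an RDM needs at least 3 conditions")
  m <- n * (n - 1L) / 2L
  values <- as.numeric(values)
  if (length(values) != m)
    stop(sprintf("expected %d condensed values for %d conditions, got %d",
                 m, n, length(values)))
  ok <- values[is.finite(values)]
  lim <- if (metric == "correlation_distance") c(0, 2) else c(0, 100)
  if (length(ok) && (min(ok) < lim[1] - 1e-9 || max(ok) > lim[2] + 1e-9))
    stop(sprintf("values outside [%g, %g] for metric '%s'", lim[1], lim[2], metric))
  if (is.null(condition_labels))
    condition_labels <- paste0("cond", seq_len(n))
  if (length(condition_labels) != n)
    stop("condition_labels length must equal n_conditions")
  structure(list(values = values, n_conditions = n, metric = metric,
                 condition_labels = as.character(condition_labels)),
            class = "rdm")
}

#' Condensed index of a condition pair
#'
#' Maps a pair `(i, j)`, `i < j`, to its position in the condensed RDM vector
#' (lexicographic pair order, as in [stats::dist()]).  Vectorised.
#'
#' @param i,j condition indices (1-based), `i < j` elementwise.
#' @param n number of conditions.
#' @return integer positions in the condensed vector.
#' @export
pair_index <- function(i, j, n) {
  stopifnot(all(i >= 1L), all(j <= n), all(i < j))
  as.integer(n * (i - 1) - i * (i - 1) / 2 + j - i)
}

#' All condition pairs in condensed order
#'
#' @param n number of conditions.
#' @return a two-column integer matrix with rows `(i, j)`, `i < j`, in
#'   condensed (lexicographic) order.
#' @export
pair_grid <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Expand an RDM to square form
#'
#' @param x an [rdm()].
#' @param diag value placed on the (undefined) diagonal, `NA` by default.
#' @return an `n x n` symmetric numeric matrix with `diag` on the diagonal.
#' @export
rdm_square <- function(x, diag = NA_real_) {
  stopifnot(inherits(x, "rdm"))
  n <- x$n_conditions
  m <- matrix(diag, n, n, dimnames = list(x$condition_labels, x$condition_labels))
  pg <- pair_grid(n)
  m[cbind(pg[, 1], pg[, 2])] <- x$values
  m[cbind(pg[, 2], pg[, 1])] <- x$values
  m
}

#' Condense a square dissimilarity matrix into an RDM
#'
#' The lower and upper triangle must agree (the matrix is symmetric up to
#' `tol`); the diagonal is discarded.
#'
#' @param m square numeric matrix.
#' @inheritParams rdm
#' @param tol symmetry tolerance.
#' @return an [rdm()].
#' @export
rdm_condense <- function(m, metric = "correlation_distance", tol = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  asym <- abs(m - t(m))
  if (any(asym > tol, na.rm = TRUE))
    stop("matrix is not symmetric")
  n <- nrow(m)
  pg <- pair_grid(n)
  labs <- rownames(m)
  rdm(m[cbind(pg[, 1], pg[, 2])], n, metric = metric, condition_labels = labs)
}

#' @export
print.rdm <- function(x, ...) {
  nmiss <- sum(!is.finite(x$values))
  cat(sprintf("RDM: %d conditions, %d pairs, metric = %s\n",
              x$n_conditions, length(x$values), x$metric))
  fin <- x$values[is.finite(x$values)]
  if (length(fin))
    cat(sprintf("  range [%.4g, %.4g], mean %.4g", min(fin), max(fin), mean(fin)))
  if (nmiss) cat(sprintf(", %d missing entries", nmiss))
  cat("\n")
  invisible(x)
}

#' @export
plot.rdm <- function(x, main = NULL, ...) {
  m <- rdm_square(x)
  n <- nrow(m)
  if (is.null(main))
    main <- sprintf("RDM (%s)", x$metric)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  xlab = "condition", ylab = "condition", main = main,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Compare two RDMs by rank correlation
#'
#' Computes Spearman's correlation between the condensed (lower-triangle)
#' vectors of two RDMs, the standard second-order similarity used to relate
#' measurement spaces (sensor, voxel, model-unit) to one another.  Missing
#' entries are excluded pairwise.
#'
#' @param a,b [rdm()] objects over the same conditions (same `n_conditions`
#'   and pair ordering).
#' @param min_pairs minimum number of jointly defined pairs required; with
#'   fewer the similarity is undefined and `NA` is returned with a warning.
#' @return Spearman's R in `[-1, 1]`, or `NA` if undefined.
#' @export
compare_rdms <- function(a, b, min_pairs = 3L) {
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  if (a$n_conditions != b$n_conditions)
    stop("RDMs have different numbers of conditions")
  ok <- is.finite(a$values) & is.finite(b$values)
  if (sum(ok) < min_pairs) {
    warning(sprintf("only %d jointly defined pairs; similarity undefined", sum(ok)))
    return(NA_real_)
  }
  stats::cor(a$values[ok], b$values[ok], method = "spearman")
}
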