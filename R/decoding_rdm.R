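# Decoding-accuracy RDMs from trial tensors: pairwise cross-validated linear
# SVM classification of sub-averaged sensor patterns, the time-resolved
# dissimilarity measure for MEG.

# Random assignment of M trials to L = floor(M/k) pseudo-trials of k raw
# trials each; surplus trials are dropped uniformly at random, per
# repetition.  Returns [condition, pseudo-trial, sensor] for one timepoint.
pseudo_average <- function(xt, k) {
  nc <- dim(xt)[1]; m <- dim(xt)[2]; ns <- dim(xt)[3]
  L <- m %/% k
  out <- array(0, dim = c(nc, L, ns))
  for (cc in seq_len(nc)) {
    perm <- sample.int(m)[seq_len(L * k)]
    xs <- matrix(xt[cc, perm, ], nrow = L * k, ncol = ns)
    for (l in seq_len(L))
      out[cc, l, ] <- colMeans(xs[((l - 1L) * k + 1L):(l * k), , drop = FALSE])
  }
  out
}

# Leave-one-pseudo-trial-out pairwise SVM accuracy for one pair, libsvm
# path.  Test labels are read off the linear decision values directly
# (w = SV' coefs, f(x) = x w - rho; positive = first class), which is
# exactly what predict() computes for a linear libsvm model.
pair_accuracy_libsvm <- function(pi_, pj, L) {
  correct <- 0L
  y <- factor(rep(c("a", "b"), each = L - 1L), levels = c("a", "b"))
  for (f in seq_len(L)) {
    tr <- rbind(pi_[-f, , drop = FALSE], pj[-f, , drop = FALSE])
    fit <- e1071::svm(tr, y, kernel = "linear", cost = 1, scale = FALSE,
                      fitted = FALSE)
    w <- crossprod(fit$SV, fit$coefs)
    dv <- rbind(pi_[f, ], pj[f, ]) %*% w - fit$rho
    correct <- correct + (dv[1] > 0) + (dv[2] < 0)
  }
  correct / (2L * L)
}

# L = 2 closed form: with one training vector per class, the soft-margin
# linear SVM's decision boundary is the perpendicular bisector of the two
# training vectors, so predicted labels have a closed form.  For pair (i, j)
# and test vector te_i the decision is
#   (tr_i - tr_j) . te_i - (|tr_i|^2 - |tr_j|^2)/2 > 0  => classified as i.
# Vectorised over condition pairs via Gram matrices; exactly
# label-equivalent to libsvm (asserted in the test suite).
pairs_accuracy_closed_form <- function(pseudo, pairs) {
  n <- dim(pseudo)[1]
  acc <- numeric(nrow(pairs))
  for (fold in 1:2) {
    tr <- pseudo[, fold, , drop = TRUE]
    te <- pseudo[, 3L - fold, , drop = TRUE]
    if (is.null(dim(tr))) { tr <- matrix(tr, nrow = n); te <- matrix(te, nrow = n) }
    gtt <- tcrossprod(te, tr)
    dtr <- rowSums(tr^2)
    gdiag <- diag(gtt)
    i <- pairs[, 1]; j <- pairs[, 2]
    half <- (dtr[i] - dtr[j]) / 2
    ci <- (gdiag[i] - gtt[cbind(i, j)]) - half     # test vector of class i
    cj <- (gdiag[j] - gtt[cbind(j, i)]) + half     # test vector of class j
    acc <- acc + (ci > 0) + (cj > 0)
  }
  acc / 4
}

#' Pairwise decoding RDM at one timepoint
#'
#' For every pair of conditions, the `M` raw trial pattern vectors at time
#' `t` are sub-averaged in randomly assigned groups of `k` into `L = M/k`
#' pseudo-trials (raising signal-to-noise), a linear maximum-margin
#' classifier (libsvm, cost 1, no rescaling) is cross-validated
#' leave-one-pseudo-trial-out over the `L` folds, and the whole procedure is
#' repeated `n_reps` times with fresh random assignments.  The RDM entry is
#' the mean test accuracy in percent: 50 is chance, higher values mean the
#' two conditions evoke more discriminable sensor patterns.
#'
#' If `M` is not divisible by `k` the surplus trials are dropped uniformly at
#' random per repetition, preserving equal pseudo-trial weighting.  With
#' `L = 2` (one training vector per class) the SVM decision boundary is the
#' perpendicular bisector of the two training vectors, and an exact
#' vectorised closed form is used; `engine` can force either path.
#'
#' @param trials a [trial_tensor()].
#' @param t timepoint, in ms (matched against the tensor's time axis).
#' @param k sub-averaging group size (default 5).
#' @param n_reps number of random-assignment repetitions (default 100).
#' @param seed integer seed for the assignment randomness.
#' @param engine `"auto"` (closed form iff `L == 2`), `"libsvm"`, or
#'   `"closed_form"` (valid only when `L == 2`).
#' @return an [rdm()] with metric `"decoding_accuracy_percent"`.
#' @export
decoding_rdm <- function(trials, t, k = 5L, n_reps = 100L, seed = 1L,
                         engine = c("auto", "libsvm", "closed_form")) {
  stopifnot(inherits(trials, "trial_tensor"))
  engine <- match.arg(engine)
  ti <- which(trials$times_ms == t)
  if (length(ti) != 1L) stop(sprintf("timepoint %g ms not on the tensor's time axis", t))
  report_surplus(dim(trials$data)[2], k)
  xt <- trials$data[, , , ti, drop = FALSE]
  dim(xt) <- dim(trials$data)[1:3]
  decoding_rdm_at(xt, k = k, n_reps = n_reps, seed = seed, engine = engine)
}

report_surplus <- function(m, k) {
  if (m %% k)
    message(sprintf(
      "decoding: %d of %d trials per condition dropped at random per repetition (k = %d)",
      m %% k, m, k))
}

# Condensed pairwise accuracies (fraction correct) on a
# [condition, trial, sensor] slice; works for 2 or more conditions.
decoding_accuracy_condensed <- function(xt, k, n_reps, seed, engine = "auto") {
  nc <- dim(xt)[1]; m <- dim(xt)[2]
  k <- as.integer(k)
  L <- m %/% k
  if (m < 2L * k || L < 2L)
    stop(sprintf("need at least 2k = %d trials per condition for 2 pseudo-trials, got %d",
                 2L * k, m))
  if (engine == "closed_form" && L != 2L)
    stop("the closed-form engine requires exactly L = 2 pseudo-trials")
  use_cf <- (engine == "closed_form") || (engine == "auto" && L == 2L)
  pairs <- pair_grid(nc)
  acc <- numeric(nrow(pairs))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      pseudo <- pseudo_average(xt, k)
      if (use_cf) {
        acc <- acc + pairs_accuracy_closed_form(pseudo, pairs)
      } else {
        for (p in seq_len(nrow(pairs))) {
          i <- pairs[p, 1]; j <- pairs[p, 2]
          pi_ <- matrix(pseudo[i, , ], nrow = L)
          pj <- matrix(pseudo[j, , ], nrow = L)
          acc[p] <- acc[p] + pair_accuracy_libsvm(pi_, pj, L)
        }
      }
    }
  })
  acc / n_reps
}

# Core worker wrapping the condensed accuracies into an RDM (needs >= 3
# conditions).
decoding_rdm_at <- function(xt, k, n_reps, seed, engine = "auto") {
  acc <- decoding_accuracy_condensed(xt, k, n_reps, seed, engine)
  rdm(100 * acc, dim(xt)[1], metric = "decoding_accuracy_percent")
}

#' Pairwise decoding accuracy for two conditions
#'
#' The decoding-RDM entry for a single condition pair, exposed directly:
#' sub-averaging into pseudo-trials, leave-one-pseudo-trial-out linear SVM
#' cross-validation, repeated `n_reps` times.  Useful for chance-level
#' calibration and for inspecting single pairs.
#'
#' @param x_a,x_b trials x sensors matrices for the two conditions (equal
#'   trial counts).
#' @inheritParams decoding_rdm
#' @return mean decoding accuracy in percent.
#' @export
pair_decoding_accuracy <- function(x_a, x_b, k = 5L, n_reps = 100L, seed = 1L,
                                   engine = c("auto", "libsvm", "closed_form")) {
  engine <- match.arg(engine)
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  stopifnot(nrow(x_a) == nrow(x_b), ncol(x_a) == ncol(x_b))
  xt <- array(0, dim = c(2L, nrow(x_a), ncol(x_a)))
  xt[1L, , ] <- x_a
  xt[2L, , ] <- x_b
  100 * decoding_accuracy_condensed(xt, k, n_reps, seed, engine)
}

#' Time-resolved decoding RDMs
#'
#' Applies [decoding_rdm()] at every timepoint of a trial tensor, yielding
#' one RDM per millisecond (or whatever the tensor's time step is).  Each
#' timepoint uses an independent, deterministically derived assignment
#' substream.
#'
#' @inheritParams decoding_rdm
#' @return an object of class `"rdm_series"`: a list of [rdm()] objects with
#'   attribute `times_ms` preserved from the input.
#' @export
decoding_rdm_timeseries <- function(trials, k = 5L, n_reps = 100L, seed = 1L,
                                    engine = c("auto", "libsvm", "closed_form")) {
  stopifnot(inherits(trials, "trial_tensor"))
  engine <- match.arg(engine)
  report_surplus(dim(trials$data)[2], k)
  nt <- length(trials$times_ms)
  out <- vector("list", nt)
  for (ti in seq_len(nt)) {
    xt <- trials$data[, , , ti, drop = FALSE]
    dim(xt) <- dim(trials$data)[1:3]
    out[[ti]] <- decoding_rdm_at(xt, k = k, n_reps = n_reps,
                                 seed = derive_seed(seed, "time", ti),
                                 engine = engine)
  }
  structure(out, times_ms = trials$times_ms, class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  tm <- attr(x, "times_ms")
  cat(sprintf("rdm_series: %d RDMs, %g..%g ms, %d conditions, metric = %s\n",
              length(x), min(tm), max(tm), x[[1]]$n_conditions, x[[1]]$metric))
  invisible(x)
}
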