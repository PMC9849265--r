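#' Detection evaluation metrics without true negatives
#'
#' Object detectors only propose boxes on classes of interest, so true
#' negatives are not defined and accuracy is computed from TP/FP/FN alone:
#'
#' * `accuracy  = tp / (tp + fp + fn)`
#' * `precision = tp / (tp + fp)`
#' * `recall    = tp / (tp + fn)`
#'
#' All three return the raw (unrounded) value; reports round proportions to
#' 2 decimals with [round_half_up()]. Degenerate zero denominators raise an
#' error rather than silently returning 0 — an undefined metric is a signal,
#' not a value.
#'
#' @param tp,fp,fn non-negative counts of true positives, false positives,
#'   and false negatives.
#' @return the metric value in `[0, 1]`.
#' @export
#' @examples
#' accuracy(65, 10, 0)    # 0.8667
#' precision(24, 1)       # 0.96
#' recall(16, 12)         # 0.5714
accuracy <- function(tp, fp, fn) {
  check_counts(tp, fp, fn)
  if (tp + fp + fn == 0) stop("accuracy undefined: tp + fp + fn = 0",
                              call. = FALSE)
  tp / (tp + fp + fn)
}

#' @rdname accuracy
#' @export
precision <- function(tp, fp) {
  check_counts(tp, fp)
  if (tp + fp == 0) stop("precision undefined: tp + fp = 0", call. = FALSE)
  tp / (tp + fp)
}

#' @rdname accuracy
#' @export
recall <- function(tp, fn) {
  check_counts(tp, fn)
  if (tp + fn == 0) stop("recall undefined: tp + fn = 0", call. = FALSE)
  tp / (tp + fn)
}

check_counts <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  invisible(v)
}

#' Percentage difference between two raw counts
#'
#' The relative discrepancy `100 * (n_test - n_ref) / denominator` between a
#' source's raw count and the reference observer's, reported to 1 decimal.
#' Two denominator conventions are in field use and both are supported: the
#' reference count (the default) and the test source's own count; see the
#' methods vignette for why both exist.
#'
#' @param n_test count from the source being evaluated.
#' @param n_ref count from the reference observer.
#' @param denominator which count to divide by.
#' @return signed percentage (raw, unrounded).
#' @export
#' @examples
#' pct_diff(114, 95)   # +20.0
#' pct_diff(103, 63)   # +63.5
pct_diff <- function(n_test, n_ref, denominator = c("reference", "test")) {
  denominator <- match.arg(denominator)
  check_counts(n_test, n_ref)
  den <- if (denominator == "reference") n_ref else n_test
  if (den == 0) stop("pct_diff undefined: zero denominator", call. = FALSE)
  100 * (n_test - n_ref) / den
}

#' Proportion of reference animals missed
#'
#' `fn / (tp + fn)`, the complement of recall: the fraction of the
#' reference observer's animals that the evaluated source failed to detect
#' at all.
#'
#' @param fn,tp counts.
#' @return proportion in `[0, 1]` (raw, unrounded).
#' @export
#' @examples
#' missing_proportion(12, 16)  # 0.4286
missing_proportion <- function(fn, tp) {
  check_counts(fn, tp)
  if (tp + fn == 0) stop("missing_proportion undefined: tp + fn = 0",
                         call. = FALSE)
  fn / (tp + fn)
}

#' Proportion of misclassifications into a class
#'
#' For a confusion cell "reference class y predicted as class x", the
#' proportion is taken relative to the correctly detected members of the
#' *predicted* class: `n / (n + tp_x)`. This is the convention that
#' reproduces the published per-mosaic misclassification tables this
#' package's reports mirror; it answers "of everything called an x that
#' involved a y-vs-x decision, how often was it really a y?".
#'
#' @param n_y_as_x count of reference-class-y boxes predicted as class x.
#' @param tp_x true positives of the predicted class x.
#' @return proportion in `[0, 1]` (raw, unrounded).
#' @export
#' @examples
#' misclass_proportion(9, 51)  # 0.15
misclass_proportion <- function(n_y_as_x, tp_x) {
  check_counts(n_y_as_x, tp_x)
  if (n_y_as_x + tp_x == 0) {
    stop("misclass_proportion undefined: zero denominator", call. = FALSE)
  }
  n_y_as_x / (n_y_as_x + tp_x)
}

#' Pearson correlation between two per-tile count vectors
#'
#' Used to compare a source's spatial count pattern with the reference
#' observer's, tile by tile. Requires at least 3 tiles and non-zero
#' variance on both sides.
#'
#' @param counts_a,counts_b equal-length numeric vectors of per-tile counts.
#' @return sample Pearson correlation coefficient.
#' @export
per_tile_correlation <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    stop("per-tile count vectors differ in length", call. = FALSE)
  }
  if (length(counts_a) < 3) {
    stop("need at least 3 tiles for a correlation", call. = FALSE)
  }
  if (sd(counts_a) == 0 || sd(counts_b) == 0) {
    stop("per_tile_correlation undefined: zero variance", call. = FALSE)
  }
  cor(counts_a, counts_b, method = "pearson")
}
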