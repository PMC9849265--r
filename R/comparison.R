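# Metric wrappers that return NA where the metric is undefined; comparison
# tables must not abort because one cell has an empty denominator.
safe_metric <- function(f, ...) {
  tryCatch(f(...), error = function(e) NA_real_)
}

#' Evaluate one annotation source against the reference observer
#'
#' Runs the full evaluation stack — [match_sets()] (class-agnostic),
#' [derive_counts()], and the metric set — for one source (a naive
#' observer or a detector) against the designated reference observer, per
#' class and pooled. The reference is treated as ground truth: it is
#' assumed to miss nothing and misclassify nothing.
#'
#' With `scope = "test-tiles"` only annotations owned by the supplied tile
#' keys (typically the held-out testing tiles of [split_tiles()]) enter the
#' evaluation; with `"whole-mosaic"` everything does. When a `grid` is
#' given, per-tile count vectors are retained for [correlation_report()].
#'
#' @param reference reference [annotation_set()].
#' @param source [annotation_set()] to evaluate, same mosaic.
#' @param grid optional [plan_grid()]; required for `scope = "test-tiles"`
#'   and for per-tile counts.
#' @param scope evaluate on the whole mosaic or only on test tiles.
#' @param test_keys character vector of tile keys (from [split_tiles()])
#'   defining the test scope.
#' @param iou_threshold passed to [match_sets()].
#' @param pct_diff_denominator passed to [pct_diff()].
#' @param processing_time_min optional minutes the source spent annotating,
#'   carried into reports for the manual-vs-automated time comparison.
#' @return an object of class `source_summary`: list with `source_id`,
#'   `mosaic_id`, `scope`, `counts` (data.frame: one row per class plus
#'   `pooled`; columns `raw_count`, `ref_count`, `tp`, `fp`, `fn`,
#'   `accuracy`, `precision`, `recall`, `pct_diff`), `confusion`,
#'   `per_tile` (data.frame `key`, `class`, `ref_n`, `src_n`, or `NULL`),
#'   and `processing_time_min`.
#' @export
evaluate_source <- function(reference, source, grid = NULL,
                            scope = c("whole-mosaic", "test-tiles"),
                            test_keys = NULL, iou_threshold = 0.3,
                            pct_diff_denominator = "reference",
                            processing_time_min = NA_real_) {
  scope <- match.arg(scope)
  if (!identical(mosaic_id(reference), mosaic_id(source))) {
    stop(sprintf("sets are on different mosaics ('%s' vs '%s')",
                 mosaic_id(reference), mosaic_id(source)), call. = FALSE)
  }
  if (scope == "test-tiles") {
    if (is.null(grid) || is.null(test_keys)) {
      stop("scope 'test-tiles' needs a grid and test tile keys", call. = FALSE)
    }
    reference <- subset_to_tiles(reference, grid, test_keys)
    source <- subset_to_tiles(source, grid, test_keys)
  }
  m <- match_sets(reference, source, iou_threshold = iou_threshold,
                  class_agnostic = TRUE)
  dc <- derive_counts(m, reference, source)
  labs <- caribou_labels()
  rows <- c(labs, "pooled")
  R <- as.data.frame(reference); S <- as.data.frame(source)
  raw <- c(vapply(labs, function(l) sum(S$label == l), 0L), nrow(S))
  refn <- c(vapply(labs, function(l) sum(R$label == l), 0L), nrow(R))
  counts <- data.frame(row.names = rows,
                       raw_count = raw, ref_count = refn,
                       tp = dc$counts[rows, "tp"],
                       fp = dc$counts[rows, "fp"],
                       fn = dc$counts[rows, "fn"])
  counts$accuracy <- mapply(function(tp, fp, fn) safe_metric(accuracy, tp, fp, fn),
                            counts$tp, counts$fp, counts$fn)
  counts$precision <- mapply(function(tp, fp) safe_metric(precision, tp, fp),
                             counts$tp, counts$fp)
  counts$recall <- mapply(function(tp, fn) safe_metric(recall, tp, fn),
                          counts$tp, counts$fn)
  counts$pct_diff <- mapply(function(a, b) {
    safe_metric(pct_diff, a, b, denominator = pct_diff_denominator)
  }, counts$raw_count, counts$ref_count)
  per_tile <- if (!is.null(grid)) {
    keys <- if (scope == "test-tiles") sort(test_keys) else grid$tiles$key
    per_tile_counts(reference, source, grid, keys)
  }
  structure(list(source_id = source_id(source), mosaic_id = mosaic_id(source),
                 scope = scope, counts = counts, confusion = dc$confusion,
                 match = m, per_tile = per_tile,
                 processing_time_min = processing_time_min),
            class = "source_summary")
}

#' @export
print.source_summary <- function(x, ...) {
  cat(sprintf("<source_summary> source '%s' vs reference on mosaic '%s' (%s)\n",
              x$source_id, x$mosaic_id, x$scope))
  print(round(x$counts, 3))
  invisible(x)
}

# Keep only annotations owned by the given tile keys (mosaic coordinates).
subset_to_tiles <- function(set, grid, keys) {
  df <- as.data.frame(set)
  if (nrow(df) == 0) return(set)
  own <- owner_index(grid, df$x0, df$y0)
  k <- sprintf("i%02d_j%02d", own$i, own$j)
  annotation_set(df[k %in% keys, , drop = FALSE], mosaic_id = mosaic_id(set),
                 source_id = source_id(set), labels = attr(set, "labels"))
}

# Long data.frame of per-tile per-class counts for two sets.
per_tile_counts <- function(reference, source, grid, keys) {
  labs <- caribou_labels()
  count_by <- function(set) {
    df <- as.data.frame(set)
    out <- matrix(0L, nrow = length(keys), ncol = length(labs),
                  dimnames = list(keys, labs))
    if (nrow(df) > 0) {
      own <- owner_index(grid, df$x0, df$y0)
      k <- sprintf("i%02d_j%02d", own$i, own$j)
      ok <- k %in% keys
      tb <- table(factor(k[ok], levels = keys),
                  factor(df$label[ok], levels = labs))
      out[] <- as.integer(tb)
    }
    out
  }
  rn <- count_by(reference); sn <- count_by(source)
  data.frame(key = rep(keys, times = length(labs)),
             class = rep(labs, each = length(keys)),
             ref_n = as.integer(rn), src_n = as.integer(sn),
             stringsAsFactors = FALSE)
}

#' Pool several observers into mean +/- SD summaries
#'
#' Aggregates the [evaluate_source()] summaries of a team of observers into
#' the per-class mean and sample standard deviation of every count column,
#' the way a multi-observer survey reports "all observers: avg +/- SD".
#' Aggregate metrics are reported both ways the field computes them:
#' recomputed from the mean counts (`accuracy`, `precision`, `recall`,
#' `pct_diff` — the convention the summary tables use) and as the mean of
#' the per-observer metrics (`accuracy_mean_of`, ...), since the two differ
#' whenever observers are heterogeneous.
#'
#' @param summaries list of `source_summary` objects on the same mosaic and
#'   scope.
#' @param pct_diff_denominator passed to [pct_diff()] for the aggregate.
#' @return an object of class `pooled_summary`: data.frame with one row per
#'   class plus `pooled`, mean/SD columns for `raw_count`, `tp`, `fp`, `fn`,
#'   and both aggregate metric variants.
#' @export
pool_observers <- function(summaries, pct_diff_denominator = "reference") {
  if (length(summaries) < 1) stop("need at least one summary", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, TRUE, "source_summary")))
  rows <- rownames(summaries[[1]]$counts)
  fields <- c("raw_count", "tp", "fp", "fn")
  out <- data.frame(row.names = rows)
  arr <- lapply(fields, function(f) {
    sapply(summaries, function(s) s$counts[rows, f])
  })
  names(arr) <- fields
  for (f in fields) {
    m <- matrix(arr[[f]], nrow = length(rows))
    out[[paste0(f, "_mean")]] <- rowMeans(m)
    out[[paste0(f, "_sd")]] <- if (ncol(m) > 1) apply(m, 1, sd) else 0
  }
  refn <- summaries[[1]]$counts[rows, "ref_count"]
  out$ref_count <- refn
  out$accuracy <- mapply(function(tp, fp, fn) safe_metric(accuracy, tp, fp, fn),
                         out$tp_mean, out$fp_mean, out$fn_mean)
  out$precision <- mapply(function(tp, fp) safe_metric(precision, tp, fp),
                          out$tp_mean, out$fp_mean)
  out$recall <- mapply(function(tp, fn) safe_metric(recall, tp, fn),
                       out$tp_mean, out$fn_mean)
  out$pct_diff <- mapply(function(a, b) {
    safe_metric(pct_diff, a, b, denominator = pct_diff_denominator)
  }, out$raw_count_mean, refn)
  mean_of <- function(f) {
    rowMeans(sapply(summaries, function(s) s$counts[rows, f]), na.rm = TRUE)
  }
  out$accuracy_mean_of <- mean_of("accuracy")
  out$precision_mean_of <- mean_of("precision")
  out$recall_mean_of <- mean_of("recall")
  out$pct_diff_mean_of <- mean_of("pct_diff")
  class(out) <- c("pooled_summary", "data.frame")
  out
}

#' Per-tile Pearson correlation report
#'
#' Computes the Pearson correlation between reference and source per-tile
#' counts, pooled over classes and (optionally) per class, from the
#' `per_tile` table of an [evaluate_source()] summary. Cells with fewer
#' than 3 tiles or zero variance are flagged undefined (`r = NA`,
#' `defined = FALSE`) rather than propagating `NaN`. The input table is
#' attached as attribute `"scatter"` so callers can plot counts against the
#' 1:1 line.
#'
#' @param per_tile data.frame with columns `key`, `class`, `ref_n`, `src_n`
#'   (from `evaluate_source(...)$per_tile`), or a `source_summary`.
#' @param by_class also report each class separately?
#' @return data.frame with columns `class`, `r`, `n_tiles`, `defined`.
#' @export
correlation_report <- function(per_tile, by_class = TRUE) {
  if (inherits(per_tile, "source_summary")) per_tile <- per_tile$per_tile
  if (is.null(per_tile)) stop("no per-tile counts available", call. = FALSE)
  one <- function(cls, a, b) {
    r <- tryCatch(per_tile_correlation(a, b), error = function(e) NA_real_)
    data.frame(class = cls, r = r, n_tiles = length(a), defined = !is.na(r),
               stringsAsFactors = FALSE)
  }
  pooled_a <- tapply(per_tile$ref_n, per_tile$key, sum)
  pooled_b <- tapply(per_tile$src_n, per_tile$key, sum)
  out <- one("pooled", as.numeric(pooled_a), as.numeric(pooled_b))
  if (by_class) {
    for (cls in unique(per_tile$class)) {
      sub <- per_tile[per_tile$class == cls, ]
      out <- rbind(out, one(cls, sub$ref_n, sub$src_n))
    }
  }
  rownames(out) <- NULL
  attr(out, "scatter") <- per_tile
  out
}
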