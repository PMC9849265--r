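#' Match a predicted annotation set against a reference set
#'
#' Establishes one-to-one geometric correspondences by greedy selection:
#' all reference x predicted pairs with IoU at or above `iou_threshold` are
#' visited in order of decreasing IoU (ties broken by smaller box-center
#' distance, then lower reference index, then lower predicted index), and a
#' pair is accepted iff both members are still unmatched. By default
#' matching is class-agnostic — label agreement is scored later by
#' [derive_counts()], so a calf predicted where the reference saw an adult
#' still matches geometrically and is then counted as a misclassification.
#' With `class_agnostic = FALSE` only same-label pairs are candidates.
#'
#' @param reference,predicted [annotation_set()]s on the same mosaic frame.
#' @param iou_threshold minimum IoU for a pair, in `(0, 1]`. The default
#'   0.3 tolerates loosely drawn human boxes while still rejecting casual
#'   overlap between adjacent animals.
#' @param class_agnostic match across labels (default) or within labels.
#' @return an object of class `match_result`: list with `pairs` (data.frame
#'   `ref`, `pred`, `iou`), `unmatched_reference`, `unmatched_predicted`
#'   (integer index vectors), and `iou_threshold`.
#' @export
match_sets <- function(reference, predicted, iou_threshold = 0.3,
                       class_agnostic = TRUE) {
  stopifnot(inherits(reference, "annotation_set"),
            inherits(predicted, "annotation_set"))
  if (!(iou_threshold > 0 && iou_threshold <= 1)) {
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (!identical(mosaic_id(reference), mosaic_id(predicted))) {
    stop(sprintf("sets are on different mosaics ('%s' vs '%s')",
                 mosaic_id(reference), mosaic_id(predicted)), call. = FALSE)
  }
  R <- as.data.frame(reference); P <- as.data.frame(predicted)
  nr <- nrow(R); np <- nrow(P)
  pairs <- data.frame(ref = integer(), pred = integer(), iou = numeric())
  if (nr > 0 && np > 0) {
    iou <- iou_matrix(R, P)
    if (!class_agnostic) {
      same <- outer(R$label, P$label, "==")
      iou[!same] <- 0
    }
    cand <- which(iou >= iou_threshold, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      rcx <- (R$x0 + R$x1) / 2; rcy <- (R$y0 + R$y1) / 2
      pcx <- (P$x0 + P$x1) / 2; pcy <- (P$y0 + P$y1) / 2
      cd <- sqrt((rcx[cand[, 1]] - pcx[cand[, 2]])^2 +
                 (rcy[cand[, 1]] - pcy[cand[, 2]])^2)
      ord <- order(-iou[cand], cd, cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      ref_free <- rep(TRUE, nr); pred_free <- rep(TRUE, np)
      acc <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        r <- cand[k, 1]; p <- cand[k, 2]
        if (ref_free[r] && pred_free[p]) {
          acc[k] <- TRUE
          ref_free[r] <- FALSE; pred_free[p] <- FALSE
        }
      }
      cand <- cand[acc, , drop = FALSE]
      pairs <- data.frame(ref = as.integer(cand[, 1]),
                          pred = as.integer(cand[, 2]),
                          iou = iou[cand])
    }
  }
  structure(list(pairs = pairs,
                 unmatched_reference = setdiff(seq_len(nr), pairs$ref),
                 unmatched_predicted = setdiff(seq_len(np), pairs$pred),
                 iou_threshold = iou_threshold,
                 class_agnostic = class_agnostic),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pair(s), %d unmatched reference, %d unmatched predicted (IoU >= %.2f)\n",
              nrow(x$pairs), length(x$unmatched_reference),
              length(x$unmatched_predicted), x$iou_threshold))
  invisible(x)
}

#' Derive TP/FP/FN tallies and the cross-class confusion table
#'
#' Applies the survey's counting rules to a class-agnostic [match_sets()]
#' result. Pooled ("species-level") counts ignore labels: every matched pair
#' is a true positive, every unmatched prediction a false positive, every
#' unmatched reference a false negative. Per class `c`: `tp_c` counts pairs
#' where both labels are `c`; a matched pair with mismatched labels (a
#' misclassification) contributes a false positive to the *predicted* class
#' and a false negative to the *reference* class; unmatched predictions and
#' references add to `fp_c` and `fn_c` of their own class. The confusion
#' table records reference class vs predicted class for all pairs, a
#' `missed` column for unmatched references, and an `object` row for
#' unmatched predictions (spurious detections of non-animals, or of animals
#' the reference did not record).
#'
#' @param match a [match_sets()] result produced with `class_agnostic = TRUE`
#'   from these same sets.
#' @param reference,predicted the matched [annotation_set()]s.
#' @return list with `counts` (data.frame, rows `adult`, `calf`, `ghost`,
#'   `pooled`; columns `tp`, `fp`, `fn`) and `confusion` (integer matrix,
#'   rows `adult`, `calf`, `ghost`, `object`; columns `adult`, `calf`,
#'   `ghost`, `missed`).
#' @export
derive_counts <- function(match, reference, predicted) {
  stopifnot(inherits(match, "match_result"))
  labs <- caribou_labels()
  R <- as.data.frame(reference); P <- as.data.frame(predicted)
  pr <- match$pairs
  ref_lab <- R$label[pr$ref]
  pred_lab <- P$label[pr$pred]
  conf <- matrix(0L, nrow = 4, ncol = 4,
                 dimnames = list(c(labs, "object"), c(labs, "missed")))
  for (k in seq_len(nrow(pr))) {
    conf[ref_lab[k], pred_lab[k]] <- conf[ref_lab[k], pred_lab[k]] + 1L
  }
  for (r in match$unmatched_reference) {
    conf[R$label[r], "missed"] <- conf[R$label[r], "missed"] + 1L
  }
  for (p in match$unmatched_predicted) {
    conf["object", P$label[p]] <- conf["object", P$label[p]] + 1L
  }
  counts <- data.frame(row.names = c(labs, "pooled"),
                       tp = rep(0L, 4), fp = rep(0L, 4), fn = rep(0L, 4))
  for (c in labs) {
    mism_pred <- sum(pred_lab == c & ref_lab != c)
    mism_ref <- sum(ref_lab == c & pred_lab != c)
    counts[c, "tp"] <- sum(ref_lab == c & pred_lab == c)
    counts[c, "fp"] <- mism_pred + sum(P$label[match$unmatched_predicted] == c)
    counts[c, "fn"] <- mism_ref + sum(R$label[match$unmatched_reference] == c)
  }
  counts["pooled", ] <- c(nrow(pr), length(match$unmatched_predicted),
                          length(match$unmatched_reference))
  list(counts = counts, confusion = conf)
}
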