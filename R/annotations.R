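#' Annotation label vocabularies
#'
#' The evaluation vocabulary has exactly three classes: `adult`, `calf` and
#' `ghost` (caribou). Ghosts are animals that moved between overlapping
#' photos and were rendered blurred/semi-transparent by the mosaicking
#' software; they are counted as their own class. Distractor objects that
#' observers must not annotate (rocks, birds, tree trunks) have a separate
#' vocabulary used only by the synthetic scene generator.
#'
#' @return character vector of label names.
#' @export
caribou_labels <- function() c("adult", "calf", "ghost")

#' @rdname caribou_labels
#' @export
distractor_labels <- function() c("rock", "bird", "trunk")

#' Normalize an annotation label
#'
#' Accepts the field phrases ("Adult caribou", "ghost caribou", ...) and
#' returns the bare lowercase class name. Unknown labels are returned
#' normalized but unvalidated; validation happens where a vocabulary is
#' known.
#'
#' @param x character vector of raw labels.
#' @return character vector of normalized labels.
#' @export
normalize_label <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("caribou", "", out, fixed = TRUE)
  trimws(out)
}

# Validate a data.frame of boxes (label,x0,y0,x1,y1[,confidence]) against a
# vocabulary and optional mosaic bounds; `where` labels error messages.
validate_boxes <- function(df, labels = caribou_labels(), meta = NULL,
                           where = "annotation set") {
  needed <- c("label", "x0", "y0", "x1", "y1")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing columns: %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(df))
  bad_lab <- !(df$label %in% labels)
  if (any(bad_lab)) {
    stop(sprintf("%s: unknown label(s): %s (vocabulary: %s)", where,
                 paste(unique(df$label[bad_lab]), collapse = ", "),
                 paste(labels, collapse = ", ")), call. = FALSE)
  }
  co <- as.matrix(df[, c("x0", "y0", "x1", "y1")])
  if (any(!is.finite(co)) || any(co < 0) || any(co != floor(co))) {
    stop(sprintf("%s: coordinates must be non-negative integers", where),
         call. = FALSE)
  }
  if (any(df$x0 >= df$x1) || any(df$y0 >= df$y1)) {
    stop(sprintf("%s: boxes must have positive area (x0 < x1, y0 < y1)",
                 where), call. = FALSE)
  }
  if ("confidence" %in% names(df)) {
    conf <- df$confidence
    if (any(!is.na(conf) & (conf < 0 | conf > 1))) {
      stop(sprintf("%s: confidence must lie in [0, 1]", where), call. = FALSE)
    }
  }
  if (!is.null(meta)) {
    if (any(df$x1 > meta$width) || any(df$y1 > meta$height)) {
      bad <- which(df$x1 > meta$width | df$y1 > meta$height)
      stop(sprintf("%s: box(es) %s outside mosaic '%s' (%d x %d)", where,
                   paste(bad, collapse = ", "), meta$mosaic_id,
                   meta$width, meta$height), call. = FALSE)
    }
  }
  invisible(df)
}

#' Construct an annotation set
#'
#' An annotation set is a data frame of labeled axis-aligned boxes on one
#' mosaic, carrying the mosaic id and the identity of the source that drew
#' them (an observer, a detector, or ground truth). Coordinates are pixels,
#' 0-based, half-open `[x0, x1) x [y0, y1)`, origin at the mosaic top-left.
#'
#' @param boxes data.frame with columns `label`, `x0`, `y0`, `x1`, `y1` and
#'   optionally `confidence` (in `[0,1]`, `NA` for human annotations).
#' @param mosaic_id identifier of the mosaic the boxes live on.
#' @param source_id identity of the annotator (e.g. `"expert"`, `"naive-1"`,
#'   `"model"`, `"truth"`).
#' @param meta optional [mosaic_meta()]; when given, boxes are checked
#'   against the mosaic bounds.
#' @param labels allowed label vocabulary.
#' @return an object of class `annotation_set` (a data.frame).
#' @export
#' @examples
#' annotation_set(data.frame(label = "adult", x0 = 50, y0 = 50,
#'                           x1 = 120, y1 = 120),
#'                mosaic_id = "m1", source_id = "expert")
annotation_set <- function(boxes = NULL, mosaic_id, source_id = "unknown",
                           meta = NULL, labels = caribou_labels()) {
  if (is.null(boxes) || nrow(boxes) == 0) {
    boxes <- data.frame(label = character(), x0 = integer(), y0 = integer(),
                        x1 = integer(), y1 = integer(),
                        confidence = numeric())
  }
  boxes <- as.data.frame(boxes)
  if (!"confidence" %in% names(boxes)) boxes$confidence <- NA_real_
  boxes$label <- normalize_label(boxes$label)
  boxes <- boxes[, c("label", "x0", "y0", "x1", "y1", "confidence")]
  validate_boxes(boxes, labels = labels, meta = meta)
  boxes$x0 <- as.integer(boxes$x0); boxes$y0 <- as.integer(boxes$y0)
  boxes$x1 <- as.integer(boxes$x1); boxes$y1 <- as.integer(boxes$y1)
  boxes$confidence <- as.numeric(boxes$confidence)
  rownames(boxes) <- NULL
  structure(boxes,
            mosaic_id = as.character(mosaic_id),
            source_id = as.character(source_id),
            labels = labels,
            class = c("annotation_set", "data.frame"))
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> mosaic '%s', source '%s', %d annotation(s)\n",
              attr(x, "mosaic_id"), attr(x, "source_id"), nrow(x)))
  if (nrow(x) > 0) print(as.data.frame(x), ...)
  invisible(x)
}

#' @rdname annotation_set
#' @param x an `annotation_set`.
#' @export
mosaic_id <- function(x) attr(x, "mosaic_id")

#' @rdname annotation_set
#' @export
source_id <- function(x) attr(x, "source_id")

#' Mosaic metadata
#'
#' Dimensions and scale of one orthomosaic. The ground sampling distance
#' (GSD) is the ground size of one pixel; the surveys this package mirrors
#' flew at 120 m above ground level (GSD 3.7 cm/px) and 75 m (2.4 cm/px).
#'
#' @param mosaic_id identifier.
#' @param width,height mosaic size in pixels.
#' @param gsd_cm ground sampling distance, centimeters per pixel.
#' @param altitude_agl flight altitude above ground level in meters
#'   (informational).
#' @return an object of class `mosaic_meta`.
#' @export
mosaic_meta <- function(mosaic_id, width, height, gsd_cm, altitude_agl = NA) {
  stopifnot(width > 0, height > 0, gsd_cm > 0)
  structure(list(mosaic_id = as.character(mosaic_id),
                 width = as.integer(width), height = as.integer(height),
                 gsd_cm = as.numeric(gsd_cm),
                 altitude_agl = as.numeric(altitude_agl)),
            class = "mosaic_meta")
}

#' Read and write mosaic metadata sidecars (YAML)
#'
#' @param path file path.
#' @param meta a [mosaic_meta()].
#' @return `read_mosaic_meta` returns a [mosaic_meta()];
#'   `write_mosaic_meta` returns `path` invisibly.
#' @export
read_mosaic_meta <- function(path) {
  m <- yaml::read_yaml(path)
  mosaic_meta(m$mosaic_id, m$width, m$height, m$gsd_cm,
              altitude_agl = if (is.null(m$altitude_agl)) NA else m$altitude_agl)
}

#' @rdname read_mosaic_meta
#' @export
write_mosaic_meta <- function(meta, path) {
  yaml::write_yaml(unclass(meta), path)
  invisible(path)
}

#' Read an annotation file
#'
#' The on-disk dialect is a headered UTF-8 CSV with one annotation per row:
#' `mosaic_id,label,x0,y0,x1,y1,confidence`. `confidence` may be blank
#' (human annotations carry none). Labels are normalized through
#' [normalize_label()], so "adult caribou" and "adult" are equivalent.
#'
#' @param path file path.
#' @param meta optional [mosaic_meta()]; when supplied, boxes outside the
#'   mosaic raise an error.
#' @param source_id source identity to attach; defaults to the file name
#'   without extension.
#' @param labels allowed vocabulary.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, meta = NULL, source_id = NULL,
                             labels = caribou_labels()) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  needed <- c("mosaic_id", "label", "x0", "y0", "x1", "y1")
  if (!all(needed %in% names(df))) {
    stop(sprintf("%s: header must contain %s", path,
                 paste(needed, collapse = ",")), call. = FALSE)
  }
  if (!"confidence" %in% names(df)) df$confidence <- ""
  for (col in c("x0", "y0", "x1", "y1", "confidence")) {
    raw <- trimws(df[[col]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- is.na(num) & nzchar(raw)
    if (any(bad)) {
      # +1 for the header line
      stop(sprintf("%s: parse error at line %d (column '%s': '%s')", path,
                   which(bad)[1] + 1L, col, raw[which(bad)[1]]), call. = FALSE)
    }
    if (col != "confidence") {
      empty <- !nzchar(raw)
      if (any(empty)) {
        stop(sprintf("%s: parse error at line %d (column '%s' empty)", path,
                     which(empty)[1] + 1L, col), call. = FALSE)
      }
    }
    df[[col]] <- num
  }
  mid <- unique(df$mosaic_id)
  if (length(mid) > 1) {
    stop(path, ": annotation file mixes mosaic ids: ",
         paste(mid, collapse = ", "), call. = FALSE)
  }
  if (length(mid) == 0) mid <- if (!is.null(meta)) meta$mosaic_id else NA_character_
  if (!is.null(meta) && !is.na(mid) && mid != meta$mosaic_id) {
    stop(sprintf("%s: file is for mosaic '%s' but metadata describes '%s'",
                 path, mid, meta$mosaic_id), call. = FALSE)
  }
  annotation_set(df[, c("label", "x0", "y0", "x1", "y1", "confidence")],
                 mosaic_id = mid, source_id = source_id, meta = meta,
                 labels = labels)
}

#' Write an annotation set
#'
#' Writes the CSV dialect read by [read_annotations()]. Confidences are
#' written with 6 decimal places; `NA` confidence is written blank. A
#' write-then-read round trip reproduces the set exactly (labels,
#' coordinates, order; confidences to 6 decimals).
#'
#' @param set an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  df <- as.data.frame(set)
  out <- data.frame(mosaic_id = rep(mosaic_id(set), nrow(df)),
                    label = df$label,
                    x0 = df$x0, y0 = df$y0, x1 = df$x1, y1 = df$y1,
                    confidence = ifelse(is.na(df$confidence), "",
                                        sprintf("%.6f", df$confidence)),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    out <- out[0, ]
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write annotations to ", path, call. = FALSE)
  invisible(path)
}

#' Intersection over union of two boxes
#'
#' Standard detection overlap measure under the half-open pixel convention:
#' shared pixel count divided by the union pixel count. Symmetric, in
#' `[0, 1]`, and 0 for disjoint boxes.
#'
#' @param a,b boxes as numeric vectors `c(x0, y0, x1, y1)` or one-row data
#'   frames with those columns.
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' box_iou(c(0, 0, 10, 10), c(1, 1, 11, 11))  # 81/119
box_iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

as_box <- function(b) {
  if (is.data.frame(b)) b <- c(b$x0[1], b$y0[1], b$x1[1], b$y1[1])
  b <- as.numeric(b)
  stopifnot(length(b) == 4, b[1] < b[3], b[2] < b[4])
  b
}

# IoU matrix between all boxes of data.frames A and B (columns x0,y0,x1,y1).
iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  iw <- outer(A$x1, B$x1, pmin) - outer(A$x0, B$x0, pmax)
  ih <- outer(A$y1, B$y1, pmin) - outer(A$y0, B$y0, pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  areaA <- (A$x1 - A$x0) * (A$y1 - A$y0)
  areaB <- (B$x1 - B$x0) * (B$y1 - B$y0)
  inter / (outer(areaA, areaB, "+") - inter)
}
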