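#' Plan an overlapping tile grid over a mosaic
#'
#' Mosaics far exceed what detectors can ingest, so they are cut into
#' fixed-size tiles. To avoid losing or double counting animals split by a
#' tile border, consecutive tiles overlap (by default 100 px on the right
#' and lower borders of a 1000 x 1000 px tile). Tiles start every
#' `stride = tile_size - overlap` pixels; the final row/column is clipped to
#' the mosaic boundary. Each tile also has a *core* — the `stride`-sized
#' region it uniquely owns (extended to the mosaic edge for the last
#' tile per axis) — so that the cores of all tiles partition the mosaic
#' exactly and every annotation has a unique owner.
#'
#' @param meta a [mosaic_meta()] (or anything with `mosaic_id`, `width`,
#'   `height`).
#' @param tile_size tile side length in pixels.
#' @param overlap overlap between consecutive tiles in pixels;
#'   must satisfy `0 < overlap < tile_size`.
#' @return an object of class `tile_grid`: a list with the grid parameters
#'   and a `tiles` data.frame (one row per tile: indices `i`, `j`, extent
#'   `x0,y0,x1,y1`, core `core_x0,...`, and a `key` string `"i<II>_j<JJ>"`).
#' @export
#' @examples
#' g <- plan_grid(mosaic_meta("m", 2800, 1000, 3.7))
#' g$tiles$x0  # tile starts 0, 900, 1800
plan_grid <- function(meta, tile_size = 1000, overlap = 100) {
  if (!(overlap >= 1 && overlap < tile_size)) {
    stop("overlap must satisfy 1 <= overlap < tile_size", call. = FALSE)
  }
  w <- as.integer(meta$width); h <- as.integer(meta$height)
  stopifnot(w > 0, h > 0)
  stride <- as.integer(tile_size - overlap)
  nx <- n_tiles_axis(w, tile_size, overlap)
  ny <- n_tiles_axis(h, tile_size, overlap)
  ij <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  x0 <- ij$i * stride
  y0 <- ij$j * stride
  tiles <- data.frame(
    i = ij$i, j = ij$j,
    x0 = x0, y0 = y0,
    x1 = pmin(x0 + tile_size, w), y1 = pmin(y0 + tile_size, h),
    core_x0 = x0, core_y0 = y0,
    core_x1 = ifelse(ij$i == nx - 1L, w, (ij$i + 1L) * stride),
    core_y1 = ifelse(ij$j == ny - 1L, h, (ij$j + 1L) * stride),
    key = sprintf("i%02d_j%02d", ij$i, ij$j),
    stringsAsFactors = FALSE)
  structure(list(mosaic_id = as.character(meta$mosaic_id),
                 width = w, height = h,
                 tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap),
                 stride = stride, nx = nx, ny = ny, tiles = tiles),
            class = "tile_grid")
}

# Smallest tile count whose extents cover one axis.
n_tiles_axis <- function(dim, tile_size, overlap) {
  stride <- tile_size - overlap
  max(1L, as.integer(ceiling((dim - overlap) / stride)))
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf(paste0("<tile_grid> mosaic '%s' %d x %d px; %d x %d tiles of ",
                     "%d px (overlap %d, stride %d)\n"),
              x$mosaic_id, x$width, x$height, x$nx, x$ny,
              x$tile_size, x$overlap, x$stride))
  invisible(x)
}

# Owning tile indices for top-left corners (x0, y0), clamped to the grid.
owner_index <- function(grid, x0, y0) {
  list(i = pmin(x0 %/% grid$stride, grid$nx - 1L),
       j = pmin(y0 %/% grid$stride, grid$ny - 1L))
}

#' Assign annotations to their owning tiles
#'
#' Every annotation belongs to exactly one tile: the tile whose core
#' contains the box's top-left corner (`i = floor(x0/stride)`, clamped to
#' the last index). With this rule, any box no larger than the overlap in
#' both dimensions is guaranteed to lie fully inside its owner's extent
#' (except where it touches the mosaic's own right/bottom border). Larger
#' boxes may overhang the owner's extent; they are kept, flagged `clipped`,
#' and a warning is issued.
#'
#' @param grid a [plan_grid()] result.
#' @param set an [annotation_set()] in mosaic coordinates.
#' @return named list (by tile `key`) of `annotation_set`s in tile-local
#'   coordinates, each with a `clipped` logical column and attributes
#'   `tile_i`, `tile_j`, `origin`. Tiles that own no annotation are omitted.
#' @export
assign_to_tiles <- function(grid, set) {
  stopifnot(inherits(grid, "tile_grid"), inherits(set, "annotation_set"))
  df <- as.data.frame(set)
  if (nrow(df) > 0 && (any(df$x1 > grid$width) || any(df$y1 > grid$height))) {
    stop("annotation(s) outside mosaic bounds", call. = FALSE)
  }
  out <- list()
  if (nrow(df) == 0) return(out)
  own <- owner_index(grid, df$x0, df$y0)
  key <- sprintf("i%02d_j%02d", own$i, own$j)
  tl <- grid$tiles
  rownames(tl) <- tl$key
  clipped_any <- FALSE
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    t <- tl[k, ]
    loc <- rows
    loc$x0 <- rows$x0 - t$x0; loc$x1 <- rows$x1 - t$x0
    loc$y0 <- rows$y0 - t$y0; loc$y1 <- rows$y1 - t$y0
    loc$clipped <- rows$x1 > t$x1 | rows$y1 > t$y1
    clipped_any <- clipped_any || any(loc$clipped)
    s <- annotation_set(loc[, c("label", "x0", "y0", "x1", "y1", "confidence")],
                        mosaic_id = grid$mosaic_id,
                        source_id = source_id(set),
                        labels = attr(set, "labels"))
    s$clipped <- loc$clipped
    attr(s, "tile_i") <- t$i; attr(s, "tile_j") <- t$j
    attr(s, "origin") <- c(x = t$x0, y = t$y0)
    out[[k]] <- s
  }
  if (clipped_any) {
    warning("some boxes exceed the overlap and overhang their owner tile's ",
            "extent; kept and flagged 'clipped'", call. = FALSE)
  }
  out[order(names(out))]
}

#' Translate boxes between tile-local and mosaic coordinates
#'
#' `tile_to_mosaic` adds the tile origin; `mosaic_to_tile` subtracts it.
#' They are exact inverses.
#'
#' @param tile a row of `grid$tiles` (or any list with `x0`, `y0`, and for
#'   bounds checks `x1`, `y1`).
#' @param boxes data.frame with columns `x0,y0,x1,y1` (other columns are
#'   carried through), or a numeric vector `c(x0,y0,x1,y1)`.
#' @param grid optional [plan_grid()]; when given, `tile_to_mosaic` errors
#'   if a translated box falls outside the mosaic.
#' @return boxes in the other frame, same shape as the input.
#' @export
tile_to_mosaic <- function(tile, boxes, grid = NULL) {
  shift_boxes(boxes, dx = tile$x0, dy = tile$y0, grid = grid)
}

#' @rdname tile_to_mosaic
#' @export
mosaic_to_tile <- function(tile, boxes) {
  shift_boxes(boxes, dx = -tile$x0, dy = -tile$y0)
}

shift_boxes <- function(boxes, dx, dy, grid = NULL) {
  vec <- !is.data.frame(boxes)
  if (vec) boxes <- data.frame(x0 = boxes[1], y0 = boxes[2],
                               x1 = boxes[3], y1 = boxes[4])
  boxes$x0 <- boxes$x0 + dx; boxes$x1 <- boxes$x1 + dx
  boxes$y0 <- boxes$y0 + dy; boxes$y1 <- boxes$y1 + dy
  if (any(boxes$x0 < 0) || any(boxes$y0 < 0)) {
    stop("translated box outside mosaic bounds", call. = FALSE)
  }
  if (!is.null(grid) &&
      (any(boxes$x1 > grid$width) || any(boxes$y1 > grid$height))) {
    stop("translated box outside mosaic bounds", call. = FALSE)
  }
  if (vec) as.numeric(boxes[1, c("x0", "y0", "x1", "y1")]) else boxes
}

#' Merge per-tile detections into mosaic coordinates
#'
#' Translates each tile's detections back to the mosaic frame and removes
#' double counting: a detection is retained only if the tile that emitted it
#' is the detection's owner under the top-left-corner rule, so an animal
#' reported by the two tiles sharing an overlap band is counted once. If
#' `nms_iou` is given, residual same-label duplicates (e.g. a box clipped
#' differently by two tiles so its observed top-left moved) are removed by
#' non-maximum suppression: among survivors with pairwise IoU at or above
#' `nms_iou`, only the highest-confidence box is kept.
#'
#' @param grid a [plan_grid()] result.
#' @param per_tile named list (by tile `key`) of tile-local
#'   [annotation_set()]s, as produced by [assign_to_tiles()] or a per-tile
#'   detector.
#' @param nms_iou IoU threshold for same-label suppression, or `NULL` to
#'   skip NMS.
#' @return an [annotation_set()] in mosaic coordinates.
#' @export
merge_tile_detections <- function(grid, per_tile, nms_iou = NULL) {
  stopifnot(inherits(grid, "tile_grid"))
  tl <- grid$tiles
  rownames(tl) <- tl$key
  src <- "merged"
  labs <- caribou_labels()
  all <- list()
  for (k in names(per_tile)) {
    s <- per_tile[[k]]
    if (is.null(s) || nrow(s) == 0) next
    src <- source_id(s)
    labs <- attr(s, "labels")
    if (!k %in% tl$key) stop("unknown tile key: ", k, call. = FALSE)
    t <- tl[k, ]
    df <- as.data.frame(s)[, c("label", "x0", "y0", "x1", "y1", "confidence")]
    df <- tile_to_mosaic(t, df)
    own <- owner_index(grid, df$x0, df$y0)
    keep <- own$i == t$i & own$j == t$j
    all[[k]] <- df[keep, , drop = FALSE]
  }
  df <- do.call(rbind, all)
  if (is.null(df)) df <- NULL
  out <- annotation_set(df, mosaic_id = grid$mosaic_id, source_id = src,
                        labels = labs)
  if (!is.null(nms_iou) && nrow(out) > 1) {
    out <- nms_filter(out, nms_iou)
  }
  out
}

# Greedy per-label non-maximum suppression; NA confidence ranks lowest but
# ties keep earlier boxes.
nms_filter <- function(set, nms_iou) {
  df <- as.data.frame(set)
  keep <- rep(TRUE, nrow(df))
  for (lab in unique(df$label)) {
    idx <- which(df$label == lab)
    if (length(idx) < 2) next
    conf <- df$confidence[idx]
    conf[is.na(conf)] <- -Inf
    ord <- idx[order(-conf, idx)]
    iou <- iou_matrix(df[ord, ], df[ord, ])
    alive <- rep(TRUE, length(ord))
    for (a in seq_along(ord)) {
      if (!alive[a]) next
      sup <- which(alive & seq_along(ord) > a & iou[a, ] >= nms_iou)
      alive[sup] <- FALSE
    }
    keep[ord[!alive]] <- FALSE
  }
  out <- annotation_set(df[keep, , drop = FALSE], mosaic_id = mosaic_id(set),
                        source_id = source_id(set), labels = attr(set, "labels"))
  out
}

#' Split tiles into training and testing sets
#'
#' Deterministic seeded split of tile keys, by default stratified per mosaic
#' so each mosaic contributes close to `fraction` of its tiles to the
#' training side (rounded to nearest, ties up). Tiles without annotations
#' are ordinary members of the population (detectors need negative
#' examples).
#'
#' @param grids a [plan_grid()] result or a list of them (one per mosaic).
#' @param fraction training fraction in `(0, 1)`.
#' @param seed integer seed; the same seed always yields the same split.
#' @param stratify_by_mosaic stratify the draw per mosaic?
#' @return list with data.frames `train` and `test`, each with columns
#'   `mosaic_id` and `key`.
#' @export
split_tiles <- function(grids, fraction = 0.75, seed = 1L,
                        stratify_by_mosaic = TRUE) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (inherits(grids, "tile_grid")) grids <- list(grids)
  pop <- do.call(rbind, lapply(grids, function(g) {
    data.frame(mosaic_id = g$mosaic_id, key = g$tiles$key,
               stringsAsFactors = FALSE)
  }))
  with_seed(seed, {
    if (stratify_by_mosaic) {
      train_idx <- unlist(lapply(split(seq_len(nrow(pop)), pop$mosaic_id),
                                 function(rows) {
        n_train <- min(length(rows),
                       as.integer(round_half_up(length(rows) * fraction, 0)))
        sort(sample(rows, n_train))
      }), use.names = FALSE)
    } else {
      n_train <- as.integer(round_half_up(nrow(pop) * fraction, 0))
      train_idx <- sort(sample(seq_len(nrow(pop)), n_train))
    }
    list(train = pop[train_idx, , drop = FALSE],
         test = pop[setdiff(seq_len(nrow(pop)), train_idx), , drop = FALSE])
  })
}
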