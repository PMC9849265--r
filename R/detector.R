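#' Configuration for the contrast-blob baseline detector
#'
#' A deliberately simple, non-learned detector so the complete
#' tile-detect-merge-evaluate pipeline can run end to end on synthetic
#' scenes without a GPU or trained weights. It is *not* a stand-in for a
#' convolutional detector's accuracy; an adapter interface (any function
#' mapping a tile raster to an [annotation_set()]) lets users plug in a
#' real model. Areas are metric (m^2) and scaled to pixels through the
#' GSD, so one configuration works at both survey altitudes.
#'
#' @param bg_block_px side of the square blocks used for local median
#'   background estimation.
#' @param z_thresh foreground threshold in robust (MAD-based) noise SDs.
#' @param min_contrast absolute lower bound on the foreground contrast
#'   threshold (gray levels), so near-uniform tiles do not dissolve into
#'   noise detections.
#' @param min_area_m2,max_area_m2 blob area window; blobs outside are
#'   discarded (birds fall below, willow islands above).
#' @param calf_area_m2 blobs below this area are labeled `calf`, above
#'   `adult`.
#' @param ghost_contrast blobs whose mean absolute contrast is below this
#'   are relabeled `ghost` regardless of size (ghosts are semi-transparent,
#'   hence low-contrast).
#' @param nms_iou IoU used when merging per-tile detections.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(bg_block_px = 120, z_thresh = 4,
                            min_contrast = 0.06,
                            min_area_m2 = 0.05, max_area_m2 = 6,
                            calf_area_m2 = 0.5, ghost_contrast = 0.25,
                            nms_iou = 0.5) {
  stopifnot(bg_block_px >= 8, z_thresh > 0, min_contrast >= 0,
            min_area_m2 > 0, calf_area_m2 > min_area_m2,
            max_area_m2 > calf_area_m2, ghost_contrast > 0,
            nms_iou > 0, nms_iou <= 1)
  structure(list(bg_block_px = as.integer(bg_block_px), z_thresh = z_thresh,
                 min_contrast = min_contrast, min_area_m2 = min_area_m2,
                 max_area_m2 = max_area_m2, calf_area_m2 = calf_area_m2,
                 ghost_contrast = ghost_contrast, nms_iou = nms_iou),
            class = "detector_config")
}

# Blockwise median background (nearest-block expansion). Animals cover a
# small fraction of any block, so the median tracks the terrain.
block_median_background <- function(img, block) {
  h <- nrow(img); w <- ncol(img)
  ri <- pmin((seq_len(h) - 1L) %/% block + 1L, max(1L, ceiling(h / block)))
  ci <- pmin((seq_len(w) - 1L) %/% block + 1L, max(1L, ceiling(w / block)))
  med <- tapply(as.vector(img),
                list(row = ri[row(img)], col = ci[col(img)]), median)
  med[cbind(ri[row(img)], ci[col(img)])] |>
    matrix(nrow = h, ncol = w)
}

#' Detect animals in a single tile raster
#'
#' Background is estimated by blockwise local medians; pixels whose
#' absolute deviation exceeds `max(z_thresh * MAD-sd, min_contrast)` are
#' foreground; 8-connected components are filtered by the GSD-scaled area
#' window and labeled: `calf` below the calf/adult area cut, `adult`
#' above, relabeled `ghost` when the blob's mean contrast falls below the
#' ghost cut. Confidence is the blob's mean contrast normalized to
#' `[0, 1]`.
#'
#' @param tile_raster numeric matrix in `[0, 1]` (rows = y).
#' @param config a [detector_config()].
#' @param gsd_cm ground sampling distance of the raster, cm/pixel.
#' @param mosaic_id,source_id identities for the returned set.
#' @return a tile-local [annotation_set()] with confidences.
#' @export
detect_tile <- function(tile_raster, config, gsd_cm,
                        mosaic_id = "tile", source_id = "baseline") {
  stopifnot(inherits(config, "detector_config"))
  if (length(tile_raster) == 0) stop("empty raster", call. = FALSE)
  px_per_m2 <- (100 / gsd_cm)^2
  bg <- block_median_background(tile_raster, config$bg_block_px)
  dev <- tile_raster - bg
  noise <- mad(dev)
  thr <- max(config$z_thresh * noise, config$min_contrast)
  fg <- abs(dev) > thr
  empty <- annotation_set(NULL, mosaic_id = mosaic_id, source_id = source_id)
  if (!any(fg)) return(empty)
  lab <- t(as.matrix(EBImage::bwlabel(EBImage::Image(t(fg * 1)))))
  idx <- which(lab > 0)
  comp <- lab[idx]
  rowi <- (idx - 1L) %% nrow(lab) + 1L
  coli <- (idx - 1L) %/% nrow(lab) + 1L
  contr <- abs(dev)[idx]
  min_px <- config$min_area_m2 * px_per_m2
  max_px <- config$max_area_m2 * px_per_m2
  calf_px <- config$calf_area_m2 * px_per_m2
  out <- list()
  for (k in unique(comp)) {
    sel <- comp == k
    area <- sum(sel)
    if (area < min_px || area > max_px) next
    mc <- mean(contr[sel])
    label <- if (mc < config$ghost_contrast) "ghost"
             else if (area < calf_px) "calf" else "adult"
    out[[length(out) + 1]] <- data.frame(
      label = label,
      x0 = min(coli[sel]) - 1L, y0 = min(rowi[sel]) - 1L,
      x1 = max(coli[sel]), y1 = max(rowi[sel]),
      confidence = min(1, mc / 0.45))
  }
  annotation_set(do.call(rbind, out), mosaic_id = mosaic_id,
                 source_id = source_id)
}

#' Detect animals across a whole mosaic via its tile grid
#'
#' Runs [detect_tile()] on every tile extent and merges the per-tile
#' detections back to mosaic coordinates with [merge_tile_detections()]
#' (owner rule + NMS at `config$nms_iou`), so animals in overlap bands are
#' counted once. Deterministic.
#'
#' @param raster full-mosaic numeric matrix in `[0, 1]`.
#' @param grid a [plan_grid()] whose dimensions match the raster.
#' @param config a [detector_config()].
#' @param gsd_cm ground sampling distance, cm/pixel.
#' @param source_id identity for the returned set.
#' @return an [annotation_set()] in mosaic coordinates.
#' @export
detect_mosaic <- function(raster, grid, config, gsd_cm,
                          source_id = "baseline") {
  stopifnot(inherits(grid, "tile_grid"))
  if (nrow(raster) != grid$height || ncol(raster) != grid$width) {
    stop(sprintf("raster is %d x %d but grid describes %d x %d",
                 ncol(raster), nrow(raster), grid$width, grid$height),
         call. = FALSE)
  }
  per_tile <- list()
  for (k in seq_len(nrow(grid$tiles))) {
    t <- grid$tiles[k, ]
    sub <- raster[(t$y0 + 1):t$y1, (t$x0 + 1):t$x1, drop = FALSE]
    det <- detect_tile(sub, config, gsd_cm, mosaic_id = grid$mosaic_id,
                       source_id = source_id)
    # a blob cut off at an interior left/top tile edge is a fragment of an
    # object that starts in (and is fully visible to) an earlier tile;
    # dropping it here prevents fragment duplicates whose clipped top-left
    # corner would otherwise fall into this tile's own core
    keep <- !(t$i > 0 & det$x0 == 0) & !(t$j > 0 & det$y0 == 0)
    det <- annotation_set(as.data.frame(det)[keep, , drop = FALSE],
                          mosaic_id = grid$mosaic_id, source_id = source_id)
    per_tile[[t$key]] <- det
  }
  merge_tile_detections(grid, per_tile, nms_iou = config$nms_iou)
}
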