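#' Read a mosaic raster from PNG or TIFF
#'
#' Returns a single-channel matrix in `[0, 1]` (rows = y, origin top-left);
#' multi-channel images are averaged to gray.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @return numeric matrix.
#' @export
read_mosaic_raster <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported raster format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                              drop = FALSE], c(1, 2), mean)
  img
}

#' Cut a mosaic into overlapping tile images on disk
#'
#' Plans the grid, writes each tile as `{mosaic_id}_i{II}_j{JJ}.png`, and a
#' tile index CSV (`tile`, `origin_x`, `origin_y`, `width`, `height`) that
#' downstream steps use to map detections back to mosaic coordinates.
#'
#' @param raster mosaic matrix (from [read_mosaic_raster()] or
#'   [generate_scene()]) or a path to an image file.
#' @param meta a [mosaic_meta()]; when `raster` is a path and `meta` is
#'   `NULL`, dimensions are taken from the image and `gsd_cm` must be
#'   supplied.
#' @param out_dir output directory.
#' @param tile_size,overlap grid geometry in pixels.
#' @param gsd_cm ground sampling distance, used only when `meta` is `NULL`.
#' @return the [plan_grid()] used, invisibly; the index CSV is written as
#'   `tile_index.csv` in `out_dir`.
#' @export
tile_mosaic <- function(raster, meta = NULL, out_dir = ".",
                        tile_size = 1000, overlap = 100, gsd_cm = NULL) {
  if (is.character(raster)) {
    path <- raster
    raster <- read_mosaic_raster(path)
    if (is.null(meta)) {
      if (is.null(gsd_cm)) stop("need meta or gsd_cm", call. = FALSE)
      meta <- mosaic_meta(sub("\\.[^.]*$", "", basename(path)),
                          ncol(raster), nrow(raster), gsd_cm)
    }
  }
  stopifnot(!is.null(meta))
  grid <- plan_grid(meta, tile_size = tile_size, overlap = overlap)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  idx <- grid$tiles
  idx$tile <- sprintf("%s_%s.png", grid$mosaic_id, idx$key)
  for (k in seq_len(nrow(idx))) {
    t <- idx[k, ]
    png::writePNG(raster[(t$y0 + 1):t$y1, (t$x0 + 1):t$x1, drop = FALSE],
                  file.path(out_dir, t$tile))
  }
  out <- data.frame(tile = idx$tile, origin_x = idx$x0, origin_y = idx$y0,
                    width = idx$x1 - idx$x0, height = idx$y1 - idx$y0)
  write.csv(out, file.path(out_dir, "tile_index.csv"), row.names = FALSE)
  message(sprintf("tiled mosaic '%s' into %d tiles (%d x %d)",
                  grid$mosaic_id, nrow(idx), grid$nx, grid$ny))
  invisible(grid)
}

#' Evaluate annotation files against a reference observer's file
#'
#' File-level front end to [evaluate_source()] / [pool_observers()]: reads
#' the reference and each source annotation CSV, evaluates every source,
#' pools them, and writes a report (counts/metrics CSV, confusion CSV,
#' pooled CSV, correlations CSV when a grid is available, and a JSON
#' bundle).
#'
#' @param reference_path reference annotation CSV.
#' @param source_paths character vector of source annotation CSVs.
#' @param meta_path optional mosaic metadata YAML; enables bounds checks
#'   and tiling-based per-tile correlations.
#' @param out_dir directory for report files (created if needed).
#' @param iou_threshold,pct_diff_denominator,tile_size,overlap evaluation
#'   configuration.
#' @return list with `summaries`, `pooled`, `correlations` (invisibly).
#' @export
evaluate_files <- function(reference_path, source_paths, meta_path = NULL,
                           out_dir = ".", iou_threshold = 0.3,
                           pct_diff_denominator = "reference",
                           tile_size = 1000, overlap = 100) {
  meta <- if (!is.null(meta_path)) read_mosaic_meta(meta_path)
  reference <- read_annotations(reference_path, meta = meta)
  grid <- if (!is.null(meta)) plan_grid(meta, tile_size, overlap)
  summaries <- lapply(source_paths, function(p) {
    evaluate_source(reference, read_annotations(p, meta = meta), grid = grid,
                    iou_threshold = iou_threshold,
                    pct_diff_denominator = pct_diff_denominator)
  })
  names(summaries) <- vapply(summaries, `[[`, "", "source_id")
  pooled <- pool_observers(summaries,
                           pct_diff_denominator = pct_diff_denominator)
  correlations <- if (!is.null(grid)) {
    do.call(rbind, lapply(summaries, function(s) {
      cbind(source_id = s$source_id, correlation_report(s))
    }))
  }
  write_report(summaries, pooled, correlations, out_dir)
  invisible(list(summaries = summaries, pooled = pooled,
                 correlations = correlations))
}

#' Write evaluation reports
#'
#' Emits the per-source counts/metrics table (one row per source x class,
#' metrics rounded the way survey tables print them: proportions to 2
#' decimals, percentages to 1), the confusion tables, the pooled
#' observer table, optional per-tile correlations, and a JSON bundle of
#' everything unrounded.
#'
#' @param summaries named list of `source_summary` objects.
#' @param pooled a [pool_observers()] result (or `NULL`).
#' @param correlations a correlations data.frame (or `NULL`).
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(summaries, pooled = NULL, correlations = NULL,
                         out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- do.call(rbind, lapply(summaries, function(s) {
    df <- s$counts
    data.frame(mosaic_id = s$mosaic_id, source_id = s$source_id,
               class = rownames(df), raw_count = df$raw_count,
               ref_count = df$ref_count, tp = df$tp, fp = df$fp, fn = df$fn,
               accuracy = round_half_up(df$accuracy, 2),
               precision = round_half_up(df$precision, 2),
               recall = round_half_up(df$recall, 2),
               pct_diff = round_half_up(df$pct_diff, 1),
               row.names = NULL)
  }))
  write.csv(counts, file.path(out_dir, "counts.csv"), row.names = FALSE)
  confusion <- do.call(rbind, lapply(summaries, function(s) {
    cf <- as.data.frame(as.table(s$confusion))
    names(cf) <- c("reference", "predicted", "n")
    cbind(source_id = s$source_id, cf)
  }))
  write.csv(confusion, file.path(out_dir, "confusion.csv"), row.names = FALSE)
  if (!is.null(pooled)) {
    pw <- cbind(class = rownames(pooled), as.data.frame(pooled))
    write.csv(pw, file.path(out_dir, "pooled.csv"), row.names = FALSE)
  }
  if (!is.null(correlations)) {
    write.csv(correlations, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
  }
  bundle <- list(
    sources = lapply(summaries, function(s) {
      list(source_id = s$source_id, mosaic_id = s$mosaic_id, scope = s$scope,
           counts = cbind(class = rownames(s$counts), s$counts),
           confusion = as.data.frame(as.table(s$confusion)),
           processing_time_min = s$processing_time_min)
    }),
    pooled = if (!is.null(pooled)) cbind(class = rownames(pooled),
                                         as.data.frame(pooled)),
    correlations = correlations)
  jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(out_dir)
}
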