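#' Specification of a synthetic survey scene
#'
#' The generator emulates the imagery a caribou drone survey produces: a
#' textured tundra background (meadow/water/shrub patches), high-contrast
#' elongated adult and calf sprites at realistic metric sizes, "ghost"
#' sprites composited semi-transparently after Gaussian blur (mimicking
#' animals that moved between overlapping photos during mosaicking), and
#' non-animal distractors (rocks, birds, tree trunks) that detectors may
#' confuse with animals. All sizes are metric and converted to pixels via
#' the ground sampling distance, so the two survey altitudes (75 m, GSD
#' 2.4 cm/px; 120 m, GSD 3.7 cm/px) are just two parameterizations.
#'
#' Numeric defaults (animal sizes, ghost alpha/blur, tones) are this
#' package's own calibration, chosen to look like the survey conditions
#' described in the field literature; they are all configuration, never
#' hard-wired into the analysis code.
#'
#' @param mosaic_id identifier for the generated mosaic.
#' @param width,height scene size in pixels.
#' @param gsd_cm ground sampling distance in cm/pixel (presets: 2.4, 3.7).
#' @param n_adult,n_calf,n_ghost animal counts per class.
#' @param n_rock,n_bird,n_trunk distractor counts.
#' @param adult_length_m adult body length range in meters.
#' @param adult_aspect body width/length ratio range.
#' @param calf_scale calf size range as a fraction of adult length.
#' @param ghost_alpha ghost opacity range (1 = opaque).
#' @param ghost_blur_sigma_px ghost Gaussian blur sigma range, pixels.
#' @param body_tone animal brightness range on the `[0, 1]` gray scale
#'   (background sits near 0.48).
#' @param min_separation_px minimum center-to-center distance between any
#'   two placed objects.
#' @param seed integer seed; the scene is a pure function of the spec.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(mosaic_id = "scene", width = 2000, height = 1500,
                       gsd_cm = 3.7,
                       n_adult = 30, n_calf = 10, n_ghost = 5,
                       n_rock = 10, n_bird = 4, n_trunk = 4,
                       adult_length_m = c(1.3, 2.1),
                       adult_aspect = c(0.30, 0.45),
                       calf_scale = c(0.5, 0.7),
                       ghost_alpha = c(0.25, 0.6),
                       ghost_blur_sigma_px = c(1, 3),
                       body_tone = c(0.82, 0.95),
                       min_separation_px = 40,
                       seed = 1L) {
  rng <- function(r, nm) {
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
      stop("invalid range for ", nm, call. = FALSE)
    }
  }
  rng(adult_length_m, "adult_length_m"); rng(adult_aspect, "adult_aspect")
  rng(calf_scale, "calf_scale"); rng(ghost_alpha, "ghost_alpha")
  rng(ghost_blur_sigma_px, "ghost_blur_sigma_px"); rng(body_tone, "body_tone")
  stopifnot(width > 0, height > 0, gsd_cm > 0, min_separation_px >= 0,
            n_adult >= 0, n_calf >= 0, n_ghost >= 0,
            n_rock >= 0, n_bird >= 0, n_trunk >= 0)
  structure(list(mosaic_id = as.character(mosaic_id),
                 width = as.integer(width), height = as.integer(height),
                 gsd_cm = gsd_cm,
                 n_adult = as.integer(n_adult), n_calf = as.integer(n_calf),
                 n_ghost = as.integer(n_ghost),
                 n_rock = as.integer(n_rock), n_bird = as.integer(n_bird),
                 n_trunk = as.integer(n_trunk),
                 adult_length_m = adult_length_m, adult_aspect = adult_aspect,
                 calf_scale = calf_scale, ghost_alpha = ghost_alpha,
                 ghost_blur_sigma_px = ghost_blur_sigma_px,
                 body_tone = body_tone,
                 min_separation_px = min_separation_px,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Exact separable Gaussian blur with renormalized (reflected-mass) edges.
# Patches are small, so dense convolution matrices are fine and fully
# deterministic.
conv_matrix <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1 & idx <= n
    K[i, idx[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

gaussian_blur <- function(m, sigma) {
  conv_matrix(nrow(m), sigma) %*% m %*% t(conv_matrix(ncol(m), sigma))
}

# Smoothly varying background field: coarse random grid, bilinearly
# interpolated to full size.
render_background <- function(width, height, base = 0.48,
                              patch_amp = 0.05, patch_px = 180,
                              noise_sd = 0.015) {
  nxc <- max(2L, ceiling(width / patch_px) + 1L)
  nyc <- max(2L, ceiling(height / patch_px) + 1L)
  coarse <- matrix(runif(nyc * nxc, -patch_amp, patch_amp), nyc, nxc)
  xi <- seq(1, nxc, length.out = width)
  yi <- seq(1, nyc, length.out = height)
  x0 <- pmin(floor(xi), nxc - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), nyc - 1L); fy <- yi - y0
  a <- coarse[y0, x0] * outer(1 - fy, 1 - fx) +
       coarse[y0 + 1, x0] * outer(fy, 1 - fx) +
       coarse[y0, x0 + 1] * outer(1 - fy, fx) +
       coarse[y0 + 1, x0 + 1] * outer(fy, fx)
  field <- base + a + matrix(rnorm(height * width, sd = noise_sd),
                             height, width)
  pmin(pmax(field, 0), 1)
}

# Rotated-ellipse sprite mask on an odd-sized square patch.
ellipse_mask <- function(len_px, aspect, theta, pad = 4L) {
  s <- as.integer(ceiling(len_px)) + 2L * pad
  if (s %% 2 == 0) s <- s + 1L
  c0 <- (s + 1) / 2
  a <- len_px / 2
  b <- max(0.8, aspect * len_px / 2)
  X <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  Y <- matrix(rep(seq_len(s), times = s), s, s)  # row index
  u <- (X - c0) * cos(theta) + (Y - c0) * sin(theta)
  v <- -(X - c0) * sin(theta) + (Y - c0) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a synthetic mosaic scene
#'
#' Renders the scene described by a [scene_spec()]: a single-channel
#' raster in `[0, 1]` (rows = y, columns = x, origin top-left), a truth
#' [annotation_set()] whose boxes are the tight bounding boxes of each
#' rendered animal's visible pixels, and a separate distractor set (rocks,
#' birds, trunks) that is rendered into the raster but is *not* part of the
#' truth — observers and detectors are never supposed to annotate them.
#' Bit-identical output for the same spec.
#'
#' @param spec a [scene_spec()].
#' @param return_masks also return each annotation's rendered pixel set
#'   (list of `(row, col)` index matrices), used by geometry audits.
#' @return list of class `scene`: `raster`, `truth`, `distractors`, `meta`
#'   (a [mosaic_meta()]), and optionally `masks`.
#' @export
generate_scene <- function(spec, return_masks = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  px_per_m <- 100 / spec$gsd_cm
  with_seed(spec$seed, {
    canvas <- render_background(spec$width, spec$height)
    placed <- matrix(numeric(0), ncol = 2)  # centers (x, y)
    truth <- list(); distract <- list(); masks <- list()
    total <- spec$n_adult + spec$n_calf + spec$n_ghost +
      spec$n_rock + spec$n_bird + spec$n_trunk

    place_center <- function(margin) {
      lo_x <- margin + 1; hi_x <- spec$width - margin
      lo_y <- margin + 1; hi_y <- spec$height - margin
      if (hi_x <= lo_x || hi_y <= lo_y) return(NULL)
      for (try in seq_len(300)) {
        cx <- runif(1, lo_x, hi_x); cy <- runif(1, lo_y, hi_y)
        if (nrow(placed) == 0 ||
            min((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >=
              spec$min_separation_px^2) {
          return(c(cx, cy))
        }
      }
      NULL
    }
    capacity_stop <- function() {
      stop(sprintf(paste0("placement capacity exceeded: placed %d of %d ",
                          "objects at min_separation %d px"),
                   nrow(placed), total, spec$min_separation_px),
           call. = FALSE)
    }

    # draw one sprite; returns its tight bbox and visible pixel set
    draw_sprite <- function(len_px, aspect, tone_rng, ghost = FALSE) {
      theta <- runif(1, 0, pi)
      alpha <- if (ghost) runif(1, spec$ghost_alpha[1], spec$ghost_alpha[2]) else 1
      sigma <- if (ghost) {
        runif(1, spec$ghost_blur_sigma_px[1], spec$ghost_blur_sigma_px[2])
      } else 0
      pad <- 4L + as.integer(ceiling(3 * sigma))
      mask <- ellipse_mask(len_px, aspect, theta, pad = pad)
      s <- nrow(mask)
      ctr <- place_center(margin = (s + 1) / 2)
      if (is.null(ctr)) capacity_stop()
      placed <<- rbind(placed, ctr)
      r0 <- as.integer(round(ctr[2] - (s - 1) / 2))
      c0 <- as.integer(round(ctr[1] - (s - 1) / 2))
      rows <- r0:(r0 + s - 1); cols <- c0:(c0 + s - 1)
      tone <- runif(1, tone_rng[1], tone_rng[2])
      body <- matrix(pmin(pmax(tone + rnorm(s * s, sd = 0.03), 0), 1), s, s)
      patch <- canvas[rows, cols]
      if (ghost) {
        eff <- gaussian_blur(mask * 1, sigma) * alpha
        patch <- patch * (1 - eff) + body * eff
        vis <- eff > 0.05
      } else {
        patch[mask] <- body[mask]
        vis <- mask
      }
      canvas[rows, cols] <<- patch
      w <- which(vis, arr.ind = TRUE)
      pix <- cbind(row = rows[w[, 1]], col = cols[w[, 2]])
      list(bbox = c(x0 = min(pix[, "col"]) - 1L, y0 = min(pix[, "row"]) - 1L,
                    x1 = max(pix[, "col"]), y1 = max(pix[, "row"])),
           pix = pix)
    }

    add <- function(bucket, label, sp) {
      row <- data.frame(label = label, x0 = sp$bbox["x0"], y0 = sp$bbox["y0"],
                        x1 = sp$bbox["x1"], y1 = sp$bbox["y1"],
                        confidence = NA_real_)
      if (bucket == "truth") truth[[length(truth) + 1]] <<- row
      else distract[[length(distract) + 1]] <<- row
      if (return_masks) masks[[length(masks) + 1]] <<-
        list(bucket = bucket, label = label, pix = sp$pix)
    }

    adult_len <- function() runif(1, spec$adult_length_m[1],
                                  spec$adult_length_m[2]) * px_per_m
    aspect <- function() runif(1, spec$adult_aspect[1], spec$adult_aspect[2])

    for (k in seq_len(spec$n_adult)) {
      add("truth", "adult", draw_sprite(adult_len(), aspect(), spec$body_tone))
    }
    for (k in seq_len(spec$n_calf)) {
      len <- adult_len() * runif(1, spec$calf_scale[1], spec$calf_scale[2])
      add("truth", "calf", draw_sprite(len, aspect(), spec$body_tone))
    }
    for (k in seq_len(spec$n_ghost)) {
      # ghosts can be adult- or calf-sized
      len <- adult_len() * if (runif(1) < 0.25) {
        runif(1, spec$calf_scale[1], spec$calf_scale[2])
      } else 1
      add("truth", "ghost", draw_sprite(len, aspect(), spec$body_tone,
                                        ghost = TRUE))
    }
    for (k in seq_len(spec$n_rock)) {
      add("distractor", "rock",
          draw_sprite(runif(1, 0.3, 0.9) * px_per_m, runif(1, 0.7, 1.0),
                      c(0.60, 0.72)))
    }
    for (k in seq_len(spec$n_bird)) {
      add("distractor", "bird",
          draw_sprite(runif(1, 0.10, 0.20) * px_per_m, runif(1, 0.5, 0.8),
                      c(0.85, 0.95)))
    }
    for (k in seq_len(spec$n_trunk)) {
      add("distractor", "trunk",
          draw_sprite(runif(1, 1.0, 3.0) * px_per_m, runif(1, 0.05, 0.12),
                      c(0.15, 0.30)))
    }

    meta <- mosaic_meta(spec$mosaic_id, spec$width, spec$height, spec$gsd_cm,
                        altitude_agl = if (spec$gsd_cm <= 3.0) 75 else 120)
    truth_set <- annotation_set(do.call(rbind, truth),
                                mosaic_id = spec$mosaic_id,
                                source_id = "truth", meta = meta)
    distract_set <- annotation_set(do.call(rbind, distract),
                                   mosaic_id = spec$mosaic_id,
                                   source_id = "distractors", meta = meta,
                                   labels = distractor_labels())
    out <- list(raster = canvas, truth = truth_set,
                distractors = distract_set, meta = meta, spec = spec)
    if (return_masks) out$masks <- masks
    structure(out, class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> '%s' %d x %d px (GSD %.1f cm): %d animals, %d distractors\n",
              x$meta$mosaic_id, x$meta$width, x$meta$height, x$meta$gsd_cm,
              nrow(x$truth), nrow(x$distractors)))
  invisible(x)
}

#' Error model for a simulated observer or detector
#'
#' Per true animal of class `y`: with probability `miss[y]` the annotator
#' does not record it at all; otherwise the recorded label is drawn from
#' the confusion row `confusion[y, ]` (so `miss[y] + sum(confusion[y, ])`
#' must equal 1) and the box corners are jittered by rounded Gaussian
#' noise. Independently, each distractor object is annotated as caribou
#' class `x` with probability `object_fp_rate[x] / 100` (the rate is
#' expressed as expected spurious annotations per 100 distractors). Human
#' observers leave `object_fp_rate` at 0 — in the surveys this package
#' mirrors, people never mistook rocks or trunks for caribou, but detectors
#' did. Detector-style models can draw confidences from a Beta
#' distribution; human annotations carry none.
#'
#' @param miss named miss probabilities for `adult`, `calf`, `ghost`
#'   (a scalar is recycled).
#' @param confusion 3x3 matrix of label-assignment probabilities (rows =
#'   true class, columns = recorded class); default: correct labeling with
#'   probability `1 - miss`.
#' @param bbox_jitter_sd_px SD of the corner jitter, pixels.
#' @param object_fp_rate named per-class spurious-annotation rates per 100
#'   distractors (scalar recycled).
#' @param confidence `NULL` (no confidences) or `c(shape1, shape2)` of a
#'   Beta distribution.
#' @param source_id identity attached to simulated sets.
#' @param seed integer seed; simulation is a pure function of
#'   (truth, distractors, model).
#' @return an object of class `observer_model`.
#' @export
observer_model <- function(miss = 0, confusion = NULL, bbox_jitter_sd_px = 0,
                           object_fp_rate = 0, confidence = NULL,
                           source_id = "observer", seed = 1L) {
  labs <- caribou_labels()
  expand <- function(x, nm) {
    if (length(x) == 1 && is.null(names(x))) x <- rep(x, 3)
    if (is.null(names(x))) names(x) <- labs
    if (!all(labs %in% names(x))) stop(nm, " must name all classes", call. = FALSE)
    x <- x[labs]
    if (any(x < 0)) stop(nm, " must be non-negative", call. = FALSE)
    x
  }
  miss <- expand(miss, "miss")
  if (any(miss > 1)) stop("miss probabilities must lie in [0, 1]", call. = FALSE)
  if (is.null(confusion)) {
    confusion <- diag(1 - miss)
    dimnames(confusion) <- list(labs, labs)
  }
  confusion <- as.matrix(confusion)[labs, labs]
  if (any(confusion < 0) || any(confusion > 1)) {
    stop("confusion probabilities must lie in [0, 1]", call. = FALSE)
  }
  tot <- miss + rowSums(confusion)
  if (any(abs(tot - 1) > 1e-8)) {
    stop("each class's miss + confusion row must sum to 1 (got ",
         paste(sprintf("%s=%.4f", labs, tot), collapse = ", "), ")",
         call. = FALSE)
  }
  object_fp_rate <- expand(object_fp_rate, "object_fp_rate")
  if (sum(object_fp_rate) > 100) {
    stop("object_fp_rate sums to more than 100 per 100 distractors",
         call. = FALSE)
  }
  if (!is.null(confidence) &&
      (length(confidence) != 2 || any(confidence <= 0))) {
    stop("confidence must be NULL or two positive Beta shapes", call. = FALSE)
  }
  structure(list(miss = miss, confusion = confusion,
                 bbox_jitter_sd_px = bbox_jitter_sd_px,
                 object_fp_rate = object_fp_rate, confidence = confidence,
                 source_id = as.character(source_id),
                 seed = as.integer(seed)),
            class = "observer_model")
}

#' Simulate an error-prone observer or detector
#'
#' Applies an [observer_model()] to a truth annotation set (and optionally
#' the scene's distractor set): each truth box is independently missed,
#' relabeled by a draw from its confusion row, and jittered; spurious
#' caribou annotations are planted on randomly selected distractors.
#' Deterministic given the model's seed; re-simulating an observer never
#' requires re-rendering the scene.
#'
#' @param truth truth [annotation_set()].
#' @param model an [observer_model()].
#' @param distractors optional distractor [annotation_set()] (labels
#'   `rock`/`bird`/`trunk`).
#' @param meta optional [mosaic_meta()]; jittered boxes are clipped to the
#'   mosaic when given.
#' @return an [annotation_set()] with `source_id` from the model.
#' @export
simulate_observer <- function(truth, model, distractors = NULL, meta = NULL) {
  stopifnot(inherits(truth, "annotation_set"), inherits(model, "observer_model"))
  labs <- caribou_labels()
  draw_conf <- function(n) {
    if (is.null(model$confidence)) rep(NA_real_, n)
    else rbeta(n, model$confidence[1], model$confidence[2])
  }
  with_seed(model$seed, {
    T <- as.data.frame(truth)
    pieces <- list()
    if (nrow(T) > 0) {
      keep <- runif(nrow(T)) >= model$miss[T$label]
      kept <- T[keep, , drop = FALSE]
      if (nrow(kept) > 0) {
        u <- runif(nrow(kept))
        newlab <- vapply(seq_len(nrow(kept)), function(k) {
          p <- model$confusion[kept$label[k], ]
          labs[findInterval(u[k] * sum(p), cumsum(p)) + 1L]
        }, "")
        kept$label <- newlab
        kept <- jitter_boxes(kept, model$bbox_jitter_sd_px, meta)
        kept$confidence <- draw_conf(nrow(kept))
        pieces$truth <- kept
      }
    }
    if (!is.null(distractors) && nrow(distractors) > 0 &&
        sum(model$object_fp_rate) > 0) {
      D <- as.data.frame(distractors)
      cum <- cumsum(model$object_fp_rate / 100)
      u <- runif(nrow(D))
      hit <- u < cum[length(cum)]
      if (any(hit)) {
        fp <- D[hit, , drop = FALSE]
        fp$label <- labs[findInterval(u[hit], c(0, cum), left.open = TRUE)]
        fp <- jitter_boxes(fp, model$bbox_jitter_sd_px, meta)
        fp$confidence <- draw_conf(nrow(fp))
        pieces$fp <- fp
      }
    }
    out <- if (length(pieces) > 0) {
      do.call(rbind, lapply(pieces, function(d) {
        d[, c("label", "x0", "y0", "x1", "y1", "confidence")]
      }))
    }
    annotation_set(out, mosaic_id = mosaic_id(truth),
                   source_id = model$source_id, meta = meta)
  })
}

# Jitter all four sides of every box, keeping each inside the mosaic with
# >= 1 px area.
jitter_boxes <- function(df, sd_px, meta) {
  b <- as.matrix(df[, c("x0", "y0", "x1", "y1")])
  if (sd_px > 0) {
    b <- b + matrix(round(rnorm(length(b), sd = sd_px)), nrow(b), 4)
  }
  b <- pmax(b, 0)
  if (!is.null(meta)) {
    b[, c(1, 3)] <- pmin(b[, c(1, 3)], meta$width)
    b[, c(2, 4)] <- pmin(b[, c(2, 4)], meta$height)
  }
  flat_x <- b[, 3] <= b[, 1]
  b[flat_x, 3] <- b[flat_x, 1] + 1
  flat_y <- b[, 4] <= b[, 2]
  b[flat_y, 4] <- b[flat_y, 2] + 1
  if (!is.null(meta)) {
    over_x <- b[, 3] > meta$width
    b[over_x, 3] <- meta$width
    b[over_x, 1] <- pmin(b[over_x, 1], meta$width - 1)
    over_y <- b[, 4] > meta$height
    b[over_y, 4] <- meta$height
    b[over_y, 2] <- pmin(b[over_y, 2], meta$height - 1)
  }
  df[, c("x0", "y0", "x1", "y1")] <- b
  df
}

# Default fixture-suite parameterization: four scenes (two per GSD preset,
# echoing two mosaics per survey altitude), herd sizes of the order a real
# survey records, one expert, five naive observers, one detector-like
# source.
default_scene_specs <- function(seed, width = 2800, height = 1900) {
  counts <- list(c(62, 29, 4), c(59, 25, 25), c(44, 9, 10), c(77, 25, 34))
  gsd <- c(3.7, 3.7, 2.4, 2.4)
  ids <- c("m120a", "m120b", "m75a", "m75b")
  lapply(1:4, function(k) {
    scene_spec(mosaic_id = ids[k], width = width, height = height,
               gsd_cm = gsd[k],
               n_adult = counts[[k]][1], n_calf = counts[[k]][2],
               n_ghost = counts[[k]][3],
               n_rock = 15, n_bird = 6, n_trunk = 6,
               seed = seed + 101L * k)
  })
}

default_observer_models <- function(seed, scene_index) {
  base <- seed + 1000L * scene_index
  labs <- caribou_labels()
  naive_conf <- matrix(c(0.87, 0.04, 0.04,
                         0.08, 0.82, 0.03,
                         0.10, 0.05, 0.70),
                       3, 3, byrow = TRUE, dimnames = list(labs, labs))
  naive_miss <- c(adult = 0.05, calf = 0.07, ghost = 0.15)
  detector_conf <- matrix(c(0.92, 0.03, 0.03,
                            0.06, 0.86, 0.03,
                            0.10, 0.05, 0.40),
                          3, 3, byrow = TRUE, dimnames = list(labs, labs))
  detector_miss <- c(adult = 0.02, calf = 0.05, ghost = 0.45)
  models <- list(expert = observer_model(source_id = "expert",
                                         seed = base + 1L))
  for (i in 1:5) {
    models[[paste0("naive-", i)]] <-
      observer_model(miss = naive_miss, confusion = naive_conf,
                     bbox_jitter_sd_px = 2, source_id = paste0("naive-", i),
                     seed = base + 1L + i)
  }
  models$detector <- observer_model(miss = detector_miss,
                                    confusion = detector_conf,
                                    bbox_jitter_sd_px = 3,
                                    object_fp_rate = c(adult = 8, calf = 2,
                                                       ghost = 2),
                                    confidence = c(8, 2),
                                    source_id = "detector",
                                    seed = base + 7L)
  models
}

#' Build a complete synthetic fixture suite
#'
#' Emits four scenes (two per GSD preset, mirroring a survey with two
#' mosaics per flight altitude), each with its raster (PNG), metadata
#' sidecar (YAML), truth and distractor annotation files, one error-free
#' expert-like source, five error-prone naive-like observers, and one
#' detector-like source with confidences and spurious object annotations.
#' A manifest records every generative parameter; the whole directory is
#' byte-for-byte reproducible from the seed.
#'
#' @param dir output directory (created if needed).
#' @param seed master integer seed; all per-scene and per-observer seeds
#'   are derived from it.
#' @param scene_specs optional list of [scene_spec()]s to use instead of
#'   the four defaults.
#' @param observer_models optional function `(seed, scene_index)` returning
#'   a named list of [observer_model()]s.
#' @param write_rasters write the scene PNGs (disable to emit only
#'   annotation fixtures)?
#' @return the manifest, invisibly (also written as `manifest.yaml`).
#' @export
build_fixture_suite <- function(dir, seed = 1L, scene_specs = NULL,
                                observer_models = default_observer_models,
                                write_rasters = TRUE) {
  seed <- as.integer(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(scene_specs)) scene_specs <- default_scene_specs(seed)
  manifest <- list(seed = seed,
                   package_version = as.character(packageVersion("herdcount")),
                   scenes = list())
  for (k in seq_along(scene_specs)) {
    spec <- scene_specs[[k]]
    sc <- generate_scene(spec)
    id <- spec$mosaic_id
    if (write_rasters) {
      png::writePNG(sc$raster, file.path(dir, paste0(id, ".png")))
    }
    write_mosaic_meta(sc$meta, file.path(dir, paste0(id, "_meta.yaml")))
    write_annotations(sc$truth, file.path(dir, paste0(id, "_truth.csv")))
    write_annotations(sc$distractors,
                      file.path(dir, paste0(id, "_distractors.csv")))
    models <- observer_models(seed, k)
    for (nm in names(models)) {
      sim <- simulate_observer(sc$truth, models[[nm]],
                               distractors = sc$distractors, meta = sc$meta)
      write_annotations(sim, file.path(dir, paste0(id, "_", nm, ".csv")))
    }
    manifest$scenes[[id]] <- list(
      spec = lapply(unclass(spec), function(v) if (is.numeric(v)) as.numeric(v) else v),
      sources = lapply(models, function(m) {
        list(miss = as.numeric(m$miss),
             confusion = as.numeric(m$confusion),
             bbox_jitter_sd_px = m$bbox_jitter_sd_px,
             object_fp_rate = as.numeric(m$object_fp_rate),
             confidence = if (is.null(m$confidence)) "none" else as.numeric(m$confidence),
             seed = m$seed)
      }))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
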