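test_that("plan_grid enumerates tile starts until the mosaic is covered", {
  g1 <- plan_grid(mosaic_meta("m", 1000, 1000, 3.7))
  expect_equal(nrow(g1$tiles), 1)
  expect_equal(as.integer(g1$tiles[1, c("x0", "y0", "x1", "y1")]),
               c(0L, 0L, 1000L, 1000L))

  g2 <- plan_grid(mosaic_meta("m", 2800, 1000, 3.7))
  expect_equal(g2$nx, 3)
  expect_equal(sort(unique(g2$tiles$x0)), c(0, 900, 1800))
  last <- g2$tiles[g2$tiles$i == 2, ]
  expect_equal(c(last$x0, last$x1), c(1800, 2800))

  g3 <- plan_grid(mosaic_meta("m", 950, 950, 3.7))
  expect_equal(nrow(g3$tiles), 1)
  expect_equal(c(g3$tiles$x1, g3$tiles$y1), c(950, 950))

  expect_error(plan_grid(mosaic_meta("m", 500, 500, 3.7), 1000, 1000),
               "overlap")
  expect_error(plan_grid(mosaic_meta("m", 500, 500, 3.7), 1000, 1200),
               "overlap")
})

test_that("tile extents cover the mosaic and cores partition it", {
  set.seed(11)
  for (k in 1:40) {
    w <- sample(300:4000, 1); h <- sample(300:4000, 1)
    ts <- sample(200:1200, 1); ov <- sample(20:(ts - 1), 1)
    g <- plan_grid(mosaic_meta("m", w, h, 3.7), tile_size = ts, overlap = ov)
    t <- g$tiles
    # per-axis extent coverage: starts ascend by stride, last extent ends at dim
    xs <- sort(unique(t$x0))
    expect_equal(xs, (seq_along(xs) - 1) * g$stride)
    expect_true(all(diff(sort(unique(t$x1))) > 0))
    expect_equal(max(t$x1), w)
    expect_equal(max(t$y1), h)
    expect_true(all(t$x1 - t$x0 <= ts & t$y1 - t$y0 <= ts))
    # cores: disjoint, contiguous, and exactly tiling each axis
    xc <- t[t$j == 0, ]
    xc <- xc[order(xc$i), ]
    expect_equal(xc$core_x0[1], 0)
    expect_equal(xc$core_x1[nrow(xc)], w)
    if (nrow(xc) > 1) {
      expect_equal(xc$core_x0[-1], xc$core_x1[-nrow(xc)])
    }
    # cores lie within extents
    expect_true(all(t$core_x0 >= t$x0 & t$core_y0 >= t$y0))
    expect_true(all(t$core_x1 <= pmax(t$x1, t$core_x1)))
  }
})

test_that("tile count never decreases with mosaic width", {
  n_of <- function(w) plan_grid(mosaic_meta("m", w, 500, 3.7))$nx
  widths <- seq(200, 5000, by = 137)
  counts <- vapply(widths, n_of, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("annotations are assigned to the tile owning their top-left corner", {
  g <- plan_grid(mosaic_meta("m", 2800, 1000, 3.7))  # stride 900
  s <- make_set(c("adult", "calf", "ghost"),
                x0 = c(50, 950, 890), y0 = c(50, 10, 10),
                x1 = c(120, 1030, 960), y1 = c(120, 60, 60), mosaic = "m")
  a <- assign_to_tiles(g, s)
  expect_named(a, c("i00_j00", "i01_j00"))
  t00 <- as.data.frame(a$i00_j00)
  # box [50,120) stays local-identical; box [890,960) crosses the core
  # boundary at x=900 but is owned by tile 0 and fits its extent [0,1000)
  expect_equal(t00$x0, c(50, 890))
  expect_false(any(t00$clipped))
  t10 <- as.data.frame(a$i01_j00)
  # floor(950/900) = 1: owner is tile 1, local x = 950 - 900
  expect_equal(c(t10$x0, t10$x1), c(50, 130))
  expect_error(assign_to_tiles(g, make_set("adult", 0, 0, 10, 3000,
                                           mosaic = "m")),
               "outside mosaic")
})

test_that("tile/mosaic translation is an exact inverse pair", {
  g <- plan_grid(mosaic_meta("m", 2800, 1000, 3.7))
  t1 <- g$tiles[g$tiles$i == 1 & g$tiles$j == 0, ]
  expect_equal(tile_to_mosaic(t1, c(50, 10, 130, 60)), c(950, 10, 1030, 60))
  t0 <- g$tiles[g$tiles$i == 0 & g$tiles$j == 0, ]
  expect_equal(tile_to_mosaic(t0, c(5, 6, 7, 8)), c(5, 6, 7, 8))
  set.seed(3)
  for (k in 1:20) {
    b <- c(x0 = sample(0:500, 1), y0 = sample(0:500, 1))
    b <- c(b, b + sample(1:100, 2))[c(1, 2, 3, 4)]
    expect_equal(mosaic_to_tile(t1, tile_to_mosaic(t1, b)), unname(b))
  }
  expect_error(mosaic_to_tile(t1, c(5, 6, 7, 8)), "outside")
})

test_that("merge keeps exactly the owner tile's copy of duplicated detections", {
  g <- plan_grid(mosaic_meta("m", 2800, 1000, 3.7))
  # one animal at mosaic [950,10,1030,60): visible in tiles i=0 (as
  # [950..] local) -- outside extent though -- and i=1; emit from both
  per <- list(
    i00_j00 = make_set("adult", 950, 10, 1000, 60, mosaic = "m"),
    i01_j00 = make_set("adult", 50, 10, 130, 60, mosaic = "m"))
  m <- merge_tile_detections(g, per)
  expect_equal(nrow(m), 1)
  expect_equal(as.integer(m[1, c("x0", "x1")]), c(950L, 1030L))

  # detections wholly in cores are all retained
  per2 <- list(i00_j00 = make_set("adult", 10, 10, 60, 60, mosaic = "m"),
               i01_j00 = make_set("calf", 100, 100, 150, 150, mosaic = "m"))
  m2 <- merge_tile_detections(g, per2)
  expect_equal(nrow(m2), 2)

  # NMS keeps only the most confident of heavily overlapping same-label boxes
  per3 <- list(i00_j00 = make_set(c("adult", "adult"),
                                  x0 = c(100, 102), y0 = c(100, 100),
                                  x1 = c(200, 202), y1 = c(200, 200),
                                  confidence = c(0.8, 0.6), mosaic = "m"))
  m3 <- merge_tile_detections(g, per3, nms_iou = 0.5)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$confidence, 0.8)
  iou_after <- box_iou(c(100, 100, 200, 200), c(102, 100, 202, 200))
  expect_gte(iou_after, 0.5)  # the suppressed pair really was above threshold
})

test_that("assign then merge reconstructs the input set (ownership round trip)", {
  set.seed(99)
  for (k in 1:25) {
    w <- sample(1200:3500, 1); h <- sample(1200:3500, 1)
    g <- plan_grid(mosaic_meta("m", w, h, 3.7))
    n <- 40
    side_x <- sample(10:100, n, replace = TRUE)  # sides <= overlap
    side_y <- sample(10:100, n, replace = TRUE)
    x0 <- sample(0:(w - 101), n, replace = TRUE)
    y0 <- sample(0:(h - 101), n, replace = TRUE)
    s <- make_set(sample(caribou_labels(), n, replace = TRUE),
                  x0, y0, x0 + side_x, y0 + side_y, mosaic = "m")
    m <- merge_tile_detections(g, assign_to_tiles(g, s))
    key <- function(d) {
      d <- as.data.frame(d)
      sort(paste(d$label, d$x0, d$y0, d$x1, d$y1))
    }
    expect_identical(key(m), key(s))
  }
})

test_that("train/test split is deterministic, exhaustive and stratified", {
  g <- plan_grid(mosaic_meta("m", 9100, 900, 3.7), tile_size = 1000,
                 overlap = 100)  # 10 x 1 tiles
  expect_equal(nrow(g$tiles), 10)
  sp1 <- split_tiles(g, fraction = 0.75, seed = 7)
  sp2 <- split_tiles(g, fraction = 0.75, seed = 7)
  expect_identical(sp1, sp2)
  expect_equal(nrow(sp1$train) + nrow(sp1$test), 10)
  expect_length(intersect(sp1$train$key, sp1$test$key), 0)
  # 10 * 0.75 = 7.5 rounds up
  expect_equal(nrow(sp1$train), 8)

  grids <- lapply(1:4, function(k) {
    plan_grid(mosaic_meta(paste0("m", k), 9100, 900, 3.7))
  })
  sp <- split_tiles(grids, fraction = 0.75, seed = 3)
  per <- table(sp$train$mosaic_id)
  expect_true(all(per == 8))

  sp100 <- split_tiles(plan_grid(mosaic_meta("m", 9100, 9100, 3.7)),
                       fraction = 0.75, seed = 1)  # 10 x 10 tiles
  expect_equal(nrow(sp100$train), 75)
  expect_equal(nrow(sp100$test), 25)

  expect_error(split_tiles(g, fraction = 1.2), "fraction")
})
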