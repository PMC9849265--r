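small_spec <- function(seed = 7, ...) {
  scene_spec(mosaic_id = "t", width = 900, height = 700,
             n_adult = 8, n_calf = 3, n_ghost = 3,
             n_rock = 3, n_bird = 2, n_trunk = 2,
             min_separation_px = 50, seed = seed, ...)
}

test_that("scene generation is deterministic and respects requested counts", {
  sc1 <- generate_scene(small_spec())
  sc2 <- generate_scene(small_spec())
  expect_identical(sc1$raster, sc2$raster)
  expect_identical(as.data.frame(sc1$truth), as.data.frame(sc2$truth))
  expect_identical(as.data.frame(sc1$distractors),
                   as.data.frame(sc2$distractors))
  # a different seed gives a different scene
  sc3 <- generate_scene(small_spec(seed = 8))
  expect_false(identical(sc1$raster, sc3$raster))

  tab <- table(sc1$truth$label)
  expect_equal(unname(tab[c("adult", "calf", "ghost")]), c(8, 3, 3),
               ignore_attr = TRUE)
  expect_equal(nrow(sc1$distractors), 7)
  # all boxes in bounds, positive area
  expect_true(all(sc1$truth$x1 <= 900 & sc1$truth$y1 <= 700))
  expect_true(all(sc1$truth$x1 > sc1$truth$x0))
  # raster values are proper gray levels
  expect_true(all(sc1$raster >= 0 & sc1$raster <= 1))

  # empty scene
  blank <- generate_scene(scene_spec(width = 300, height = 300,
                                     n_adult = 0, n_calf = 0, n_ghost = 0,
                                     n_rock = 0, n_bird = 0, n_trunk = 0))
  expect_equal(nrow(blank$truth), 0)
})

test_that("placed objects honor the minimum separation", {
  sc <- generate_scene(small_spec())
  all_boxes <- rbind(as.data.frame(sc$truth)[, c("x0", "y0", "x1", "y1")],
                     as.data.frame(sc$distractors)[, c("x0", "y0", "x1", "y1")])
  cx <- (all_boxes$x0 + all_boxes$x1) / 2
  cy <- (all_boxes$y0 + all_boxes$y1) / 2
  d <- as.matrix(dist(cbind(cx, cy)))
  diag(d) <- Inf
  # centers were separated at placement; the bbox centers of ghosts can
  # drift a little from the placement center through blur asymmetry
  expect_gt(min(d), 50 * 0.8)
})

test_that("infeasible placement raises a capacity error naming achieved counts", {
  expect_error(generate_scene(scene_spec(width = 250, height = 250,
                                         n_adult = 200, min_separation_px = 60)),
               "capacity")
})

test_that("truth boxes are the tight bounding boxes of rendered pixels", {
  sc <- generate_scene(small_spec(), return_masks = TRUE)
  truth_masks <- Filter(function(m) m$bucket == "truth", sc$masks)
  expect_length(truth_masks, nrow(sc$truth))
  for (k in seq_along(truth_masks)) {
    pix <- truth_masks[[k]]$pix
    b <- as.data.frame(sc$truth)[k, ]
    expect_equal(min(pix[, "col"]) - 1, b$x0)
    expect_equal(max(pix[, "col"]), b$x1)
    expect_equal(min(pix[, "row"]) - 1, b$y0)
    expect_equal(max(pix[, "row"]), b$y1)
    # shrinking any side by one pixel drops sprite pixels
    expect_gt(sum(pix[, "col"] == b$x0 + 1), 0)
    expect_gt(sum(pix[, "col"] == b$x1), 0)
    expect_gt(sum(pix[, "row"] == b$y0 + 1), 0)
    expect_gt(sum(pix[, "row"] == b$y1), 0)
  }
})

test_that("ghost sprites have lower contrast than adult sprites", {
  sc <- generate_scene(small_spec())
  bg_level <- median(sc$raster)
  mean_contrast <- function(b) {
    mean(abs(sc$raster[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1] - bg_level))
  }
  d <- as.data.frame(sc$truth)
  adult_c <- sapply(which(d$label == "adult"), function(k) mean_contrast(d[k, ]))
  ghost_c <- sapply(which(d$label == "ghost"), function(k) mean_contrast(d[k, ]))
  expect_lt(mean(ghost_c), mean(adult_c))
})

test_that("observer model validation enforces probability structure", {
  expect_error(observer_model(miss = 1.2), "\\[0, 1\\]")
  labs <- caribou_labels()
  bad <- matrix(0.5, 3, 3, dimnames = list(labs, labs))
  expect_error(observer_model(miss = 0.1, confusion = bad), "sum to 1")
  expect_error(observer_model(object_fp_rate = c(adult = 60, calf = 60,
                                                 ghost = 0)), "100")
  expect_error(observer_model(confidence = c(-1, 2)), "Beta")
  # valid model passes
  ok <- matrix(c(0.8, 0.05, 0.05, 0.05, 0.85, 0, 0.1, 0.1, 0.7),
               3, 3, byrow = TRUE, dimnames = list(labs, labs))
  m <- observer_model(miss = c(adult = 0.1, calf = 0.1, ghost = 0.1),
                      confusion = ok)
  expect_s3_class(m, "observer_model")
})

test_that("a zero-error observer reproduces truth; class-specific misses work", {
  sc <- generate_scene(small_spec())
  sim0 <- simulate_observer(sc$truth, observer_model(seed = 5), meta = sc$meta)
  expect_identical(as.data.frame(sim0)[, 1:5], as.data.frame(sc$truth)[, 1:5])

  ghost_gone <- observer_model(miss = c(adult = 0, calf = 0, ghost = 1),
                               seed = 5)
  simg <- simulate_observer(sc$truth, ghost_gone, meta = sc$meta)
  expect_equal(sum(simg$label == "ghost"), 0)
  expect_equal(sum(simg$label == "adult"), sum(sc$truth$label == "adult"))
  expect_equal(sum(simg$label == "calf"), sum(sc$truth$label == "calf"))

  # simulation is deterministic in the model seed
  om <- observer_model(miss = 0.3, bbox_jitter_sd_px = 2, seed = 11)
  expect_identical(as.data.frame(simulate_observer(sc$truth, om)),
                   as.data.frame(simulate_observer(sc$truth, om)))
})

test_that("planted miss and confusion rates are recovered by the pipeline", {
  # n = 500 planted adults at miss 0.2; over 200 seeds the pipeline recall
  # must sit within 3 binomial standard errors of 0.8
  tr <- grid_truth(500, side = 60, pitch = 100)
  labs <- caribou_labels()
  conf <- matrix(c(0.70, 0.06, 0.04,
                   0.05, 0.70, 0.05,
                   0.05, 0.05, 0.70),
                 3, 3, byrow = TRUE, dimnames = list(labs, labs))
  tr_mixed <- grid_truth(500, labels = c("adult", "calf", "ghost"),
                         side = 60, pitch = 100)
  n_seeds <- 200
  recalls <- numeric(n_seeds)
  adult_as_calf <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    om <- observer_model(miss = 0.2, confusion = conf, bbox_jitter_sd_px = 2,
                         seed = s)
    sim <- simulate_observer(tr_mixed, om)
    m <- match_sets(tr_mixed, sim)
    dc <- derive_counts(m, tr_mixed, sim)
    recalls[s] <- recall(dc$counts["pooled", "tp"], dc$counts["pooled", "fn"])
    # confusion frequency: adults recorded as calves among all adults
    n_adults <- sum(tr_mixed$label == "adult")
    adult_as_calf[s] <- dc$confusion["adult", "calf"] / n_adults
  }
  se3 <- 3 * sqrt(0.8 * 0.2 / (500 * n_seeds))
  expect_lt(abs(mean(recalls) - 0.8), se3)
  p_ac <- conf["adult", "calf"]
  n_adults <- sum(tr_mixed$label == "adult")
  se3_conf <- 3 * sqrt(p_ac * (1 - p_ac) / (n_adults * n_seeds))
  expect_lt(abs(mean(adult_as_calf) - p_ac), se3_conf)
})

test_that("the fixture suite is reproducible byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  specs <- function() list(
    scene_spec(mosaic_id = "a", width = 600, height = 500, gsd_cm = 3.7,
               n_adult = 6, n_calf = 2, n_ghost = 2, n_rock = 2, n_bird = 1,
               n_trunk = 1, min_separation_px = 40, seed = 31),
    scene_spec(mosaic_id = "b", width = 600, height = 500, gsd_cm = 2.4,
               n_adult = 4, n_calf = 2, n_ghost = 1, n_rock = 2, n_bird = 1,
               n_trunk = 1, min_separation_px = 40, seed = 32))
  build_fixture_suite(d1, seed = 9, scene_specs = specs())
  build_fixture_suite(d2, seed = 9, scene_specs = specs())
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  expect_true("manifest.yaml" %in% f1)
  expect_true(all(c("a.png", "a_truth.csv", "a_expert.csv", "a_naive-5.csv",
                    "a_detector.csv", "a_distractors.csv", "a_meta.yaml")
                  %in% f1))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # the expert-like source is error-free: evaluating it gives perfect scores
  truth <- read_annotations(file.path(d1, "a_truth.csv"), source_id = "truth")
  expert <- read_annotations(file.path(d1, "a_expert.csv"),
                             source_id = "expert")
  es <- evaluate_source(truth, expert)
  expect_equal(es$counts["pooled", "tp"], nrow(truth))
  expect_true(all(es$counts["pooled", c("fp", "fn")] == 0))
})
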