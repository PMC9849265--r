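# Independent oracles and fixture builders used across the suite.

# Pixel-set IoU by brute-force rasterization: enumerate the integer pixels
# each half-open box covers and count shared/union pixels.
brute_iou <- function(a, b) {
  pix <- function(box) {
    g <- expand.grid(x = seq(box[1], box[3] - 1), y = seq(box[2], box[4] - 1))
    paste(g$x, g$y)
  }
  pa <- pix(a); pb <- pix(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# Maximum one-to-one matching size by exhaustive recursion (instances are
# kept at <= 6 boxes per side).
brute_max_matching <- function(adj) {
  if (nrow(adj) == 0 || ncol(adj) == 0) return(0L)
  rec <- function(r, used) {
    if (r > nrow(adj)) return(0L)
    best <- rec(r + 1L, used)
    for (p in which(adj[r, ] & !used)) {
      used[p] <- TRUE
      best <- max(best, 1L + rec(r + 1L, used))
      used[p] <- FALSE
    }
    best
  }
  rec(1L, rep(FALSE, ncol(adj)))
}

# Textbook Pearson correlation straight from the covariance formula.
hand_pearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Quick annotation-set builder.
make_set <- function(label, x0, y0, x1, y1, confidence = NA_real_,
                     mosaic = "m1", source = "test") {
  annotation_set(data.frame(label = label, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                            confidence = confidence),
                 mosaic_id = mosaic, source_id = source)
}

# Non-overlapping grid-placed truth set (box side `side`, pitch `pitch`).
grid_truth <- function(n, labels = "adult", side = 60, pitch = 100,
                       per_row = 25, mosaic = "m1") {
  gx <- (seq_len(n) - 1) %% per_row
  gy <- (seq_len(n) - 1) %/% per_row
  make_set(rep(labels, length.out = n), gx * pitch, gy * pitch,
           gx * pitch + side, gy * pitch + side,
           mosaic = mosaic, source = "truth")
}

# Printed worked-example counts shipped with the package.
survey_counts <- function() {
  read.csv(system.file("extdata", "survey_model_counts.csv",
                       package = "herdcount"))
}

survey_misclass <- function() {
  read.csv(system.file("extdata", "survey_misclassifications.csv",
                       package = "herdcount"))
}
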