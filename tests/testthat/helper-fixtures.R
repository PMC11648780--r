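# Shared fixtures and independent oracles for the test suite.

# Small-cell class specs and canvases keep unit tests fast; the acceptance
# benchmark uses the shipped defaults.
tiny_specs <- function() {
  lapply(default_class_specs(), function(s) {
    s$size_range <- s$size_range / 3
    s
  })
}

tiny_dataset <- function(n_per_class, style, seed) {
  counts <- stats::setNames(rep(n_per_class, 6), cell_classes())
  generate_dataset(counts, style, seed, class_specs = tiny_specs(),
                   canvas_side_range = c(96L, 112L))
}

random_image <- function(h = 8, w = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * 3, 0.05, 0.95), c(h, w, 3))
}

# --- independent straight-line oracle for the colour conversion chain ----
# Written directly from the published matrices, independent of the package
# implementation path (per-pixel loops, published inverse rotation).
oracle_rgb2lab <- function(rgb_mat) {
  M <- matrix(c(0.3811, 0.5783, 0.0402,
                0.1967, 0.7244, 0.0782,
                0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
  out <- matrix(0, nrow(rgb_mat), 3)
  for (i in seq_len(nrow(rgb_mat))) {
    lms <- pmax(as.numeric(M %*% rgb_mat[i, ]), 1e-6)
    ll <- log10(lms)
    out[i, ] <- c(sum(ll) / sqrt(3),
                  (ll[1] + ll[2] - 2 * ll[3]) / sqrt(6),
                  (ll[1] - ll[2]) / sqrt(2))
  }
  out
}

oracle_lab2rgb <- function(lab_mat) {
  M <- matrix(c(0.3811, 0.5783, 0.0402,
                0.1967, 0.7244, 0.0782,
                0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
  Minv <- solve(M)
  out <- matrix(0, nrow(lab_mat), 3)
  for (i in seq_len(nrow(lab_mat))) {
    l <- lab_mat[i, 1]; a <- lab_mat[i, 2]; b <- lab_mat[i, 3]
    ll <- c(l / sqrt(3) + a / sqrt(6) + b / sqrt(2),
            l / sqrt(3) + a / sqrt(6) - b / sqrt(2),
            l / sqrt(3) - 2 * a / sqrt(6))
    out[i, ] <- pmin(pmax(as.numeric(Minv %*% 10^ll), 0), 1)
  }
  out
}

# Confusion-matrix-first metrics oracle (direct double-loop counting).
oracle_metrics <- function(pred, truth, classes) {
  k <- length(classes)
  conf <- matrix(0L, k, k, dimnames = list(classes, classes))
  for (i in seq_along(truth))
    conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
  prec <- rec <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    tp <- conf[j, j]
    if (sum(conf[, j]) > 0) prec[j] <- tp / sum(conf[, j])
    if (sum(conf[j, ]) > 0) rec[j] <- tp / sum(conf[j, ])
  }
  list(accuracy = sum(diag(conf)) / length(truth), confusion = conf,
       precision = prec, recall = rec,
       macro_precision = mean(prec, na.rm = TRUE),
       macro_recall = mean(rec, na.rm = TRUE))
}

# Circular mean hue (degrees) of selected pixels via grDevices::rgb2hsv.
mean_hue <- function(pixels_mat) {
  hsv <- grDevices::rgb2hsv(t(pixels_mat), maxColorValue = 1)
  h <- hsv[1, ] * 360
  ang <- atan2(mean(sin(h * pi / 180)), mean(cos(h * pi / 180))) * 180 / pi
  (ang + 360) %% 360
}

circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  min(d, 360 - d)
}

# 16 px inputs make training-path unit tests cheap.
tiny_config <- function(...) classifier_config(input_side = 16L, ...)

tiny_batch <- function(n, side = 16L, seed = 1) {
  set.seed(seed)
  array(runif(side * side * 3 * n), c(side, side, 3, n))
}

# A linearly separable toy image set: class k gets a bright block in a
# class-specific location plus noise. Learnable by the small CNN in a few
# epochs at 16 px.
toy_arrays <- function(n_per_class, k = 6, side = 16L, seed = 1,
                       noise = 0.1) {
  set.seed(seed)
  n <- n_per_class * k
  x <- array(runif(side * side * 3 * n, 0, noise), c(side, side, 3, n))
  labels <- rep(cell_classes()[seq_len(k)], each = n_per_class)
  for (i in seq_len(n)) {
    cls <- (i - 1) %/% n_per_class
    r0 <- 2 + (cls %% 3) * 4; c0 <- 2 + (cls %/% 3) * 6
    x[r0:(r0 + 3), c0:(c0 + 3), (cls %% 3) + 1, i] <-
      x[r0:(r0 + 3), c0:(c0 + 3), (cls %% 3) + 1, i] + 0.8
  }
  list(x = x, labels = labels)
}
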