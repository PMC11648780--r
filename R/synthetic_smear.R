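#' @name synthetic_smear
#' @title Synthetic blood-smear image generator
#'
#' @description
#' Generates labelled single-cell images whose class identity is carried by
#' the same visual cues a morphologist uses — nucleus shape and lobation,
#' granulation colour, and cytoplasm colour — and whose "domain" (the
#' imaging source) is controlled by a style: stain hue rotation, brightness,
#' background tint, optical blur, zoom, and sensor noise. Every output is a
#' pure function of (class spec, style, seed), so the full training /
#' fine-tuning / ablation pipeline can be exercised and regression-tested
#' without any external image data.
NULL

# ---- class specs -----------------------------------------------------------

#' Default cell class specifications
#'
#' The six class specs ship as an editable JSON file
#' (`system.file("extdata", "default_class_specs.json", package =
#' "cytoshift")`). Granule hue bands for basophils (purple) and eosinophils
#' (orange) are disjoint; lymphocytes and erythroblasts are agranular and
#' recognizable by nucleus area fraction and cytoplasm colour; neutrophils
#' carry 3-5 nuclear lobes versus the eosinophil's 2.
#'
#' @param path Optional path to an alternative class-spec JSON file.
#' @return Named list of validated class specs.
#' @export
default_class_specs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_class_specs.json",
                        package = "cytoshift")
  specs <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(specs, function(s) {
    s$cytoplasm_color <- as.numeric(s$cytoplasm_color)
    if (!is.null(s$granule_hue_range) && length(s$granule_hue_range))
      s$granule_hue_range <- as.numeric(s$granule_hue_range)
    else s$granule_hue_range <- NULL
    s$size_range <- as.numeric(s$size_range)
    if (is.null(s$lobe_count)) s$lobe_count <- c(1, 1)
    s$lobe_count <- as.integer(s$lobe_count)
    validate_class_spec(s)
  })
  # purple vs orange granule bands must not overlap
  b <- specs$basophil$granule_hue_range
  e <- specs$eosinophil$granule_hue_range
  if (!is.null(b) && !is.null(e) && b[1] <= e[2] && e[1] <= b[2])
    stop("basophil and eosinophil granule hue ranges overlap", call. = FALSE)
  specs
}

#' Validate a cell class specification
#'
#' @param spec List with fields `class_name`, `nucleus_shape` (`round`,
#'   `multilobed`, `kidney`, or `band`), `nucleus_area_fraction` in (0, 1),
#'   optional `granule_hue_range` (degrees), `granule_density` (expected
#'   granules per pixel^2 of cell area), `cytoplasm_color` (RGB triple),
#'   `size_range` (cell diameter bounds in pixels, min < max), and optional
#'   `lobe_count` (integer pair).
#' @return The spec, invisibly usable, or an error.
#' @export
validate_class_spec <- function(spec) {
  shapes <- c("round", "multilobed", "kidney", "band")
  if (is.null(spec$class_name) || !nzchar(spec$class_name))
    stop("class spec needs a class_name", call. = FALSE)
  if (!spec$nucleus_shape %in% shapes)
    stop("unknown nucleus_shape: ", spec$nucleus_shape, call. = FALSE)
  f <- spec$nucleus_area_fraction
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("nucleus_area_fraction must lie in (0, 1)", call. = FALSE)
  if (!is.null(spec$granule_hue_range)) {
    h <- spec$granule_hue_range
    if (length(h) != 2L || h[1] > h[2])
      stop("granule_hue_range must be an ordered degree interval",
           call. = FALSE)
  }
  if (spec$granule_density < 0)
    stop("granule_density must be >= 0", call. = FALSE)
  if (length(spec$cytoplasm_color) != 3L ||
      any(spec$cytoplasm_color < 0 | spec$cytoplasm_color > 1))
    stop("cytoplasm_color must be an RGB triple in [0, 1]", call. = FALSE)
  s <- spec$size_range
  if (length(s) != 2L || s[1] <= 0 || s[1] >= s[2])
    stop("size_range must satisfy 0 < min < max", call. = FALSE)
  lc <- spec$lobe_count
  if (length(lc) != 2L || lc[1] < 1L || lc[1] > lc[2] || lc[2] > 5L)
    stop("lobe_count must be an integer pair within 1..5", call. = FALSE)
  spec
}

# ---- domain styles ---------------------------------------------------------

#' Construct a domain style
#'
#' A domain style is the synthetic analogue of an imaging source: it fixes
#' the stain hue rotation (degrees), a multiplicative brightness factor, the
#' background tint, an optical Gaussian blur (sigma in pixels at render
#' resolution), the magnification jitter (zoom factor range), and additive
#' sensor noise (standard deviation in 8-bit intensity units). Applying a
#' style is deterministic given the RNG state.
#'
#' @param style_id Identifier recorded in manifests as `dataset_id`.
#' @param stain_hue_shift Hue rotation in degrees.
#' @param brightness_factor Multiplicative brightness, > 0.
#' @param background_color RGB triple in `[0, 1]`.
#' @param blur_sigma Gaussian blur sigma in pixels, >= 0.
#' @param zoom_factor_range Ordered pair of positive zoom factors.
#' @param noise_sd Additive noise SD in 8-bit units, >= 0.
#' @return A validated `domain_style` list.
#' @export
domain_style <- function(style_id = "default",
                         stain_hue_shift = 0,
                         brightness_factor = 1,
                         background_color = c(0.93, 0.91, 0.95),
                         blur_sigma = 0,
                         zoom_factor_range = c(0.95, 1.05),
                         noise_sd = 2) {
  style <- list(style_id = style_id,
                stain_hue_shift = stain_hue_shift,
                brightness_factor = brightness_factor,
                background_color = as.numeric(background_color),
                blur_sigma = blur_sigma,
                zoom_factor_range = as.numeric(zoom_factor_range),
                noise_sd = noise_sd)
  validate_domain_style(style)
}

#' @rdname domain_style
#' @param style A style list to validate.
#' @export
validate_domain_style <- function(style) {
  if (style$brightness_factor <= 0)
    stop("brightness_factor must be > 0", call. = FALSE)
  if (style$blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  if (style$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  z <- style$zoom_factor_range
  if (length(z) != 2L || z[1] <= 0 || z[1] > z[2])
    stop("zoom_factor_range must be ordered and positive", call. = FALSE)
  bg <- style$background_color
  if (length(bg) != 3L || any(bg < 0 | bg > 1))
    stop("background_color must be an RGB triple in [0, 1]", call. = FALSE)
  structure(style, class = "domain_style")
}

#' @rdname domain_style
#' @export
default_domain_style <- function(style_id = "default") domain_style(style_id)

#' Generate a controlled pair of domain styles
#'
#' Returns a base style and a shifted style whose hue rotation, brightness,
#' background tint, blur, zoom, and noise offsets all scale monotonically
#' with `shift_magnitude`. Offset directions are drawn once from `seed`, so
#' the pair is reproducible and `shift_magnitude = 0` returns two identical
#' styles. At full magnitude the shifted style differs by up to 50 degrees
#' of hue, 35% brightness, 0.2 background tint per channel, blur sigma 6
#' (at render resolution), 0.25 zoom, and 20/255 noise SD — the synthetic
#' analogue of changing microscope, camera, and staining protocol at once.
#'
#' @param shift_magnitude Scalar in `[0, 1]`.
#' @param seed Integer seed for the offset directions.
#' @param base Base `domain_style`.
#' @return List with elements `style_a` and `style_b`.
#' @export
make_style_pair <- function(shift_magnitude, seed = 1,
                            base = default_domain_style()) {
  if (!is.numeric(shift_magnitude) || shift_magnitude < 0 ||
      shift_magnitude > 1)
    stop("shift_magnitude must lie in [0, 1]", call. = FALSE)
  m <- shift_magnitude
  dirs <- with_seed(child_seed(seed, 17), {
    sample(c(-1, 1), 6, replace = TRUE) * runif(6, 0.6, 1)
  })
  b <- base
  b$stain_hue_shift <- base$stain_hue_shift + dirs[1] * 50 * m
  b$brightness_factor <- base$brightness_factor * (1 + dirs[2] * 0.35 * m)
  b$background_color <- clamp01(base$background_color + dirs[3:5] * 0.2 * m)
  b$blur_sigma <- base$blur_sigma + 6 * m
  b$zoom_factor_range <- base$zoom_factor_range + dirs[6] * 0.25 * m
  b$noise_sd <- base$noise_sd + 20 * m
  if (m > 0) b$style_id <- sprintf("%s_shift%.2g", base$style_id, m)
  list(style_a = base, style_b = validate_domain_style(b))
}

# ---- low-level drawing -----------------------------------------------------

# Vectorized HSV -> RGB; h in degrees, s and v in [0, 1]. Returns n x 3.
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  for (k in 0:5) {
    sel <- i == k
    if (!any(sel)) next
    rgb <- switch(as.character(k),
                  "0" = cbind(v, t, p), "1" = cbind(q, v, p),
                  "2" = cbind(p, v, t), "3" = cbind(p, q, v),
                  "4" = cbind(t, p, v), "5" = cbind(v, p, q))
    r[sel] <- rgb[sel, 1]; g[sel] <- rgb[sel, 2]; b[sel] <- rgb[sel, 3]
  }
  cbind(r, g, b)
}

# Luminance-preserving hue rotation applied as a 3x3 matrix in RGB.
hue_rotation_matrix <- function(deg) {
  c0 <- cos(deg * pi / 180); s0 <- sin(deg * pi / 180)
  matrix(c(0.213 + c0 * 0.787 - s0 * 0.213,
           0.715 - c0 * 0.715 - s0 * 0.715,
           0.072 - c0 * 0.072 + s0 * 0.928,
           0.213 - c0 * 0.213 + s0 * 0.143,
           0.715 + c0 * 0.285 + s0 * 0.140,
           0.072 - c0 * 0.072 - s0 * 0.283,
           0.213 - c0 * 0.213 - s0 * 0.787,
           0.715 - c0 * 0.715 + s0 * 0.715,
           0.072 + c0 * 0.928 + s0 * 0.072), 3, 3, byrow = TRUE)
}

rotate_hue <- function(img, deg) {
  if (deg == 0) return(img)
  d <- dim(img)
  out <- matrix(img, ncol = 3L) %*% t(hue_rotation_matrix(deg))
  array(out, d)
}

# Alpha-composite an anti-aliased (rotated) ellipse onto img.
# Center (cr, cc) in 1-based pixel coordinates; radii in pixels.
draw_ellipse <- function(img, cr, cc, rr, rc = rr, theta = 0, color,
                         alpha = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  rmax <- max(rr, rc) + 1.5
  r1 <- max(1L, floor(cr - rmax)); r2 <- min(h, ceiling(cr + rmax))
  c1 <- max(1L, floor(cc - rmax)); c2 <- min(w, ceiling(cc + rmax))
  if (r1 > r2 || c1 > c2) return(img)
  ys <- (r1:r2) - cr; xs <- (c1:c2) - cc
  Y <- matrix(ys, length(ys), length(xs))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  u <- (Y * ct + X * st) / rr
  v <- (-Y * st + X * ct) / rc
  d <- sqrt(u^2 + v^2)
  edge <- min(rr, rc)
  a <- clamp01((1 - d) * edge + 0.5) * alpha
  if (all(a == 0)) return(img)
  for (ch in 1:3) {
    block <- img[r1:r2, c1:c2, ch]
    img[r1:r2, c1:c2, ch] <- block * (1 - a) + color[ch] * a
  }
  img
}

# Composite many small anti-aliased discs in one call (granules). Operating
# on flat indices inside a single function keeps the canvas copy count at
# one instead of one per disc.
draw_discs <- function(img, cy, cx, r, colors, alpha) {
  h <- dim(img)[1]; w <- dim(img)[2]
  plane <- h * w
  for (g in seq_along(cy)) {
    rg <- r[g]
    r1 <- max(1L, floor(cy[g] - rg - 1)); r2 <- min(h, ceiling(cy[g] + rg + 1))
    c1 <- max(1L, floor(cx[g] - rg - 1)); c2 <- min(w, ceiling(cx[g] + rg + 1))
    if (r1 > r2 || c1 > c2) next
    ys <- (r1:r2) - cy[g]; xs <- (c1:c2) - cx[g]
    d <- sqrt(outer(ys^2, xs^2, "+"))
    a <- clamp01(rg - d + 0.5) * alpha[g]
    if (all(a == 0)) next
    # flat vector index: a k x 3 index matrix would otherwise be read as
    # per-dimension coordinates into the 3-d array
    idx <- as.vector(outer(r1:r2, (c1 - 1L):(c2 - 1L) * h, "+"))
    av <- as.vector(a)
    for (ch in 1:3) {
      ii <- idx + (ch - 1L) * plane
      img[ii] <- img[ii] * (1 - av) + colors[g, ch] * av
    }
  }
  img
}

# ---- render ----------------------------------------------------------------

.NUCLEUS_COLOR <- c(0.36, 0.18, 0.48)

#' Render one labelled cell image
#'
#' Draws background, cytoplasm (an irregular ellipse), a nucleus built as a
#' union of 1-5 anti-aliased lobes (round, multilobed, kidney with a
#' concave bite, or band), and granules as small anti-aliased discs with
#' hues drawn from the class's granule band; then applies the domain style
#' (hue rotation, brightness, zoom, blur, noise). The canvas side is drawn
#' from `canvas_side_range`, emulating heterogeneous acquisition
#' resolutions; downstream preprocessing (window crop + resize) is expected
#' to normalize geometry.
#'
#' @param class_spec A validated class spec (see [default_class_specs()]).
#' @param style A `domain_style`.
#' @param seed Integer seed; identical `(class_spec, style, seed)` gives a
#'   pixel-identical image.
#' @param canvas_side_range Integer pair of canvas side bounds in pixels.
#' @param keep_unclipped If `TRUE`, the returned object carries the render
#'   buffer before the final `[0, 1]` clip in `$unclipped` (useful to reason
#'   about brightness arithmetic free of saturation).
#' @return A `labeled_image`: list with `pixels` (`H x W x 3` in `[0, 1]`),
#'   `label`, `dataset_id`, and `seed`.
#' @export
render_cell <- function(class_spec, style, seed,
                        canvas_side_range = c(256L, 320L),
                        keep_unclipped = FALSE) {
  class_spec <- validate_class_spec(class_spec)
  style <- validate_domain_style(style)
  if (any(canvas_side_range <= 0))
    stop("canvas_side_range must be positive", call. = FALSE)
  img <- with_seed(seed, {
    side <- if (canvas_side_range[1] == canvas_side_range[2])
      as.integer(canvas_side_range[1])
    else sample(canvas_side_range[1]:canvas_side_range[2], 1L)

    img <- array(rep(style$background_color, each = side * side),
                 dim = c(side, side, 3L))
    # faint background texture so backgrounds are not strictly constant
    img <- img + array(rnorm(side * side, 0, 0.004), dim = dim(img))

    d <- runif(1, class_spec$size_range[1], class_spec$size_range[2])
    rcell <- d / 2
    cr <- side / 2 + runif(1, -0.03, 0.03) * side
    cc <- side / 2 + runif(1, -0.03, 0.03) * side

    # cytoplasm: slightly eccentric rotated ellipse
    ecc <- runif(1, 0.9, 1.1)
    th <- runif(1, 0, pi)
    cyto_col <- clamp01(class_spec$cytoplasm_color + runif(3, -0.03, 0.03))
    img <- draw_ellipse(img, cr, cc, rcell * ecc, rcell / ecc, th, cyto_col)

    # granules, drawn under the nucleus
    if (class_spec$granule_density > 0 &&
        !is.null(class_spec$granule_hue_range)) {
      area <- pi * rcell^2
      n_gr <- rpois(1, class_spec$granule_density * area)
      if (n_gr > 0) {
        rad <- rcell * 0.92 * sqrt(runif(n_gr))
        ang <- runif(n_gr, 0, 2 * pi)
        gy <- cr + rad * cos(ang) * ecc
        gx <- cc + rad * sin(ang) / ecc
        hue <- runif(n_gr, class_spec$granule_hue_range[1],
                     class_spec$granule_hue_range[2])
        cols <- hsv_to_rgb(hue, runif(n_gr, 0.55, 0.85),
                           runif(n_gr, 0.5, 0.8))
        grr <- runif(n_gr, 0.010, 0.020) * d
        gal <- runif(n_gr, 0.7, 1)
        img <- draw_discs(img, gy, gx, grr, cols, gal)
      }
    }

    # nucleus lobes
    frac <- class_spec$nucleus_area_fraction
    rn <- rcell * sqrt(frac)
    ncol_ <- clamp01(.NUCLEUS_COLOR + runif(3, -0.03, 0.03))
    lc <- class_spec$lobe_count
    k <- if (lc[1] == lc[2]) lc[1] else sample(lc[1]:lc[2], 1L)
    shape <- class_spec$nucleus_shape
    if (shape == "round" || (k == 1L && shape == "multilobed")) {
      e2 <- runif(1, 0.92, 1.08)
      img <- draw_ellipse(img, cr, cc, rn * e2, rn / e2,
                          runif(1, 0, pi), ncol_)
    } else if (shape == "kidney") {
      img <- draw_ellipse(img, cr, cc, rn * 1.05, rn * 0.95,
                          runif(1, 0, pi), ncol_)
      bite_ang <- runif(1, 0, 2 * pi)
      img <- draw_ellipse(img, cr + 1.05 * rn * cos(bite_ang),
                          cc + 1.05 * rn * sin(bite_ang), rn * 0.7,
                          color = cyto_col)
    } else if (shape == "band") {
      arc0 <- runif(1, 0, 2 * pi)
      for (j in 0:2) {
        a <- arc0 + j * 0.9
        img <- draw_ellipse(img, cr + 0.55 * rn * cos(a),
                            cc + 0.55 * rn * sin(a), rn * 0.55,
                            color = ncol_)
      }
    } else { # multilobed, k >= 2
      rl <- rn / sqrt(k) * 1.2
      ang0 <- runif(1, 0, 2 * pi)
      for (j in seq_len(k)) {
        a <- ang0 + 2 * pi * (j - 1) / k + runif(1, -0.25, 0.25)
        rdist <- (rn - rl * 0.7) * runif(1, 0.85, 1.1)
        e2 <- runif(1, 0.9, 1.1)
        img <- draw_ellipse(img, cr + rdist * cos(a), cc + rdist * sin(a),
                            rl * e2, rl / e2, runif(1, 0, pi), ncol_)
      }
    }

    # ---- domain style ----
    img <- rotate_hue(img, style$stain_hue_shift)
    img <- img * style$brightness_factor
    z <- runif(1, style$zoom_factor_range[1], style$zoom_factor_range[2])
    img <- zoom_image(img, z)
    if (style$blur_sigma > 0) img <- gaussian_blur(img, style$blur_sigma)
    img <- img + array(rnorm(length(img), 0, style$noise_sd / 255),
                       dim = dim(img))
    img
  })
  out <- list(pixels = clamp01(img), label = class_spec$class_name,
              dataset_id = style$style_id, seed = seed)
  if (keep_unclipped) out$unclipped <- img
  structure(out, class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("labeled_image: %s (%s), %d x %d px\n",
              x$label, x$dataset_id, d[1], d[2]))
  invisible(x)
}

#' Generate a labelled synthetic dataset
#'
#' Renders `n_per_class[label]` cells per class under one domain style. One
#' master seed expands into independent per-image substreams, so the
#' manifest is reproducible and images may be generated in any order.
#'
#' @param n_per_class Named integer vector or list mapping labels to counts
#'   (counts >= 0). Labels must appear in `class_specs`.
#' @param style A `domain_style`.
#' @param seed Master integer seed.
#' @param class_specs Named list of class specs.
#' @param out_dir If given, images are written as PNG files under this
#'   directory and the manifest's `path` column points at them; otherwise
#'   images are kept in memory in the manifest's `image` list column.
#' @param canvas_side_range Passed to [render_cell()].
#' @return A manifest `data.frame` with columns `path`, `label`,
#'   `dataset_id` (and list column `image` for in-memory output).
#' @export
generate_dataset <- function(n_per_class, style, seed,
                             class_specs = default_class_specs(),
                             out_dir = NULL,
                             canvas_side_range = c(256L, 320L)) {
  counts <- unlist(n_per_class)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("n_per_class must be named by label", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  unknown <- setdiff(names(counts), names(class_specs))
  if (length(unknown))
    stop("labels without class spec: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  labels <- rep(names(counts), times = counts)
  n <- length(labels)
  img_seeds <- with_seed(seed, sample.int(2147483646L, max(n, 1L)))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  paths <- rep(NA_character_, n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- render_cell(class_specs[[labels[i]]], style, img_seeds[i],
                        canvas_side_range = canvas_side_range)
    if (!is.null(out_dir)) {
      paths[i] <- file.path(out_dir, sprintf("%s_%s_%04d.png",
                                             style$style_id, labels[i], i))
      png::writePNG(cell$pixels, paths[i])
    } else {
      images[[i]] <- cell$pixels
    }
  }
  manifest <- data.frame(path = paths, label = labels,
                         dataset_id = rep(style$style_id, n),
                         stringsAsFactors = FALSE)
  if (is.null(out_dir)) manifest$image <- I(images)
  manifest
}
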