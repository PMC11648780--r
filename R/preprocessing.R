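#' @name preprocessing
#' @title Geometric preprocessing and training-set augmentation
#'
#' @description
#' Mirrors the acquisition pipeline of heterogeneous single-cell datasets:
#' a fixed window (default 250 px) is cropped around the cell — centred on
#' a bounding box, a binary mask centroid, or the image centre — the
#' training pool is optionally augmented with resolution degradation and
#' random zoom, and images are resized (bilinear) to the network input
#' side. Evaluation images receive crop + colour transfer + resize only.
NULL

#' Crop/resize specification
#'
#' @param window_side Side of the square window cropped around the cell, in
#'   pixels.
#' @param padding_mode `"reflect"` (mirror at borders) or `"constant"`
#'   (zero fill) for out-of-bounds regions.
#' @param network_input_side Side of the square network input, in pixels.
#' @return A `crop_spec` list.
#' @export
crop_spec <- function(window_side = 250L, padding_mode = c("reflect",
                                                           "constant"),
                      network_input_side = 224L) {
  padding_mode <- match.arg(padding_mode)
  if (window_side <= 0 || network_input_side <= 0)
    stop("window_side and network_input_side must be > 0", call. = FALSE)
  structure(list(window_side = as.integer(window_side),
                 padding_mode = padding_mode,
                 network_input_side = as.integer(network_input_side)),
            class = "crop_spec")
}

# Map possibly out-of-range 0-based indices onto 0..n-1 by symmetric
# reflection (half-sample: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  j <- i %% (2L * n)
  j[j < 0] <- j[j < 0] + 2L * n
  ifelse(j < n, j, 2L * n - 1L - j)
}

#' Crop a window around the cell
#'
#' @param image `H x W x 3` RGB array.
#' @param locator `NULL` (use the image centre), a bounding box
#'   `c(x_min, y_min, x_max, y_max)` in 0-based half-open pixel
#'   coordinates, or a binary mask matrix (non-zero = cell) whose centroid
#'   becomes the window centre.
#' @param spec A [crop_spec()].
#' @return A `window_side x window_side x 3` array; out-of-bounds regions
#'   filled per `spec$padding_mode`.
#' @export
center_crop <- function(image, locator = NULL, spec = crop_spec()) {
  stopifnot_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(locator)) {
    cx <- w / 2; cy <- h / 2
  } else if (is.matrix(locator)) {
    fg <- which(locator > 0, arr.ind = TRUE)
    if (nrow(fg) == 0L) stop("empty mask", call. = FALSE)
    cy <- mean(fg[, 1] - 1) + 0.5
    cx <- mean(fg[, 2] - 1) + 0.5
  } else if (is.numeric(locator) && length(locator) == 4L) {
    if (locator[1] < 0 || locator[2] < 0 || locator[3] > w ||
        locator[4] > h || locator[1] >= locator[3] ||
        locator[2] >= locator[4])
      stop("bounding box must be within the image and non-degenerate",
           call. = FALSE)
    cx <- (locator[1] + locator[3]) / 2
    cy <- (locator[2] + locator[4]) / 2
  } else {
    stop("locator must be NULL, a bbox of length 4, or a mask matrix",
         call. = FALSE)
  }
  side <- spec$window_side
  rows0 <- ceiling(cy - side / 2) + 0:(side - 1L)  # 0-based
  cols0 <- ceiling(cx - side / 2) + 0:(side - 1L)
  if (spec$padding_mode == "reflect") {
    out <- image[reflect_index(rows0, h) + 1L,
                 reflect_index(cols0, w) + 1L, , drop = FALSE]
  } else {
    out <- array(0, c(side, side, 3L))
    rok <- rows0 >= 0 & rows0 < h
    cok <- cols0 >= 0 & cols0 < w
    out[which(rok), which(cok), ] <-
      image[rows0[rok] + 1L, cols0[cok] + 1L, , drop = FALSE]
  }
  out
}

# Bilinear resize via EBImage; works on H x W x 3 arrays.
ebi_resize <- function(image, h, w) {
  out <- EBImage::resize(EBImage::Image(image, colormode = "Color"),
                         w = h, h = w, filter = "bilinear")
  array(EBImage::imageData(out), dim = c(h, w, dim(image)[3]))
}

gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  out <- EBImage::gblur(EBImage::Image(image, colormode = "Color"),
                        sigma = sigma)
  array(EBImage::imageData(out), dim = dim(image))
}

# Rescale by factor z about the centre, then crop (z > 1) or reflect-pad
# (z < 1) back to the original size.
zoom_image <- function(image, z, padding_mode = "reflect") {
  if (z == 1) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  nh <- max(1L, round(h * z)); nw <- max(1L, round(w * z))
  res <- ebi_resize(image, nh, nw)
  crop_or_pad(res, h, w, padding_mode)
}

crop_or_pad <- function(image, h, w, padding_mode = "reflect") {
  ih <- dim(image)[1]; iw <- dim(image)[2]
  rows0 <- floor((ih - h) / 2) + 0:(h - 1L)
  cols0 <- floor((iw - w) / 2) + 0:(w - 1L)
  if (padding_mode == "reflect") {
    image[reflect_index(rows0, ih) + 1L, reflect_index(cols0, iw) + 1L, ,
          drop = FALSE]
  } else {
    out <- array(0, c(h, w, dim(image)[3]))
    rok <- rows0 >= 0 & rows0 < ih
    cok <- cols0 >= 0 & cols0 < iw
    out[which(rok), which(cok), ] <-
      image[rows0[rok] + 1L, cols0[cok] + 1L, , drop = FALSE]
    out
  }
}

#' Degrade image resolution
#'
#' Downsamples by an integer factor and upsamples back to the original
#' size (both bilinear), emulating a lower-resolution acquisition while
#' keeping dimensions unchanged.
#'
#' @param image `H x W x 3` array.
#' @param factor Integer >= 1; must not exceed the smaller image dimension.
#' @return Array of the same dimensions.
#' @export
degrade_resolution <- function(image, factor) {
  stopifnot_image(image)
  if (factor < 1 || factor != round(factor))
    stop("factor must be an integer >= 1", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (factor > min(h, w))
    stop("factor exceeds image dimensions", call. = FALSE)
  if (factor == 1) return(image)
  small <- ebi_resize(image, max(1L, floor(h / factor)),
                      max(1L, floor(w / factor)))
  ebi_resize(small, h, w)
}

#' Random zoom augmentation
#'
#' Samples a zoom factor uniformly from `zoom_range`, rescales about the
#' centre, and crops or reflect-pads back to the original size.
#'
#' @param image `H x W x 3` array.
#' @param zoom_range Pair `(min, max)` with `0 < min <= max`.
#' @param seed Integer seed; same seed, same output. `NULL` uses the
#'   current RNG stream.
#' @return Array of the same dimensions.
#' @export
random_zoom <- function(image, zoom_range = c(0.8, 1.2), seed = NULL) {
  stopifnot_image(image)
  if (length(zoom_range) != 2L || zoom_range[1] <= 0 ||
      zoom_range[1] > zoom_range[2])
    stop("zoom_range must satisfy 0 < min <= max", call. = FALSE)
  z <- with_seed(seed, runif(1, zoom_range[1], zoom_range[2]))
  zoom_image(image, z)
}

#' Resize to the network input size
#'
#' @param image `H x W x 3` array.
#' @param spec A [crop_spec()]; output side is `spec$network_input_side`.
#' @return Bilinear-resized square array.
#' @export
resize_to_input <- function(image, spec = crop_spec()) {
  stopifnot_image(image)
  s <- spec$network_input_side
  if (all(dim(image)[1:2] == s)) return(image)
  ebi_resize(image, s, s)
}

#' Full preprocessing of one image
#'
#' Applies the pipeline crop -> colour transfer -> (degrade -> zoom, if
#' augmenting) -> resize. Colour transfer precedes the geometric jitter so
#' the reference statistics stay meaningful; augmentation is meant for
#' training-pool images only.
#'
#' @param image `H x W x 3` array.
#' @param locator Passed to [center_crop()].
#' @param spec A [crop_spec()].
#' @param color_ref Optional `color_stats` reference for
#'   [transfer_color()]; `NULL` skips colour standardization.
#' @param augment Apply training augmentations?
#' @param degrade_choices Integer factors sampled for resolution
#'   degradation.
#' @param zoom_range Zoom factor range for [random_zoom()].
#' @param seed Optional seed for the augmentation draws.
#' @return `network_input_side` square RGB array.
#' @export
preprocess_image <- function(image, locator = NULL, spec = crop_spec(),
                             color_ref = NULL, augment = FALSE,
                             degrade_choices = c(1L, 2L, 3L),
                             zoom_range = c(0.8, 1.2), seed = NULL) {
  out <- center_crop(image, locator, spec)
  if (!is.null(color_ref)) out <- transfer_color(out, color_ref)
  if (augment) {
    out <- with_seed(seed, {
      f <- degrade_choices[sample.int(length(degrade_choices), 1L)]
      x <- degrade_resolution(out, f)
      random_zoom(x, zoom_range)
    })
  }
  resize_to_input(out, spec)
}

#' Preprocess every image of a manifest into a batch array
#'
#' @param manifest Manifest `data.frame` (see [load_manifest()]); in-memory
#'   `image` list columns are used directly, otherwise images are read from
#'   `path`.
#' @param spec A [crop_spec()].
#' @param color_ref Optional `color_stats` reference.
#' @param augment Apply training augmentations (per-image seeded
#'   substreams derived from `seed`)?
#' @param seed Master seed for augmentation draws.
#' @inheritParams preprocess_image
#' @return List with `x` (`side x side x 3 x N` array), `labels`
#'   (character), and `ids` (row identifiers).
#' @export
preprocess_manifest <- function(manifest, spec = crop_spec(),
                                color_ref = NULL, augment = FALSE,
                                seed = 1L, degrade_choices = c(1L, 2L, 3L),
                                zoom_range = c(0.8, 1.2)) {
  n <- nrow(manifest)
  side <- spec$network_input_side
  x <- array(0, c(side, side, 3L, n))
  seeds <- with_seed(child_seed(seed, 5), sample.int(2147483646L,
                                                     max(n, 1L)))
  for (i in seq_len(n)) {
    img <- manifest_image(manifest, i)
    x[, , , i] <- preprocess_image(img, locator = manifest_locator(manifest,
                                                                   i),
                                   spec = spec, color_ref = color_ref,
                                   augment = augment,
                                   degrade_choices = degrade_choices,
                                   zoom_range = zoom_range,
                                   seed = if (augment) seeds[i] else NULL)
  }
  list(x = x, labels = manifest$label, ids = manifest_ids(manifest))
}
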