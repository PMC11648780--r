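#' @name color_space
#' @title Colour standardization in the decorrelated l-alpha-beta space
#'
#' @description
#' Blood smear images acquired in different laboratories differ in stain
#' palette, illumination, and white balance. The package standardizes colour
#' by matching per-channel first and second moments in the l-alpha-beta
#' space of Reinhard et al.: a linear RGB-to-LMS cone-response map, a
#' base-10 logarithm, and a decorrelating rotation into a luminance channel
#' (l) and two opponent chroma channels (alpha: yellow-blue, beta:
#' red-green). Because the channels are close to statistically independent
#' for natural images, transferring each channel's mean and standard
#' deviation to a reference moves an image into the reference "style"
#' without distorting structure.
NULL

# Forward matrices as published by the Reinhard transfer method. The inverse
# maps are computed numerically from the forward ones so that the round trip
# is exact to floating-point precision (the published 4-decimal inverse of
# the RGB->LMS map is only accurate to ~1e-4).
.reinhard <- local({
  rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                      0.1967, 0.7244, 0.0782,
                      0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
  rot <- matrix(c(1, 1, 1,
                  1, 1, -2,
                  1, -1, 0), 3, 3, byrow = TRUE)
  log2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*% rot
  list(rgb2lms = rgb2lms, lms2rgb = solve(rgb2lms),
       log2lab = log2lab, lab2log = solve(log2lab))
})

# LMS values are floored before the logarithm so black pixels stay finite.
.LMS_FLOOR <- 1e-6
# Source-channel standard deviations below this are treated as zero and the
# scaling term suppressed (mean shift retained).
.SIGMA_FLOOR <- 1e-8

# Accept an H x W x 3 array or an N x 3 matrix; return list(pix = 3 x N,
# restore = function(3 x N) -> original shape).
.as_pixel_matrix <- function(x, what = "image") {
  if (is.matrix(x) && ncol(x) == 3L) {
    list(pix = t(x), restore = function(p) t(p))
  } else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L) {
    d <- dim(x)
    list(pix = t(matrix(x, ncol = 3L)),
         restore = function(p) array(t(p), dim = d))
  } else {
    stop(what, " must be an H x W x 3 array or an N x 3 matrix",
         call. = FALSE)
  }
}

#' Convert RGB pixels to l-alpha-beta
#'
#' @param pixels An `H x W x 3` array or `N x 3` matrix of RGB values in
#'   `[0, 1]`.
#' @return Object of the same shape holding l-alpha-beta values. Luminance
#'   is carried in channel 1; channels 2 and 3 are the yellow-blue and
#'   red-green opponent axes and are approximately 0 for achromatic pixels.
#' @details LMS cone responses are floored at `1e-6` before the base-10
#'   logarithm so that black pixels map to finite values.
#' @seealso [lab_to_rgb()], [transfer_color()]
#' @export
#' @examples
#' lab <- rgb_to_lab(array(0.5, c(2, 2, 3)))
#' max(abs(lab[, , 2:3]))  # chroma of mid-gray vanishes
rgb_to_lab <- function(pixels) {
  m <- .as_pixel_matrix(pixels, "pixels")
  if (!all(is.finite(m$pix)))
    stop("pixels contain non-finite values", call. = FALSE)
  lms <- .reinhard$rgb2lms %*% m$pix
  lms[lms < .LMS_FLOOR] <- .LMS_FLOOR
  m$restore(.reinhard$log2lab %*% log10(lms))
}

#' Convert l-alpha-beta values back to RGB
#'
#' @param lab An `H x W x 3` array or `N x 3` matrix of l-alpha-beta values.
#' @return RGB values clipped to `[0, 1]`, same shape as the input. Within
#'   gamut this is the exact inverse of [rgb_to_lab()].
#' @export
lab_to_rgb <- function(lab) {
  m <- .as_pixel_matrix(lab, "lab")
  if (!all(is.finite(m$pix)))
    stop("lab values contain non-finite values", call. = FALSE)
  lms <- 10^(.reinhard$lab2log %*% m$pix)
  m$restore(clamp01(.reinhard$lms2rgb %*% lms))
}

# Unclipped inverse, used to detect gamut clipping.
.lab_to_rgb_raw <- function(labmat3xN) {
  .reinhard$lms2rgb %*% 10^(.reinhard$lab2log %*% labmat3xN)
}

#' Pooled colour statistics of an image pool
#'
#' Computes the per-channel mean and (population) standard deviation in
#' l-alpha-beta over all pixels of one or more RGB images. The resulting
#' `color_stats` object is the unit of the style transfer: a reference style
#' is nothing more than the pooled statistics of a reference image pool.
#'
#' @param images A single RGB image (`H x W x 3` array), an `N x 3` pixel
#'   matrix, or a list of such objects. All pixels are pooled.
#' @return A `color_stats` object: list with `mu` and `sigma` (3-vectors in
#'   l-alpha-beta order), `n_pixels`, and `space` (`"lab_reinhard"`).
#' @seealso [transfer_color()], [write_color_stats()]
#' @export
compute_color_stats <- function(images) {
  if (!is.list(images)) images <- list(images)
  if (length(images) == 0L) stop("empty image pool", call. = FALSE)
  # stream over images, accumulating channel moments, so arbitrarily large
  # pools use bounded memory
  s1 <- s2 <- c(0, 0, 0); n <- 0
  for (im in images) {
    pix <- .as_pixel_matrix(im, "image")$pix
    if (ncol(pix) < 1L) next
    lab <- .reinhard$rgb2lms %*% pix
    lab[lab < .LMS_FLOOR] <- .LMS_FLOOR
    lab <- .reinhard$log2lab %*% log10(lab)
    s1 <- s1 + rowSums(lab)
    s2 <- s2 + rowSums(lab^2)
    n <- n + ncol(lab)
  }
  if (n < 1L) stop("empty image pool", call. = FALSE)
  mu <- s1 / n
  structure(list(mu = as.numeric(mu),
                 sigma = as.numeric(sqrt(pmax(s2 / n - mu^2, 0))),
                 n_pixels = n, space = "lab_reinhard"),
            class = "color_stats")
}

#' Reference colour statistics of a manifest
#'
#' Streams over the manifest, cropping each image and accumulating pooled
#' l-alpha-beta channel moments, so large pools use bounded memory.
#'
#' @param manifest Manifest data frame.
#' @param crop A [crop_spec()] applied before pooling.
#' @return A `color_stats` object.
#' @export
manifest_color_stats <- function(manifest, crop = crop_spec()) {
  s1 <- s2 <- c(0, 0, 0); n <- 0
  for (i in seq_len(nrow(manifest))) {
    img <- center_crop(manifest_image(manifest, i),
                       manifest_locator(manifest, i), crop)
    st <- compute_color_stats(img)
    s1 <- s1 + st$mu * st$n_pixels
    s2 <- s2 + (st$sigma^2 + st$mu^2) * st$n_pixels
    n <- n + st$n_pixels
  }
  if (n < 1L) stop("empty manifest", call. = FALSE)
  mu <- s1 / n
  color_stats(mu, sqrt(pmax(s2 / n - mu^2, 0)), n)
}

#' @export
print.color_stats <- function(x, ...) {
  cat("Colour statistics (", x$space, "), ", x$n_pixels, " pixels\n",
      sep = "")
  cat(sprintf("  mu    = (%.4f, %.4f, %.4f)\n", x$mu[1], x$mu[2], x$mu[3]))
  cat(sprintf("  sigma = (%.4f, %.4f, %.4f)\n",
              x$sigma[1], x$sigma[2], x$sigma[3]))
  invisible(x)
}

#' Construct colour statistics from known values
#'
#' @param mu,sigma Numeric 3-vectors (l-alpha-beta order); `sigma` must be
#'   non-negative.
#' @param n_pixels Number of pixels the statistics were computed from.
#' @return A `color_stats` object.
#' @export
color_stats <- function(mu, sigma, n_pixels = 1L) {
  mu <- as.numeric(mu); sigma <- as.numeric(sigma)
  if (length(mu) != 3L || length(sigma) != 3L)
    stop("mu and sigma must be length-3", call. = FALSE)
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) || any(sigma < 0))
    stop("sigma must be finite and non-negative", call. = FALSE)
  if (n_pixels < 1) stop("n_pixels must be >= 1", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, n_pixels = as.integer(n_pixels),
                 space = "lab_reinhard"), class = "color_stats")
}

#' Write / read colour statistics as JSON
#'
#' The JSON schema is `{"space": "lab_reinhard", "mu": [l, a, b],
#' "sigma": [l, a, b], "n_pixels": N}` and round-trips losslessly.
#'
#' @param stats A `color_stats` object.
#' @param path File path.
#' @return `write_color_stats` returns `path` invisibly; `read_color_stats`
#'   returns a `color_stats` object.
#' @export
write_color_stats <- function(stats, path) {
  stopifnot(inherits(stats, "color_stats"))
  jsonlite::write_json(list(space = stats$space, mu = stats$mu,
                            sigma = stats$sigma, n_pixels = stats$n_pixels),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_color_stats
#' @export
read_color_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$space, "lab_reinhard"))
    stop("unsupported colour space tag: ", x$space, call. = FALSE)
  color_stats(x$mu, x$sigma, x$n_pixels)
}

#' Transfer an image to a reference colour style
#'
#' Matches the image's per-channel l-alpha-beta mean and standard deviation
#' to a reference: `x' = (x - mu_src) * sigma_ref / sigma_src + mu_ref`
#' applied channel-wise, followed by the inverse conversion to RGB. Source
#' statistics are computed from the image itself; source channels with
#' (near-)zero variance keep only the mean shift, so a constant-colour image
#' maps to the constant colour whose l-alpha-beta value is `ref$mu`.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param ref A `color_stats` reference (see [compute_color_stats()]).
#' @param as_lab If `TRUE`, return the moment-matched l-alpha-beta array
#'   (before inverse conversion and gamut clipping) instead of RGB; useful
#'   for verifying moment matching free of quantization effects.
#' @return RGB array in `[0, 1]` (or an l-alpha-beta array when
#'   `as_lab = TRUE`). The attribute `clipped_fraction` reports the fraction
#'   of pixels that fell outside the RGB gamut and were clipped.
#' @export
transfer_color <- function(image, ref, as_lab = FALSE) {
  stopifnot(inherits(ref, "color_stats"))
  if (any(!is.finite(ref$sigma))) stop("reference sigma must be finite",
                                       call. = FALSE)
  m <- .as_pixel_matrix(image, "image")
  lab <- .as_pixel_matrix(rgb_to_lab(image), "image")$pix
  mu_src <- rowMeans(lab)
  sd_src <- sqrt(rowMeans((lab - mu_src)^2))
  sd_src[sd_src < .SIGMA_FLOOR] <- 1
  matched <- (lab - mu_src) * (ref$sigma / sd_src) + ref$mu
  if (as_lab) return(m$restore(matched))
  raw <- .lab_to_rgb_raw(matched)
  clipped <- colSums(raw < 0 | raw > 1) > 0
  out <- m$restore(clamp01(raw))
  attr(out, "clipped_fraction") <- mean(clipped)
  out
}
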