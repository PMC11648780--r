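# Window cropping, augmentations, and resizing.

test_that("center_crop window arithmetic matches direct indexing", {
  set.seed(1)
  img <- array(runif(400 * 400 * 3), c(400, 400, 3))
  # bbox centred at (200, 200) -> rows/cols 75..324 (0-based)
  out <- center_crop(img, c(150, 150, 250, 250), crop_spec())
  expect_identical(out, img[76:325, 76:325, ])

  # locator = NULL on an exactly window-sized image is the identity
  sq <- array(runif(250 * 250 * 3), c(250, 250, 3))
  expect_identical(center_crop(sq, NULL, crop_spec()), sq)
})

test_that("mask centroids centre the window and padding fills borders", {
  img <- array(runif(60 * 60 * 3), c(60, 60, 3))
  mask <- matrix(0L, 60, 60)
  mask[31, 41] <- 1L  # 0-based foreground pixel (30, 40)
  spec <- crop_spec(window_side = 20L)
  out <- center_crop(img, mask, spec)
  # centroid of a single pixel (30, 40) + .5 -> window rows 21..40, cols
  # 31..50 (0-based); all in range, so the block must match exactly
  expect_identical(out, img[22:41, 32:51, ])

  # mask centroid = mean of foreground coordinates
  mask2 <- matrix(0L, 60, 60)
  mask2[11, 11] <- 1L; mask2[31, 51] <- 1L  # centroid (20, 30) 0-based
  out2 <- center_crop(img, mask2, spec)
  expect_identical(out2, img[12:31, 22:41, ])

  expect_error(center_crop(img, matrix(0L, 60, 60), spec), "empty mask")

  # constant padding fills out-of-bounds with zeros
  corner <- matrix(0L, 60, 60); corner[1, 1] <- 1L
  outc <- center_crop(img, corner, crop_spec(window_side = 20L,
                                             padding_mode = "constant"))
  expect_equal(outc[1:5, 1:5, ], array(0, c(5, 5, 3)))
  # reflect padding mirrors image content instead
  outr <- center_crop(img, corner, crop_spec(window_side = 20L))
  expect_false(any(outr == 0))
})

test_that("resolution degradation reduces detail but keeps dimensions", {
  img <- array(0, c(32, 32, 3))
  img[, , ] <- (row(matrix(0, 32, 32)) + col(matrix(0, 32, 32))) %% 2
  expect_identical(degrade_resolution(img, 1), img)
  out <- degrade_resolution(img, 2)
  expect_equal(dim(out), dim(img))
  expect_lt(var(as.numeric(out)), var(as.numeric(img)))

  big <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_equal(dim(degrade_resolution(big, 4)), c(224, 224, 3))
  expect_error(degrade_resolution(img, 100), "exceeds")
  expect_error(degrade_resolution(img, 1.5), "integer")
})

test_that("random zoom is seeded and scales structures", {
  img <- random_image(40, 40, seed = 2)
  expect_identical(random_zoom(img, c(1, 1), seed = 1), img)
  expect_identical(random_zoom(img, c(0.8, 1.2), seed = 3),
                   random_zoom(img, c(0.8, 1.2), seed = 3))
  expect_error(random_zoom(img, c(0, 1)), "zoom_range")

  # a centred bright disc doubles in radius under zoom (2, 2)
  disc <- array(0, c(101, 101, 3))
  for (ch in 1:3)
    disc[, , ch] <- (outer((1:101) - 51, (1:101) - 51,
                           function(y, x) sqrt(x^2 + y^2)) <= 10) * 1
  zoomed <- random_zoom(disc, c(2, 2), seed = 1)
  radius <- function(im) sum(im[51, , 1] > 0.5) / 2
  expect_equal(radius(zoomed), 2 * radius(disc), tolerance = 0.1)
})

test_that("resize_to_input hits exact dimensions and preserves constants", {
  img <- random_image(250, 250)
  out <- resize_to_input(img, crop_spec())
  expect_equal(dim(out), c(224, 224, 3))

  same <- random_image(224, 224)
  expect_identical(resize_to_input(same, crop_spec()), same)

  const <- array(0.42, c(100, 100, 3))
  expect_equal(resize_to_input(const, crop_spec(network_input_side = 64L)),
               array(0.42, c(64, 64, 3)), tolerance = 1e-12)
})

test_that("manifest preprocessing stacks images deterministically", {
  m <- tiny_dataset(2, default_domain_style(), seed = 6)
  spec <- crop_spec(window_side = 96L, network_input_side = 32L)
  p1 <- preprocess_manifest(m, spec, augment = TRUE, seed = 9)
  p2 <- preprocess_manifest(m, spec, augment = TRUE, seed = 9)
  expect_identical(p1$x, p2$x)
  expect_equal(dim(p1$x), c(32, 32, 3, nrow(m)))
  expect_equal(p1$labels, m$label)
  p3 <- preprocess_manifest(m, spec, augment = TRUE, seed = 10)
  expect_false(identical(p1$x, p3$x))
  # evaluation path applies no augmentation and needs no seed
  e1 <- preprocess_manifest(m, spec)
  e2 <- preprocess_manifest(m, spec)
  expect_identical(e1$x, e2$x)
})
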