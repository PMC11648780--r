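# Synthetic smear generator: determinism, class-distinguishing features,
# style arithmetic, and separability.

test_that("rendering is a pure function of (spec, style, seed)", {
  specs <- tiny_specs()
  style <- default_domain_style()
  a <- render_cell(specs$monocyte, style, seed = 7,
                   canvas_side_range = c(96L, 112L))
  b <- render_cell(specs$monocyte, style, seed = 7,
                   canvas_side_range = c(96L, 112L))
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$label, "monocyte")
  expect_identical(a$dataset_id, style$style_id)

  c2 <- render_cell(specs$monocyte, style, seed = 8,
                    canvas_side_range = c(96L, 112L))
  expect_false(identical(a$pixels, c2$pixels))

  bad <- specs$monocyte
  bad$size_range <- c(0, 0)
  expect_error(render_cell(bad, style, seed = 1), "size_range")
})

test_that("eosinophil and basophil granules live in distant hue bands", {
  specs <- tiny_specs()
  # clean style: no blur/noise/zoom so granule pixels stay pure
  style <- domain_style(blur_sigma = 0, noise_sd = 0,
                        zoom_factor_range = c(1, 1))
  grab_granule_hue <- function(cls) {
    spec <- specs[[cls]]
    img <- render_cell(spec, style, seed = 99,
                       canvas_side_range = c(112L, 112L))$pixels
    px <- matrix(img, ncol = 3)
    # independent granule segmentation: pixels far from background,
    # cytoplasm, and nucleus tones
    dist_to <- function(col) sqrt(rowSums(sweep(px, 2, col)^2))
    sel <- dist_to(style$background_color) > 0.15 &
      dist_to(spec$cytoplasm_color) > 0.15 &
      dist_to(c(0.36, 0.18, 0.48)) > 0.15
    expect_gt(sum(sel), 20)
    mean_hue(px[sel, , drop = FALSE])
  }
  h_eos <- grab_granule_hue("eosinophil")
  h_bas <- grab_granule_hue("basophil")
  expect_gte(circ_diff(h_eos, h_bas), 30)
})

test_that("brightness scales mean intensity before clipping", {
  specs <- tiny_specs()
  base <- domain_style(blur_sigma = 0, noise_sd = 0,
                       zoom_factor_range = c(1, 1), brightness_factor = 1)
  bright <- base
  bright$brightness_factor <- 1.4
  a <- render_cell(specs$lymphocyte, base, seed = 21,
                   canvas_side_range = c(96L, 96L), keep_unclipped = TRUE)
  b <- render_cell(specs$lymphocyte, bright, seed = 21,
                   canvas_side_range = c(96L, 96L), keep_unclipped = TRUE)
  for (ch in 1:3) {
    ratio <- mean(b$unclipped[, , ch]) / mean(a$unclipped[, , ch])
    expect_equal(ratio, 1.4, tolerance = 0.01)
  }
})

test_that("generate_dataset counts, determinism, and zero-count classes", {
  style <- default_domain_style("styX")
  counts <- c(basophil = 3, eosinophil = 0, erythroblast = 2,
              lymphocyte = 2, monocyte = 1, neutrophil = 2)
  m <- generate_dataset(counts, style, seed = 4,
                        class_specs = tiny_specs(),
                        canvas_side_range = c(96L, 104L))
  expect_equal(nrow(m), sum(counts))
  expect_false("eosinophil" %in% m$label)
  expect_equal(as.numeric(table(m$label)[c("basophil", "erythroblast")]),
               c(3, 2))
  expect_true(all(m$dataset_id == "styX"))

  m2 <- generate_dataset(counts, style, seed = 5,
                         class_specs = tiny_specs(),
                         canvas_side_range = c(96L, 104L))
  expect_equal(table(m2$label), table(m$label))
  expect_false(identical(m$image[[1]], m2$image[[1]]))

  expect_error(generate_dataset(c(basophil = -1), style, 1), ">= 0")
  expect_error(generate_dataset(c(myeloblast = 1), style, 1),
               "without class spec")
})

test_that("dataset generation writes PNGs and a loadable manifest", {
  dir <- withr::local_tempdir()
  style <- default_domain_style("disk")
  m <- generate_dataset(c(lymphocyte = 2, monocyte = 1), style, seed = 2,
                        class_specs = tiny_specs(), out_dir = dir,
                        canvas_side_range = c(96L, 96L))
  expect_true(all(file.exists(m$path)))
  csv <- file.path(dir, "manifest.csv")
  save_manifest(m, csv)
  back <- load_manifest(csv)
  expect_equal(back$label, m$label)
  img <- load_image(m$path[1])
  expect_equal(dim(img), c(96L, 96L, 3L))
})

test_that("style pairs scale monotonically with the shift magnitude", {
  zero <- make_style_pair(0, seed = 9)
  expect_identical(zero$style_a, zero$style_b)

  p1 <- make_style_pair(0.5, seed = 9)
  p2 <- make_style_pair(0.5, seed = 9)
  expect_identical(p1$style_b, p2$style_b)

  expect_error(make_style_pair(1.2, seed = 1), "\\[0, 1\\]")

  gap <- function(m) {
    pair <- make_style_pair(m, seed = 9)
    a <- tiny_dataset(2, pair$style_a, seed = 31)
    b <- tiny_dataset(2, pair$style_b, seed = 32)
    mu <- function(x) compute_color_stats(x$image)$mu
    sqrt(sum((mu(a) - mu(b))^2))
  }
  expect_gt(gap(1), gap(0.3))
})

test_that("classes are separable by a nearest-centroid pixel-mean rule", {
  style <- default_domain_style()
  m <- tiny_dataset(8, style, seed = 77)
  feats <- t(vapply(m$image, function(im) colMeans(matrix(im, ncol = 3)),
                    numeric(3)))
  train <- unlist(lapply(split(seq_len(nrow(m)), m$label), head, 5))
  test <- setdiff(seq_len(nrow(m)), train)
  cents <- do.call(rbind, lapply(split(as.data.frame(feats[train, ]),
                                       m$label[train]), colMeans))
  pred <- rownames(cents)[apply(feats[test, ], 1, function(f)
    which.min(colSums((t(cents) - f)^2)))]
  expect_gt(mean(pred == m$label[test]), 1 / 3)  # chance is 1/6
})
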