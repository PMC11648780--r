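# Metrics, bootstrap intervals, PR curves, embeddings, error analysis.

test_that("metric formulas on constructed cases", {
  cls <- cell_classes()
  truth <- rep(cls[1], 10)
  pred <- c(rep(cls[1], 8), cls[2], cls[3])
  rep1 <- suppressWarnings(compute_metrics(pred, truth, cls))
  expect_equal(rep1$accuracy, 0.8)
  expect_equal(rep1$n, 10)
  expect_equal(sum(rep1$confusion), 10)

  # class with TP = 3, FP = 1, FN = 2
  truth2 <- c(rep("basophil", 5), "monocyte")
  pred2 <- c(rep("basophil", 3), "monocyte", "monocyte", "basophil")
  rep2 <- suppressWarnings(compute_metrics(pred2, truth2, cls))
  expect_equal(rep2$per_class$precision[1], 3 / 4)
  expect_equal(rep2$per_class$recall[1], 3 / 5)

  expect_error(compute_metrics(pred, truth[-1], cls), "equal length")
  expect_error(compute_metrics(c(pred, "blast"), c(truth, "blast"), cls),
               "outside class_order")
})

test_that("report equals the confusion-matrix oracle on random instances", {
  set.seed(11)
  cls <- cell_classes()
  truth <- sample(cls, 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.6, truth, sample(cls, 500, replace = TRUE))
  got <- suppressWarnings(compute_metrics(pred, truth, cls))
  want <- oracle_metrics(pred, truth, cls)
  expect_identical(got$accuracy, want$accuracy)
  expect_equal(unclass(got$confusion), unclass(want$confusion),
               ignore_attr = TRUE)
  expect_equal(got$per_class$precision, want$precision)
  expect_equal(got$per_class$recall, want$recall)
  expect_equal(got$macro_precision, want$macro_precision)
  expect_equal(got$macro_recall, want$macro_recall)
})

test_that("undefined precision/recall is flagged and excluded", {
  cls <- cell_classes()
  truth <- rep("basophil", 4)
  pred <- rep("basophil", 4)  # other classes have no support/predictions
  expect_warning(rep1 <- compute_metrics(pred, truth, cls), "undefined")
  expect_true(is.na(rep1$per_class$precision[2]))
  expect_equal(rep1$macro_precision, 1)
})

test_that("bootstrap interval contracts and shrinkage rate", {
  truth <- rep("basophil", 20)
  ci <- bootstrap_ci(truth, truth, n_boot = 50, seed = 1)
  expect_equal(as.numeric(ci), c(1, 1))

  one <- bootstrap_ci("basophil", "eosinophil", n_boot = 20, seed = 1)
  expect_equal(as.numeric(one), c(0, 0))

  expect_identical(bootstrap_ci(c("a", "b"), c("a", "a"), seed = 3),
                   bootstrap_ci(c("a", "b"), c("a", "a"), seed = 3))
  expect_error(bootstrap_ci("a", "a", level = 1.2), "level")

  width <- function(n) {
    set.seed(n)
    truth <- sample(cell_classes(), n, TRUE)
    pred <- ifelse(runif(n) < 0.8, truth, "basophil")
    ci <- bootstrap_ci(pred, truth, n_boot = 500, seed = 5)
    ci[2] - ci[1]
  }
  w <- vapply(c(100, 400, 1600), width, numeric(1))
  # quadrupling n should roughly halve the width
  expect_gt(w[1] / w[2], 1.4); expect_lt(w[1] / w[2], 2.9)
  expect_gt(w[2] / w[3], 1.4); expect_lt(w[2] / w[3], 2.9)
})

test_that("PR curves match hand enumeration and edge cases", {
  cls2 <- c("basophil", "eosinophil")
  # perfectly separating scores -> averaged AUC = 1
  truth <- c("basophil", "basophil", "eosinophil", "eosinophil")
  probs <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  perfect <- pr_curve(probs, truth, cls2)
  expect_equal(perfect$auc, 1)

  # hand-enumerated thresholds for one class of a 4-item problem:
  # scores for basophil: .9 (pos), .8 (pos), .2 (neg), .1 (neg) with
  # truth (pos, neg, pos, neg) instead:
  truth2 <- c("basophil", "eosinophil", "basophil", "eosinophil")
  scores <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.1, 0.9))
  pc <- pr_curve(scores, truth2, cls2)$per_class$basophil
  expect_equal(pc$precision, c(1, 1 / 2, 2 / 3, 2 / 4))
  expect_equal(pc$recall, c(1 / 2, 1 / 2, 1, 1))

  # class without positives is excluded and flagged
  truth3 <- rep("basophil", 4)
  out <- pr_curve(scores, truth3, cls2)
  expect_equal(out$excluded_classes, "eosinophil")

  # random scores, balanced classes: average precision ~ prevalence
  set.seed(21)
  n <- 6000
  truthr <- sample(cell_classes(), n, TRUE)
  pr <- matrix(runif(n * 6), n)
  pr <- pr / rowSums(pr)
  res <- pr_curve(pr, truthr, cell_classes())
  expect_equal(mean(res$average$precision), 1 / 6, tolerance = 0.05 * 6)
})

test_that("error analysis ranks the true class and counts exactly", {
  cls <- cell_classes()
  # no errors
  probs <- diag(6)
  clean <- error_analysis(probs, cls, cls)
  expect_equal(clean$summary$n_errors, 0)
  expect_true(is.na(clean$summary$second_rank_fraction))

  # constructed errors with true class ranked 2, 2, 3
  p1 <- c(0.5, 0.4, 0.1, 0, 0, 0)        # true = 2 -> rank 2
  p2 <- c(0.6, 0.1, 0.3, 0, 0, 0)        # true = 3 -> rank 2
  p3 <- c(0.4, 0.3, 0.2, 0.1, 0, 0)      # true = 3 -> rank 3
  tab <- rbind(p1, p2, p3)
  res <- error_analysis(tab, cls[c(2, 3, 3)], cls)
  expect_equal(res$summary$n_errors, 3)
  expect_equal(res$errors$rank_of_true, c(2L, 2L, 3L))
  expect_equal(res$summary$second_rank_fraction, 2 / 3)
  expect_equal(res$summary$confusion_pairs$Freq[1], 2)
})

test_that("embedding export has contract dimensions and determinism", {
  m <- tiny_dataset(2, default_domain_style("d1"), seed = 8)
  m$image[[2]] <- m$image[[1]]  # duplicate image
  crop <- crop_spec(window_side = 96L, network_input_side = 16L)
  b <- build_classifier(tiny_config(), seed = 1)
  df <- export_embeddings(b, m, crop = crop)
  expect_equal(nrow(df), nrow(m))
  expect_length(grep("^e\\d+$", names(df)), 128)
  expect_true(all(c("dim1", "dim2") %in% names(df)))
  expect_equal(attr(df, "reduction")$method, "pca")
  emb <- as.matrix(df[, grep("^e\\d+$", names(df))])
  expect_equal(emb[1, ], emb[2, ])  # duplicated image, identical rows

  px <- export_embeddings(b, m, mode = "pixels", reduce = FALSE,
                          crop = crop)
  expect_length(grep("^px\\d+$", names(px)), 16 * 16 * 3)
})
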