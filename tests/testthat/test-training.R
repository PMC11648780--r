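# Source training, few-shot splits, hyperparameter search, fine-tuning.

test_that("optimizer step counting follows batch arithmetic", {
  data <- toy_arrays(27)  # normally 162; trim to 160 images
  x <- data$x[, , , 1:160, drop = FALSE]
  labels <- data$labels[1:160]
  b <- build_classifier(tiny_config(), seed = 1)
  fit <- cytoshift:::.fit_arrays(b, x, labels,
                                 train_config(batch_size = 16,
                                              epochs = 1, seed = 2))
  expect_equal(fit$n_steps, 10L)
  expect_equal(nrow(fit$history), 1L)

  fit3 <- cytoshift:::.fit_arrays(b, x, labels,
                                  train_config(batch_size = 16,
                                               epochs = 3, seed = 2))
  expect_equal(fit3$n_steps, 30L)
  expect_equal(nrow(fit3$history), 3L)
})

test_that("training on separable toy data reduces loss and fits", {
  data <- toy_arrays(10)
  b <- build_classifier(tiny_config(), seed = 1)
  fit <- cytoshift:::.fit_arrays(b, data$x, data$labels,
                                 train_config(learning_rate = 1e-3,
                                              epochs = 8, seed = 3))
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_gt(tail(fit$history$accuracy, 1), 0.9)

  expect_error(cytoshift:::.fit_arrays(b, data$x,
                                       rep("plasmocyte", 60),
                                       train_config()), "class_order")
})

test_that("train_source mixes domains and records provenance", {
  mA <- tiny_dataset(2, default_domain_style("domA"), seed = 1)
  mB <- tiny_dataset(2, default_domain_style("domB"), seed = 2)
  crop <- crop_spec(window_side = 96L, network_input_side = 16L)
  b <- build_classifier(tiny_config(), seed = 1)
  fit <- train_source(b, list(mA, mB),
                      train_config(epochs = 1, seed = 4),
                      crop = crop)
  prov <- fit$bundle$provenance[[length(fit$bundle$provenance)]]
  expect_equal(prov$stage, "source_train")
  expect_setequal(prov$domains, c("domA", "domB"))
  expect_equal(prov$n_images, 24)
  expect_equal(nrow(fit$history), 1)

  # single-domain training behaves the same way (mixing is a no-op)
  fit1 <- train_source(b, mA, train_config(epochs = 1, seed = 4),
                       crop = crop)
  expect_equal(fit1$bundle$provenance[[2]]$domains, "domA")
})

test_that("few-shot budgets, allocation, and determinism", {
  fake_manifest <- function(n, prev = c(0.05, 0.1, 0.1, 0.25, 0.2, 0.3)) {
    set.seed(n)
    data.frame(path = sprintf("img%06d.png", seq_len(n)),
               label = sample(cell_classes(), n, TRUE, prob = prev),
               dataset_id = "t", stringsAsFactors = FALSE)
  }
  for (case in list(c(8564, 100), c(300, 30), c(60, 6))) {
    m <- fake_manifest(case[1])
    sp <- select_fewshot(m, seed = 1)
    expect_equal(length(sp$tuning_ids), case[2])
    # disjoint and exhaustive
    expect_length(intersect(sp$tuning_ids, sp$eval_ids), 0)
    expect_setequal(c(sp$tuning_ids, sp$eval_ids), m$path)
    # per-class counts within 1 of exact proportionality
    prev <- table(m$label)[names(sp$per_class_counts)]
    expect_true(all(abs(sp$per_class_counts -
                          case[2] * as.numeric(prev) / case[1]) <= 1))
    # deterministic per seed
    expect_identical(sp$tuning_ids,
                     select_fewshot(m, seed = 1)$tuning_ids)
    expect_false(identical(sp$tuning_ids,
                           select_fewshot(m, seed = 2)$tuning_ids))
  }

  # fixed budget overrides the default rule
  m <- fake_manifest(8564)
  expect_length(select_fewshot(m, budget_rule = 100)$tuning_ids, 100)

  # budget 0: empty tuning set, everything evaluates
  m0 <- fake_manifest(60)
  sp0 <- select_fewshot(m0, budget_rule = 0)
  expect_length(sp0$tuning_ids, 0)
  expect_length(sp0$eval_ids, 60)

  # balanced manifest, budget 12 -> 2 per class
  mb <- data.frame(path = sprintf("i%03d", 1:60),
                   label = rep(cell_classes(), each = 10),
                   dataset_id = "t")
  spb <- select_fewshot(mb, budget_rule = 12)
  expect_true(all(spb$per_class_counts == 2))

  # equal-per-class allocation flag
  mq <- fake_manifest(600)
  spq <- select_fewshot(mq, budget_rule = 12, allocation = "equal")
  expect_true(all(spq$per_class_counts == 2))
})

test_that("fine-tuning honours the freeze contract and empty splits", {
  m <- tiny_dataset(3, default_domain_style("tgt"), seed = 3)
  crop <- crop_spec(window_side = 96L, network_input_side = 16L)
  b <- build_classifier(tiny_config(), seed = 1)
  split <- select_fewshot(m, budget_rule = 6, seed = 1)

  encoder_weights <- function(bundle)
    lapply(Filter(function(l) l$part == "encoder" && !is.null(l$W),
                  bundle$net$layers), function(l) l$W)

  head_fit <- finetune(b, m, split, train_config(epochs = 1, seed = 2),
                       mode = "head_only", crop = crop)
  expect_identical(encoder_weights(head_fit$bundle), encoder_weights(b))

  full_fit <- finetune(b, m, split, train_config(epochs = 1, seed = 2),
                       mode = "full", crop = crop)
  expect_false(identical(encoder_weights(full_fit$bundle),
                         encoder_weights(b)))

  empty <- select_fewshot(m, budget_rule = 0, seed = 1)
  same <- finetune(b, m, empty, train_config(), crop = crop)
  expect_identical(same$bundle$net, b$net)
  expect_equal(same$n_steps, 0L)

  expect_error(finetune(b, m, split, train_config(), mode = "encoder"))
})

test_that("evaluation ids never reach a gradient step", {
  m <- tiny_dataset(3, default_domain_style("tgt"), seed = 5)
  crop <- crop_spec(window_side = 96L, network_input_side = 16L)
  b <- build_classifier(tiny_config(), seed = 1)
  split <- select_fewshot(m, budget_rule = 6, seed = 2)
  fit <- finetune(b, m, split, train_config(epochs = 1, seed = 2),
                  crop = crop)
  prov <- fit$bundle$provenance[[length(fit$bundle$provenance)]]
  expect_setequal(prov$tuning_ids, split$tuning_ids)
  expect_length(intersect(prov$tuning_ids, split$eval_ids), 0)
})

test_that("hyperparameter search is reproducible and avoids divergence", {
  data <- toy_arrays(3)  # 18 images
  m <- data.frame(path = sprintf("i%02d", 1:18), label = data$labels,
                  dataset_id = "t", stringsAsFactors = FALSE)
  m$image <- I(lapply(1:18, function(i) {
    # inflate 16px toy arrays to a 96px "raw" image for the crop pipeline
    cytoshift:::ebi_resize(data$x[, , , i], 96, 96)
  }))
  crop <- crop_spec(window_side = 96L, network_input_side = 16L)
  b <- build_classifier(tiny_config(), seed = 1)
  split <- structure(list(tuning_ids = m$path, eval_ids = character(0),
                          per_class_counts = table(m$label),
                          budget_rule = list(budget = 18)),
                     class = "fewshot_split")

  space <- hp_space(lr_bounds = c(1e-4, 10), epoch_bounds = c(2L, 3L),
                    batch_choices = 6L, n_trials = 4L, seed = 7)
  s1 <- hp_search(b, m, split, space, crop = crop)
  s2 <- hp_search(b, m, split, space, crop = crop)
  expect_identical(s1$trials, s2$trials)
  expect_equal(nrow(s1$trials), 4)
  # the winner is the first trial attaining the maximum CV score
  expect_equal(which.max(s1$trials$cv_accuracy),
               match(s1$best_config$learning_rate,
                     s1$trials$learning_rate))
  # divergent learning rates score at or below chance and cannot win
  worst <- s1$trials[which.max(s1$trials$learning_rate), ]
  if (worst$learning_rate > 1)
    expect_lte(worst$cv_accuracy, max(s1$trials$cv_accuracy))

  # a single-candidate space returns that candidate
  one <- hp_space(lr_bounds = c(1e-3, 1e-3), batch_choices = 6L,
                  epoch_bounds = c(2L, 2L), n_trials = 1L, seed = 1)
  best <- hp_search(b, m, split, one, crop = crop)
  expect_equal(best$best_config$learning_rate, 1e-3)
  expect_equal(best$best_config$epochs, 2L)

  tiny_split <- structure(list(tuning_ids = m$path[1:2]),
                          class = "fewshot_split")
  expect_error(hp_search(b, m, tiny_split, space, crop = crop),
               "smaller than")
})
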