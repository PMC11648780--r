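# Ablation conditions, the paired Wilcoxon test, and the harness plumbing.

test_that("the six shipped conditions map to their knobs", {
  cond <- ablation_conditions()
  expect_equal(nrow(cond), 6)
  expect_equal(cond$name[c(1, 6)], c("without_source_train",
                                     "proposed_workflow"))
  expect_false(cond$source_pretrain[1])
  expect_equal(cond$finetune_mode[2], "none")
  expect_equal(cond$finetune_mode[3], "head_only")
  expect_equal(cond$finetune_pool[4], "target+source")
  expect_false(cond$color_transform[5])
  expect_true(all(cond$color_transform[-5]))
})

test_that("signed-rank p-values match exact enumeration", {
  expect_equal(pairwise_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # all-positive differences (1..5): two-sided exact p = 2/32
  expect_equal(pairwise_test(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1)), 0.0625)
  # symmetry under swapping the arguments
  a <- c(0.6, 0.9, 0.8, 0.85); b <- c(0.5, 0.7, 0.85, 0.6)
  expect_equal(pairwise_test(a, b), pairwise_test(b, a))
  expect_error(pairwise_test(1:3, 1:2), "equal length")
})

test_that("exact branch agrees with the reference implementation", {
  set.seed(13)
  for (n in c(5, 8, 10)) {
    x <- round(rnorm(n), 3); y <- round(rnorm(n), 3)
    # tie/zero-free by construction with continuous draws
    want <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(pairwise_test(x, y), want, tolerance = 1e-12)
  }
  # large-sample branch tracks the reference approximation
  set.seed(14)
  x <- rnorm(30); y <- rnorm(30, 0.3)
  want <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                             correct = TRUE)$p.value
  expect_equal(pairwise_test(x, y), want, tolerance = 1e-6)
})

test_that("the harness runs all conditions with a paired design", {
  mA <- tiny_dataset(2, default_domain_style("srcA"), seed = 1)
  mB <- tiny_dataset(2, default_domain_style("srcB"), seed = 2)
  pair <- make_style_pair(0.5, seed = 3,
                          base = default_domain_style("tgt"))
  tgt <- tiny_dataset(4, pair$style_b, seed = 4)
  tgt$dataset_id <- "tgt_shift"

  crop <- crop_spec(window_side = 96L, network_input_side = 16L)
  res <- run_ablation(list(mA, mB), tgt, seeds = 1L, budget_rule = 6,
                      config = tiny_config(),
                      source_cfg = train_config(learning_rate = 1e-3,
                                                epochs = 2),
                      finetune_cfg = train_config(epochs = 2),
                      crop = crop, source_holdout = 0.25)
  expect_equal(res$summary$condition_id, 1:6)
  expect_equal(nrow(res$per_run), 6)
  expect_equal(nrow(res$source_accuracy), 1)
  expect_true(all(res$per_run$accuracy >= 0 & res$per_run$accuracy <= 1))
  expect_true(all(is.na(res$summary$p_vs_previous[1])))
  expect_true(all(res$summary$p_vs_previous[-1] >= 0 &
                    res$summary$p_vs_previous[-1] <= 1))

  dir <- withr::local_tempdir()
  save_ablation(res, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "ablation.json")))

  # a condition with neither pretraining nor fine-tuning is rejected
  bad <- ablation_conditions()
  bad$finetune_mode[1] <- "none"
  expect_error(run_ablation(list(mA), tgt, conditions = bad,
                            seeds = 1L, config = tiny_config(),
                            crop = crop), "nothing")
})

test_that("duplicated targets average to the single-target result", {
  mA <- tiny_dataset(2, default_domain_style("srcA"), seed = 5)
  tgt <- tiny_dataset(3, default_domain_style("tgt"), seed = 6)
  crop <- crop_spec(window_side = 96L, network_input_side = 16L)
  conds <- ablation_conditions()[c(2, 6), ]
  one <- run_ablation(mA, tgt, conditions = conds, seeds = 1L,
                      budget_rule = 6, config = tiny_config(),
                      source_cfg = train_config(learning_rate = 1e-3,
                                                epochs = 1),
                      finetune_cfg = train_config(epochs = 1),
                      crop = crop)
  two <- run_ablation(mA, list(tgt, tgt), conditions = conds, seeds = 1L,
                      budget_rule = 6, config = tiny_config(),
                      source_cfg = train_config(learning_rate = 1e-3,
                                                epochs = 1),
                      finetune_cfg = train_config(epochs = 1),
                      crop = crop)
  expect_equal(two$summary$accuracy, one$summary$accuracy)
  expect_equal(two$summary$macro_recall, one$summary$macro_recall)
})
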