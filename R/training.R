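#' @name training
#' @title Source training and the few-shot fine-tuning protocol
#'
#' @description
#' Source training draws every batch from the shuffled union of the source
#' domains (mixed-domain batches). Adaptation to a new target domain uses a
#' stratified few-shot split — at most 100 labelled images, by default
#' `min(100, floor(n/10))`, allocated to classes by largest-remainder
#' proportional rounding — optionally a random hyperparameter search scored
#' by stratified 3-fold cross-validation on the tuning set, and fine-tuning
#' of either the full model or the head only (encoder frozen). Evaluation
#' images never contribute a gradient step; the provenance log records
#' which ids were used at every stage.
NULL

#' Training configuration
#'
#' @param batch_size Images per optimizer step (default 16).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Number of passes over the pool (default 15).
#' @param optimizer Only `"adam"` is supported.
#' @param seed Integer seed controlling shuffling, dropout, and any
#'   augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16L, learning_rate = 1e-4,
                         epochs = 15L, optimizer = "adam", seed = 1L) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (!identical(optimizer, "adam"))
    stop("only the adam optimizer is supported", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "train_config")
}

labels_to_index <- function(labels, class_order) {
  y <- match(as.character(labels), class_order)
  if (anyNA(y))
    stop("labels outside class_order: ",
         paste(unique(labels[is.na(y)]), collapse = ", "), call. = FALSE)
  y
}

# Shared fitting path on preprocessed arrays.
.fit_arrays <- function(bundle, x, labels, cfg, freeze_encoder = FALSE) {
  y <- labels_to_index(labels, bundle$class_order)
  fit <- nn_train(bundle$net, x, y, epochs = cfg$epochs,
                  batch_size = cfg$batch_size, lr = cfg$learning_rate,
                  eps_smooth = bundle$config$smoothing_eps, seed = cfg$seed,
                  freeze_encoder = freeze_encoder)
  bundle$net <- fit$net
  list(bundle = bundle, history = fit$history, n_steps = fit$n_steps)
}

#' Train on one or more source domains
#'
#' Every epoch shuffles the pooled images of all source manifests jointly,
#' so each batch mixes domains. Training images are augmented (resolution
#' degradation + random zoom) before resizing; the colour reference, when
#' given, is applied to every image first.
#'
#' @param bundle A `classifier_bundle`.
#' @param manifests A manifest `data.frame` or list of manifests (one per
#'   source domain).
#' @param train_cfg A [train_config()].
#' @param color_ref Optional `color_stats` reference for colour
#'   standardization.
#' @param crop A [crop_spec()]; its `network_input_side` must match the
#'   bundle's `input_side`.
#' @param augment Apply training augmentations (default `TRUE`).
#' @return List with the trained `bundle`, a per-epoch `history`
#'   data frame (`epoch`, `loss`, `accuracy`), and `n_steps`.
#' @export
train_source <- function(bundle, manifests, train_cfg = train_config(),
                         color_ref = NULL, crop = NULL, augment = TRUE) {
  stopifnot(inherits(bundle, "classifier_bundle"))
  if (is.data.frame(manifests)) manifests <- list(manifests)
  if (!length(manifests)) stop("no source manifests", call. = FALSE)
  manifest <- do.call(rbind, manifests)
  if (is.null(crop))
    crop <- crop_spec(network_input_side = bundle$config$input_side)
  prep <- preprocess_manifest(manifest, spec = crop, color_ref = color_ref,
                              augment = augment,
                              seed = child_seed(train_cfg$seed, 11))
  fit <- .fit_arrays(bundle, prep$x, prep$labels, train_cfg)
  fit$bundle$provenance <- c(fit$bundle$provenance, list(list(
    stage = "source_train", seed = train_cfg$seed,
    epochs = train_cfg$epochs, n_steps = fit$n_steps,
    domains = unique(manifest$dataset_id), n_images = nrow(manifest),
    color_transform = !is.null(color_ref))))
  fit
}

#' Stratified few-shot split of a target domain
#'
#' Splits a target manifest into a small tuning set (used for fine-tuning)
#' and an evaluation set holding every remaining image. The default budget
#' rule is `min(100, floor(n / 10))`: at most 100 annotated images, and a
#' tenth of small datasets. Class counts in the tuning set follow class
#' prevalence with largest-remainder rounding (or equal counts with
#' `allocation = "equal"`). A budget of 0 yields an empty tuning set — the
#' case of a target already classified well enough without adaptation.
#'
#' @param manifest Target manifest.
#' @param budget_rule `"default"`, a fixed non-negative number, or a
#'   function of the manifest size returning the budget.
#' @param seed Integer seed for the within-class sampling.
#' @param allocation `"proportional"` (prevalence-proportional, default)
#'   or `"equal"`.
#' @return A `fewshot_split`: `tuning_ids`, `eval_ids` (disjoint,
#'   exhaustive), `per_class_counts`, and a `budget_rule` record.
#' @export
select_fewshot <- function(manifest, budget_rule = "default", seed = 1L,
                           allocation = c("proportional", "equal")) {
  allocation <- match.arg(allocation)
  n <- nrow(manifest)
  if (n == 0L) stop("empty manifest", call. = FALSE)
  budget <- if (is.function(budget_rule)) budget_rule(n)
  else if (identical(budget_rule, "default")) min(100L, floor(n / 10))
  else if (is.numeric(budget_rule)) min(as.integer(budget_rule), n)
  else stop("budget_rule must be \"default\", a number, or a function",
            call. = FALSE)
  budget <- as.integer(budget)
  if (budget < 0) stop("budget must be >= 0", call. = FALSE)
  ids <- manifest_ids(manifest)
  cls <- split(ids, manifest$label)
  sizes <- vapply(cls, length, integer(1))
  counts <- if (allocation == "equal") {
    base <- budget %/% length(cls)
    cnt <- pmin(rep(base, length(cls)), sizes)
    # distribute any leftover to the largest classes
    left <- budget - sum(cnt)
    ord <- order(sizes - cnt, decreasing = TRUE)
    i <- 1L
    while (left > 0L && any(cnt < sizes)) {
      j <- ord[(i - 1L) %% length(ord) + 1L]
      if (cnt[j] < sizes[j]) { cnt[j] <- cnt[j] + 1L; left <- left - 1L }
      i <- i + 1L
    }
    cnt
  } else {
    quota <- budget * sizes / n
    cnt <- floor(quota)
    rem <- budget - sum(cnt)
    if (rem > 0L) {
      frac <- quota - cnt
      ord <- order(frac, sizes, names(sizes), decreasing = TRUE)
      take <- ord[seq_len(rem)]
      cnt[take] <- cnt[take] + 1L
    }
    pmin(cnt, sizes)
  }
  names(counts) <- names(cls)
  tuning <- with_seed(child_seed(seed, 23), {
    unlist(lapply(names(cls), function(k) {
      if (counts[[k]] == 0L) return(character(0))
      as.character(sample(as.character(cls[[k]]), counts[[k]]))
    }), use.names = FALSE)
  })
  structure(list(tuning_ids = tuning,
                 eval_ids = setdiff(as.character(ids), tuning),
                 per_class_counts = counts,
                 budget_rule = list(rule = if (is.function(budget_rule))
                   "custom" else as.character(budget_rule),
                   budget = budget, n = n, seed = seed,
                   allocation = allocation)),
            class = "fewshot_split")
}

#' @export
print.fewshot_split <- function(x, ...) {
  cat(sprintf("fewshot_split: %d tuning / %d eval (budget %d of %d)\n",
              length(x$tuning_ids), length(x$eval_ids),
              x$budget_rule$budget, x$budget_rule$n))
  print(x$per_class_counts)
  invisible(x)
}

#' Save / load a few-shot split as CSV
#'
#' @param split A `fewshot_split`.
#' @param path CSV path; rows are `(id, role)` with role `tuning` or
#'   `eval`.
#' @export
save_split <- function(split, path) {
  df <- data.frame(id = c(split$tuning_ids, split$eval_ids),
                   role = c(rep("tuning", length(split$tuning_ids)),
                            rep("eval", length(split$eval_ids))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fine-tune on a target's tuning set
#'
#' @param bundle A trained `classifier_bundle`.
#' @param manifest The target manifest the split refers to.
#' @param split A [select_fewshot()] split; an empty tuning set returns the
#'   bundle unchanged.
#' @param train_cfg A [train_config()].
#' @param mode `"full"` (default: all parameters updated) or
#'   `"head_only"` (encoder frozen; its parameters stay bit-identical).
#' @param color_ref Optional `color_stats` reference.
#' @param crop A [crop_spec()] (defaults to the bundle's input side).
#' @param extra_pool Optional list(x =, labels =) of extra preprocessed
#'   images mixed into the tuning pool (used for mixed-source
#'   fine-tuning).
#' @return List with the fine-tuned `bundle`, `history`, and `n_steps`.
#' @export
finetune <- function(bundle, manifest, split,
                     train_cfg = train_config(), mode = c("full",
                                                          "head_only"),
                     color_ref = NULL, crop = NULL, extra_pool = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "classifier_bundle"),
            inherits(split, "fewshot_split"))
  if (length(split$tuning_ids) == 0L && is.null(extra_pool)) {
    bundle$provenance <- c(bundle$provenance, list(list(
      stage = "finetune_skipped", reason = "empty tuning set")))
    return(list(bundle = bundle, history = NULL, n_steps = 0L))
  }
  if (is.null(crop))
    crop <- crop_spec(network_input_side = bundle$config$input_side)
  sub <- manifest[match(split$tuning_ids, manifest_ids(manifest)), ,
                  drop = FALSE]
  prep <- preprocess_manifest(sub, spec = crop, color_ref = color_ref,
                              augment = FALSE)
  x <- prep$x; labels <- prep$labels
  if (!is.null(extra_pool)) {
    x <- array(c(x, extra_pool$x),
               c(dim(x)[1:3], dim(x)[4] + dim(extra_pool$x)[4]))
    labels <- c(labels, extra_pool$labels)
  }
  fit <- .fit_arrays(bundle, x, labels, train_cfg,
                     freeze_encoder = mode == "head_only")
  fit$bundle$provenance <- c(fit$bundle$provenance, list(list(
    stage = "finetune", mode = mode, seed = train_cfg$seed,
    epochs = train_cfg$epochs, n_steps = fit$n_steps,
    n_tuning = length(split$tuning_ids),
    n_extra = if (is.null(extra_pool)) 0L else dim(extra_pool$x)[4],
    tuning_ids = split$tuning_ids,
    color_transform = !is.null(color_ref))))
  fit
}

#' Hyperparameter search space
#'
#' @param lr_bounds Log-uniform learning-rate bounds.
#' @param batch_choices Candidate batch sizes.
#' @param epoch_bounds Integer epoch bounds (uniform).
#' @param n_trials Number of random trials.
#' @param folds Cross-validation folds (>= 2, default 3).
#' @param seed Integer seed.
#' @return An `hp_space` list.
#' @export
hp_space <- function(lr_bounds = c(1e-5, 1e-2), batch_choices = c(8L, 16L),
                     epoch_bounds = c(5L, 20L), n_trials = 20L, folds = 3L,
                     seed = 1L) {
  if (lr_bounds[1] <= 0 || lr_bounds[1] > lr_bounds[2])
    stop("lr_bounds must be ordered and positive", call. = FALSE)
  if (epoch_bounds[1] < 1 || epoch_bounds[1] > epoch_bounds[2])
    stop("epoch_bounds must be ordered and >= 1", call. = FALSE)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  structure(list(lr_bounds = lr_bounds,
                 batch_choices = as.integer(batch_choices),
                 epoch_bounds = as.integer(epoch_bounds),
                 n_trials = as.integer(n_trials),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "hp_space")
}

# Stratified fold assignment: within each class, shuffled ids are dealt
# round-robin to folds.
stratified_folds <- function(labels, folds, seed) {
  with_seed(child_seed(seed, 31), {
    fold <- integer(length(labels))
    for (k in unique(labels)) {
      idx <- sample(which(labels == k))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Random hyperparameter search with cross-validated scoring
#'
#' Samples fine-tuning configurations (learning rate log-uniform, batch
#' size, epochs) and scores each by stratified k-fold cross-validation on
#' the tuning set: every fold fine-tunes a fresh copy of the bundle on the
#' remaining folds and is scored by validation accuracy. The first trial
#' attaining the best mean score wins.
#'
#' @param bundle A trained `classifier_bundle`.
#' @param manifest The target manifest.
#' @param split A [select_fewshot()] split; needs at least `folds` tuning
#'   images.
#' @param space An [hp_space()].
#' @param mode Fine-tuning mode passed through to the per-fold fits.
#' @param color_ref,crop As in [finetune()].
#' @return List with `best_config` (a [train_config()]) and `trials` (one
#'   row per trial: parameters and mean CV accuracy).
#' @export
hp_search <- function(bundle, manifest, split, space = hp_space(),
                      mode = "full", color_ref = NULL, crop = NULL) {
  stopifnot(inherits(split, "fewshot_split"))
  ids <- split$tuning_ids
  if (length(ids) < space$folds)
    stop("tuning set smaller than the number of folds", call. = FALSE)
  if (is.null(crop))
    crop <- crop_spec(network_input_side = bundle$config$input_side)
  sub <- manifest[match(ids, manifest_ids(manifest)), , drop = FALSE]
  prep <- preprocess_manifest(sub, spec = crop, color_ref = color_ref,
                              augment = FALSE)
  y <- labels_to_index(prep$labels, bundle$class_order)
  fold <- stratified_folds(prep$labels, space$folds, space$seed)
  params <- with_seed(child_seed(space$seed, 41), data.frame(
    trial = seq_len(space$n_trials),
    learning_rate = exp(runif(space$n_trials, log(space$lr_bounds[1]),
                              log(space$lr_bounds[2]))),
    batch_size = space$batch_choices[
      sample.int(length(space$batch_choices), space$n_trials,
                 replace = TRUE)],
    epochs = {
      ep <- space$epoch_bounds[1]:space$epoch_bounds[2]
      ep[sample.int(length(ep), space$n_trials, replace = TRUE)]
    }))
  scores <- numeric(space$n_trials)
  for (tr in seq_len(space$n_trials)) {
    accs <- numeric(space$folds)
    for (f in seq_len(space$folds)) {
      tr_idx <- which(fold != f); va_idx <- which(fold == f)
      cfg <- train_config(batch_size = params$batch_size[tr],
                          learning_rate = params$learning_rate[tr],
                          epochs = params$epochs[tr],
                          seed = child_seed(space$seed, 100 + tr))
      fit <- .fit_arrays(bundle, prep$x[, , , tr_idx, drop = FALSE],
                         prep$labels[tr_idx], cfg,
                         freeze_encoder = mode == "head_only")
      pred <- nn_predict(fit$bundle$net,
                         prep$x[, , , va_idx, drop = FALSE])
      accs[f] <- mean(max.col(pred$logits) == y[va_idx])
    }
    scores[tr] <- mean(accs)
  }
  params$cv_accuracy <- scores
  best <- which.max(scores)  # first max wins
  list(best_config = train_config(batch_size = params$batch_size[best],
                                  learning_rate =
                                    params$learning_rate[best],
                                  epochs = params$epochs[best],
                                  seed = space$seed),
       trials = params)
}
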