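#' @name evaluation
#' @title Metrics, bootstrap intervals, PR curves, embeddings, and error
#'   analysis
#'
#' @description
#' Implements the evaluation stack: overall accuracy (rightly predicted /
#' total), per-class precision `TP / (TP + FP)` and recall
#' `TP / (TP + FN)` with unweighted macro averages, percentile bootstrap
#' confidence intervals on accuracy, one-vs-rest precision-recall curves
#' averaged over classes, embedding / raw-pixel exports for 2-D
#' visualization, and a wrong-prediction analysis including the rank of the
#' true class in the output probability vector.
NULL

#' Classification metrics report
#'
#' @param predictions Character (or factor) predicted labels.
#' @param truths True labels, same length.
#' @param class_order Label vector fixing row/column order of the
#'   confusion matrix.
#' @return An `eval_report`: `n`, `accuracy`, `per_class` (label,
#'   precision, recall, support; `NA` when undefined), `macro_precision`
#'   and `macro_recall` (unweighted means over classes with defined
#'   values), and the `confusion` matrix (rows = truth, columns =
#'   prediction).
#' @export
compute_metrics <- function(predictions, truths,
                            class_order = cell_classes()) {
  predictions <- as.character(predictions); truths <- as.character(truths)
  if (length(predictions) != length(truths) || length(truths) < 1L)
    stop("predictions and truths must have equal length >= 1",
         call. = FALSE)
  bad <- setdiff(unique(c(predictions, truths)), class_order)
  if (length(bad))
    stop("labels outside class_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  confusion <- table(factor(truths, levels = class_order),
                     factor(predictions, levels = class_order))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("truth", "prediction")
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  if (anyNA(precision) || anyNA(recall))
    warning("precision/recall undefined for some classes; ",
            "excluded from macro means", call. = FALSE)
  structure(list(
    n = length(truths),
    accuracy = sum(tp) / length(truths),
    per_class = data.frame(label = class_order, precision = precision,
                           recall = recall, support = rowSums(confusion),
                           row.names = NULL),
    macro_precision = mean(precision, na.rm = TRUE),
    macro_recall = mean(recall, na.rm = TRUE),
    confusion = confusion, ci = NULL), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d, accuracy = %.3f", x$n, x$accuracy))
  if (!is.null(x$ci))
    cat(sprintf(" [%.3f, %.3f]", x$ci[1], x$ci[2]))
  cat(sprintf("\n  macro precision = %.3f, macro recall = %.3f\n",
              x$macro_precision, x$macro_recall))
  invisible(x)
}

#' Percentile bootstrap confidence interval for accuracy
#'
#' Resamples (prediction, truth) pairs with replacement `n_boot` times and
#' returns the percentile interval of the recomputed accuracy.
#'
#' @param predictions,truths Label vectors of equal length.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed.
#' @return Numeric `c(low, high)` with attributes `level`, `n_boot`, and
#'   `method = "percentile"`.
#' @export
bootstrap_ci <- function(predictions, truths, n_boot = 1000L,
                         level = 0.95, seed = 1L) {
  n <- length(truths)
  if (n < 1L || length(predictions) != n)
    stop("predictions and truths must have equal length >= 1",
         call. = FALSE)
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)",
                                     call. = FALSE)
  correct <- as.integer(as.character(predictions) == as.character(truths))
  accs <- with_seed(seed, {
    draws <- matrix(sample(correct, n * n_boot, replace = TRUE), n)
    colMeans(draws)
  })
  ci <- unname(quantile(accs, c((1 - level) / 2, 1 - (1 - level) / 2)))
  attributes(ci) <- list(level = level, n_boot = n_boot,
                         method = "percentile")
  ci
}

#' One-vs-rest precision-recall curves, averaged over classes
#'
#' For every class, precision and recall are traced across descending score
#' thresholds (one point per distinct score). The class-averaged curve is
#' the unweighted mean of per-class precision interpolated at a fixed
#' recall grid (101 points, step-function interpolation: the precision of
#' the first curve point whose recall reaches the grid value), and the
#' summary AUC is the trapezoidal area under that averaged curve. Classes
#' without positives are excluded from the average and flagged.
#'
#' @param probabilities `N x K` matrix of class scores; columns named by
#'   (or ordered as) `class_order`.
#' @param truths True labels of length N.
#' @param class_order Label vector.
#' @param recall_grid Recall grid for curve averaging.
#' @return List with `per_class` (one data frame of threshold / precision /
#'   recall per class), `average` (data frame recall / precision),
#'   `auc`, and `excluded_classes`.
#' @export
pr_curve <- function(probabilities, truths, class_order = cell_classes(),
                     recall_grid = seq(0, 1, length.out = 101L)) {
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) != length(truths))
    stop("probabilities rows must match truths", call. = FALSE)
  if (ncol(probabilities) != length(class_order))
    stop("probabilities columns must match class_order", call. = FALSE)
  truths <- as.character(truths)
  per_class <- list(); excluded <- character(0)
  grid_prec <- matrix(NA_real_, length(recall_grid), 0)
  for (k in seq_along(class_order)) {
    pos <- truths == class_order[k]
    if (!any(pos)) {
      excluded <- c(excluded, class_order[k])
      next
    }
    sc <- probabilities[, k]
    ord <- order(sc, decreasing = TRUE)
    sc_sorted <- sc[ord]; pos_sorted <- pos[ord]
    tp <- cumsum(pos_sorted)
    fp <- cumsum(!pos_sorted)
    # one point per distinct threshold (last index of each tied block)
    keep <- c(sc_sorted[-1] != sc_sorted[-length(sc_sorted)], TRUE)
    prec <- tp[keep] / (tp[keep] + fp[keep])
    rec <- tp[keep] / sum(pos)
    df <- data.frame(threshold = sc_sorted[keep], precision = prec,
                     recall = rec)
    per_class[[class_order[k]]] <- df
    # step interpolation onto the grid
    gi <- findInterval(recall_grid, rec, left.open = TRUE) + 1L
    gp <- ifelse(gi <= length(rec), prec[gi], prec[length(prec)])
    grid_prec <- cbind(grid_prec, gp)
  }
  if (ncol(grid_prec) == 0L) stop("no class with positives", call. = FALSE)
  avg_prec <- rowMeans(grid_prec)
  auc <- sum(diff(recall_grid) * (head(avg_prec, -1) + avg_prec[-1]) / 2)
  list(per_class = per_class,
       average = data.frame(recall = recall_grid, precision = avg_prec),
       auc = auc, excluded_classes = excluded)
}

#' Wrong-prediction analysis
#'
#' Enumerates misclassified items and, for each, the rank of the true class
#' in the descending-sorted probability vector (rank 1 = the prediction
#' itself). The summary reports the fraction of errors whose true class is
#' ranked second — the signature of "near-miss" errors where the model's
#' second guess is right — and the most frequent (true, predicted)
#' confusion pairs.
#'
#' @param probabilities `N x K` matrix of class probabilities.
#' @param truths True labels of length N.
#' @param class_order Label vector matching the probability columns.
#' @return An `error_analysis` list: `errors` (data frame: index,
#'   predicted, true, rank_of_true), `probabilities` (rows of the error
#'   items), and `summary` (`n_errors`, `second_rank_fraction` — `NA` when
#'   there are no errors — and `confusion_pairs`).
#' @export
error_analysis <- function(probabilities, truths,
                           class_order = cell_classes()) {
  probabilities <- as.matrix(probabilities)
  truths <- as.character(truths)
  y <- match(truths, class_order)
  if (anyNA(y)) stop("truths outside class_order", call. = FALSE)
  pred_idx <- max.col(probabilities, ties.method = "first")
  err <- which(pred_idx != y)
  rank_of_true <- vapply(err, function(i)
    which(order(probabilities[i, ], decreasing = TRUE) == y[i]),
    integer(1))
  errors <- data.frame(index = err,
                       predicted = class_order[pred_idx[err]],
                       true = truths[err],
                       rank_of_true = rank_of_true)
  pairs <- if (nrow(errors)) {
    tab <- as.data.frame(table(true = errors$true,
                               predicted = errors$predicted),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, ]
    tab[order(-tab$Freq), ]
  } else data.frame(true = character(0), predicted = character(0),
                    Freq = integer(0))
  structure(list(
    errors = errors,
    probabilities = probabilities[err, , drop = FALSE],
    summary = list(n_errors = length(err),
                   second_rank_fraction = if (length(err))
                     mean(rank_of_true == 2L) else NA_real_,
                   confusion_pairs = pairs)), class = "error_analysis")
}

#' Evaluate a classifier on preprocessed images or a manifest
#'
#' Convenience wrapper: predicts, computes the metrics report, and attaches
#' a bootstrap confidence interval.
#'
#' @param bundle A `classifier_bundle`.
#' @param manifest Target manifest (ignored when `x` is given).
#' @param x Optional preprocessed `side x side x 3 x N` array.
#' @param labels True labels when `x` is given.
#' @param color_ref,crop Preprocessing options used with a manifest.
#' @param n_boot,level,seed Bootstrap options (see [bootstrap_ci()]).
#' @return An `eval_report` with the `ci` field set and attribute
#'   `probabilities`.
#' @export
evaluate_classifier <- function(bundle, manifest = NULL, x = NULL,
                                labels = NULL, color_ref = NULL,
                                crop = NULL, n_boot = 1000L, level = 0.95,
                                seed = 1L) {
  if (is.null(x)) {
    if (is.null(crop))
      crop <- crop_spec(network_input_side = bundle$config$input_side)
    prep <- preprocess_manifest(manifest, spec = crop,
                                color_ref = color_ref, augment = FALSE)
    x <- prep$x; labels <- prep$labels
  }
  pred <- nn_predict(bundle$net, x)
  pred_labels <- bundle$class_order[max.col(pred$logits,
                                            ties.method = "first")]
  report <- compute_metrics(pred_labels, labels, bundle$class_order)
  report$ci <- bootstrap_ci(pred_labels, labels, n_boot = n_boot,
                            level = level, seed = seed)
  z <- exp(pred$logits - apply(pred$logits, 1, max))
  attr(report, "probabilities") <- z / rowSums(z)
  attr(report, "predictions") <- pred_labels
  report
}

#' Export image embeddings (or flattened pixels) with 2-D reduction
#'
#' Writes one row per image: identifiers, label, domain, the
#' `embedding_dim`-wide embedding (or the flattened preprocessed pixels in
#' `mode = "pixels"`), and optionally a 2-D reduction for visualization.
#' The reduction is delegated to [stats::prcomp()] (principal components);
#' the method and seed are stamped on the result.
#'
#' @param bundle A `classifier_bundle`.
#' @param manifest Manifest of images to embed.
#' @param mode `"embedding"` (encoder output) or `"pixels"` (flattened
#'   network-input image, the pixel-space analogue).
#' @param reduce Add 2-D reduction columns `dim1`, `dim2`?
#' @param color_ref,crop Preprocessing options.
#' @param seed Seed stamped on the reduction.
#' @param out Optional CSV path.
#' @return Data frame with columns `id`, `label`, `dataset_id`, feature
#'   columns (`e1...` or `px1...`), and `dim1`/`dim2` when reduced.
#' @export
export_embeddings <- function(bundle, manifest,
                              mode = c("embedding", "pixels"),
                              reduce = TRUE, color_ref = NULL, crop = NULL,
                              seed = 1L, out = NULL) {
  mode <- match.arg(mode)
  if (is.null(crop))
    crop <- crop_spec(network_input_side = bundle$config$input_side)
  prep <- preprocess_manifest(manifest, spec = crop, color_ref = color_ref,
                              augment = FALSE)
  feats <- if (mode == "embedding") {
    nn_predict(bundle$net, prep$x)$embeddings
  } else {
    t(matrix(prep$x, ncol = dim(prep$x)[4]))
  }
  colnames(feats) <- paste0(if (mode == "embedding") "e" else "px",
                            seq_len(ncol(feats)))
  df <- data.frame(id = prep$ids, label = prep$labels,
                   dataset_id = manifest$dataset_id, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(feats))
  if (reduce) {
    red <- with_seed(seed, prcomp(feats, rank. = 2L))
    df$dim1 <- red$x[, 1]; df$dim2 <- red$x[, 2]
    attr(df, "reduction") <- list(method = "pca", seed = seed)
  }
  if (!is.null(out)) write.csv(df, out, row.names = FALSE)
  df
}
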