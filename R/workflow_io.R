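#' @name workflow_io
#' @title Manifests, configuration, and the umbrella workflow
#'
#' @description
#' Datasets are described by CSV manifests with columns `path`, `label`,
#' and `dataset_id`, optionally bounding boxes (`x_min`, `y_min`, `x_max`,
#' `y_max`; 0-based, half-open) or `mask_path`. [run_workflow()] ties the
#' stages together in order — reference statistics, source training,
#' per-target few-shot fine-tuning, evaluation — writing every artifact
#' under a config-hash-stamped directory with a structured JSONL log.
NULL

# Row identifiers: explicit `id` column, else path, else row index.
manifest_ids <- function(manifest) {
  if (!is.null(manifest$id)) as.character(manifest$id)
  else if (!is.null(manifest$path) && !anyNA(manifest$path) &&
           !any(duplicated(manifest$path))) manifest$path
  else as.character(seq_len(nrow(manifest)))
}

# Fetch the i-th image: in-memory list column, else read from disk.
manifest_image <- function(manifest, i) {
  if (!is.null(manifest$image)) return(manifest$image[[i]])
  load_image(manifest$path[i])
}

# Optional bbox/mask locator of row i, or NULL.
manifest_locator <- function(manifest, i) {
  bb <- c("x_min", "y_min", "x_max", "y_max")
  if (all(bb %in% names(manifest)) &&
      !anyNA(unlist(manifest[i, bb]))) {
    return(as.numeric(manifest[i, bb]))
  }
  if (!is.null(manifest$mask_path) && !is.na(manifest$mask_path[i]) &&
      nzchar(manifest$mask_path[i])) {
    m <- load_image_any(manifest$mask_path[i])
    if (length(dim(m)) == 3L) m <- m[, , 1]
    return(m)
  }
  NULL
}

#' Read an RGB image from disk
#'
#' Supports PNG and (when the `tiff` package is installed) TIFF. Grayscale
#' images are expanded to three channels; alpha channels are dropped.
#'
#' @param path Image file path.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
load_image <- function(path) {
  img <- load_image_any(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  img
}

load_image_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop("unsupported image format: .", ext, call. = FALSE)
}

#' Load and validate a dataset manifest
#'
#' @param path Manifest CSV path.
#' @param class_set Allowed label vocabulary.
#' @param check_paths Verify that every referenced image file exists.
#' @return Validated manifest `data.frame`.
#' @export
load_manifest <- function(path, class_set = cell_classes(),
                          check_paths = TRUE) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("path", "label", "dataset_id")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols))
    stop("manifest is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!m$label %in% class_set)
  if (length(bad))
    stop("unknown label(s) in manifest: ",
         paste(sprintf("row %d: '%s'", bad, m$label[bad]),
               collapse = "; "), call. = FALSE)
  ids <- manifest_ids(m)
  if (any(duplicated(ids)))
    stop("duplicate ids in manifest", call. = FALSE)
  if (check_paths) {
    gone <- m$path[!file.exists(m$path)]
    if (length(gone))
      stop("missing image file(s): ", paste(gone, collapse = ", "),
           call. = FALSE)
  }
  m
}

#' Save a manifest as CSV
#'
#' In-memory `image` columns are dropped (they cannot be serialized to
#' CSV).
#'
#' @param manifest Manifest data frame.
#' @param path Output CSV path.
#' @export
save_manifest <- function(manifest, path) {
  manifest$image <- NULL
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Build a manifest from a class-per-subdirectory image tree
#'
#' @param dir Directory whose subdirectories are class labels.
#' @param dataset_id Domain identifier recorded in the manifest.
#' @param class_set Allowed labels; subdirectories outside it are an
#'   error.
#' @return Manifest data frame.
#' @export
manifest_from_directory <- function(dir, dataset_id = basename(dir),
                                    class_set = cell_classes()) {
  labels <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  bad <- setdiff(labels, class_set)
  if (length(bad))
    stop("subdirectories outside the class set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rows <- lapply(labels, function(lb) {
    files <- list.files(file.path(dir, lb), full.names = TRUE,
                        pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
    if (!length(files)) return(NULL)
    data.frame(path = files, label = lb, dataset_id = dataset_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.log_stage <- function(log_path, stage, seed = NULL, t0 = NULL,
                       extra = list()) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage),
             if (!is.null(seed)) list(seed = seed),
             if (!is.null(t0))
               list(wall_s = round(as.numeric(Sys.time()) - t0, 3)),
             extra)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE)
}

#' Run the full workflow
#'
#' Executes the stages in order: compute reference colour statistics from
#' the source pool, train the source model on mixed-source batches,
#' then for every target select the few-shot split, fine-tune, and
#' evaluate on the remaining images. All artifacts are written under
#' `out_dir/<config-hash>/` and every stage is logged with its seed and
#' wall time. A target with a budget of 0 is evaluated with the
#' un-fine-tuned source model.
#'
#' @param config A nested list (or path to a YAML file) with sections:
#'   `data` (`sources`, `targets`: manifest CSV paths or in-memory
#'   manifests; `out_dir`), `color` (`enabled`), `model` (fields of
#'   [classifier_config()]), `train` / `finetune_train` (fields of
#'   [train_config()]), `finetune` (`budget_rule`, `mode`), `eval`
#'   (`n_boot`, `level`), and `seed`.
#' @return List of artifact paths: reference stats, source bundle, and
#'   per-target bundles and reports.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_root <- config$data$out_dir %||% stop("config$data$out_dir required",
                                            call. = FALSE)

  cfg_for_hash <- config
  cfg_for_hash$data$sources <- NULL; cfg_for_hash$data$targets <- NULL
  tmp <- tempfile(); on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE,
                              force = TRUE), tmp)
  hash <- substr(unname(tools::md5sum(tmp)), 1, 12)
  out_dir <- file.path(out_root, hash)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "workflow.log.jsonl")

  as_manifest <- function(x) if (is.character(x)) load_manifest(x) else x
  sources <- lapply(config$data$sources, as_manifest)
  targets <- lapply(config$data$targets, as_manifest)

  model_cfg <- do.call(classifier_config, config$model %||% list())
  crop <- crop_spec(window_side = config$crop$window_side %||% 250L,
                    network_input_side = model_cfg$input_side)
  train_cfg <- do.call(train_config,
                       c(config$train %||% list(), list(seed = seed)))
  ft_cfg <- do.call(train_config,
                    c(config$finetune_train %||% list(),
                      list(seed = child_seed(seed, 2) %% 2^30)))
  color_on <- config$color$enabled %||% TRUE

  # stage: reference statistics
  t0 <- as.numeric(Sys.time())
  source_manifest <- do.call(rbind, sources)
  color_ref <- NULL
  if (color_on) {
    color_ref <- manifest_color_stats(source_manifest, crop)
    write_color_stats(color_ref, file.path(out_dir,
                                           "reference_stats.json"))
  }
  .log_stage(log_path, "reference_stats", seed, t0)

  # stage: source training
  t0 <- as.numeric(Sys.time())
  bundle <- build_classifier(model_cfg, seed = seed)
  fit <- train_source(bundle, sources, train_cfg, color_ref = color_ref,
                      crop = crop)
  bundle <- fit$bundle
  src_dir <- file.path(out_dir, "source_bundle")
  save_classifier(bundle, src_dir)
  write.csv(fit$history, file.path(out_dir, "source_history.csv"),
            row.names = FALSE)
  .log_stage(log_path, "source_train", seed, t0,
             list(n_steps = fit$n_steps))

  # stage: per-target fine-tune + evaluate
  reports <- list()
  for (ti in seq_along(targets)) {
    t0 <- as.numeric(Sys.time())
    tgt <- targets[[ti]]
    tgt_id <- tgt$dataset_id[1] %||% sprintf("target%d", ti)
    tdir <- file.path(out_dir, "targets", tgt_id)
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    split <- select_fewshot(tgt,
                            budget_rule = config$finetune$budget_rule %||%
                              "default",
                            seed = child_seed(seed, 50 + ti))
    save_split(split, file.path(tdir, "split.csv"))
    ft <- finetune(bundle, tgt, split, ft_cfg,
                   mode = config$finetune$mode %||% "full",
                   color_ref = color_ref, crop = crop)
    save_classifier(ft$bundle, file.path(tdir, "bundle"))
    eval_manifest <- tgt[match(split$eval_ids, manifest_ids(tgt)), ,
                         drop = FALSE]
    report <- evaluate_classifier(ft$bundle, eval_manifest,
                                  color_ref = color_ref, crop = crop,
                                  n_boot = config$eval$n_boot %||% 1000L,
                                  level = config$eval$level %||% 0.95,
                                  seed = child_seed(seed, 70 + ti))
    jsonlite::write_json(list(
      dataset_id = tgt_id, n = report$n, accuracy = report$accuracy,
      macro_precision = report$macro_precision,
      macro_recall = report$macro_recall,
      ci = as.numeric(report$ci), per_class = report$per_class,
      budget = split$budget_rule$budget),
      file.path(tdir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    reports[[tgt_id]] <- file.path(tdir, "report.json")
    .log_stage(log_path, "finetune_evaluate", seed, t0,
               list(target = tgt_id, budget = split$budget_rule$budget,
                    accuracy = report$accuracy))
  }

  list(out_dir = out_dir,
       reference_stats = if (color_on)
         file.path(out_dir, "reference_stats.json"),
       source_bundle = src_dir, reports = reports, log = log_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
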