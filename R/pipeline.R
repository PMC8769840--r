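#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline in one nested list; every module
#' reads its section. Round-trips losslessly through YAML via
#' [write_config()] / [read_config()].
#'
#' @param ... Named overrides for top-level sections, e.g.
#'   `segmentation = list(seed = 1)` (merged into the defaults).
#' @return List of class `wbc_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    segmentation = list(seed = 0L, min_area_frac = 0.001, n_sample = 5000L),
    sift = list(n_octaves = 4L, n_levels = 5L, sigma0 = 1.6,
                contrast_thr = 0.03, edge_ratio = 10),
    cnn = list(n_filters = 8L, hidden = 32L, lr = 0.01, epochs = 10L,
               batch = 16L, seed = 0L, crop_size = 48L),
    classifier = list(t = 0.01, k = 2, gamma = 0.01, M = NULL),
    metrics = list(rde_variant = "rms"),
    cv = list(folds = 5L, seed = 0L)
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "wbc_config")
}

# Recursive merge that refuses keys absent from the defaults.
merge_config <- function(base, upd, path = character()) {
  for (nm in names(upd)) {
    here <- paste(c(path, nm), collapse = "$")
    if (!nm %in% names(base)) stop("unknown config key: ", here, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]], c(path, nm))
    } else {
      base[nm] <- upd[nm]  # [ ] keeps NULL assignments
    }
  }
  base
}

#' Write a configuration to YAML
#'
#' @param cfg A `wbc_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "wbc_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return List of class `wbc_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(pipeline_config()), raw)
  structure(cfg, class = "wbc_config")
}

#' Hash of a configuration
#'
#' MD5 of the canonical YAML serialization; recorded in every run report so
#' results can be traced to the exact configuration.
#'
#' @param cfg A `wbc_config`.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(cfg, f)
  unname(tools::md5sum(f))
}

#' Crop each segmented nucleus from an image
#'
#' One square crop per 8-connected mask component, centered on the component
#' centroid with a side covering the component bounding box plus a margin,
#' zero-padded where it leaves the image (cells at the border are kept), and
#' resized to `size x size` by bilinear interpolation.
#'
#' @param img RGB array (0--255) or grayscale matrix in `[0, 1]`.
#' @param mask Logical nucleus mask of matching shape.
#' @param size Output crop side length.
#' @param margin Extra pixels around the bounding box before resizing.
#' @return List with `crops` (list of `size x size` grayscale matrices in
#'   `[0, 1]`) and `info` (tibble: component id, centroid `row`/`col`
#'   (0-based), area).
#' @export
crop_cells <- function(img, mask, size = 48L, margin = 4L) {
  gray <- as_gray(img)
  stopifnot(identical(dim(gray), dim(mask)))
  lab <- label_components(mask)
  n <- max(lab)
  crops <- list()
  info <- list()
  for (comp in seq_len(n)) {
    idx <- which(lab == comp, arr.ind = TRUE)
    ctr_r <- mean(idx[, 1L]); ctr_c <- mean(idx[, 2L])
    side <- max(max(idx[, 1L]) - min(idx[, 1L]),
                max(idx[, 2L]) - min(idx[, 2L])) + 1L + 2L * margin
    half <- side / 2
    rows <- round(ctr_r - half + 0.5):(round(ctr_r - half + 0.5) + side - 1L)
    cols <- round(ctr_c - half + 0.5):(round(ctr_c - half + 0.5) + side - 1L)
    patch <- matrix(0, side, side)
    rin <- rows >= 1L & rows <= nrow(gray)
    cin <- cols >= 1L & cols <= ncol(gray)
    patch[rin, cin] <- gray[rows[rin], cols[cin]]
    crops[[comp]] <- resize_bilinear(patch, size)
    info[[comp]] <- tibble::tibble(component = comp, row = ctr_r - 1,
                                   col = ctr_c - 1, area = nrow(idx))
  }
  list(crops = crops,
       info = if (n > 0L) dplyr::bind_rows(info) else
         tibble::tibble(component = integer(), row = numeric(),
                        col = numeric(), area = integer()))
}

# Bilinear square resize (EBImage does the interpolation).
resize_bilinear <- function(m, size) {
  out <- EBImage::resize(m, w = size, h = size, filter = "bilinear")
  matrix(as.numeric(out), size, size)
}

#' Resize a grayscale crop to a square side length
#'
#' Bilinear interpolation; used to bring externally supplied crops to the
#' network's input size.
#'
#' @param m Grayscale matrix in `[0, 1]`.
#' @param size Output side length.
#' @return `size x size` matrix.
#' @export
resize_crop <- function(m, size) {
  stopifnot(is.matrix(m), size >= 1L)
  resize_bilinear(m, as.integer(size))
}

#' Run the full pipeline over a directory of images
#'
#' For every `img_*.png` in `image_dir`: segment the nuclei, score the mask
#' against `mask_*.png` ground truth when present, and crop each nucleus.
#' When a `labels.csv` (columns `image`, `label`) is present and at least
#' two classes occur, the crops are evaluated by stratified cross-validation:
#' within each fold a CNN feature extractor is trained on the training
#' crops, every crop is encoded by its CNN features fused with pooled SIFT
#' descriptors, and a WTPTSSR classifier fit on the training fold predicts
#' the held-out fold. Deterministic given the configuration; failures on
#' single images are logged and skipped.
#'
#' @param image_dir Directory of input images (`img_*.png`, optional
#'   `mask_*.png`, optional `labels.csv`).
#' @param config A `wbc_config`.
#' @param out_dir Output directory for masks, reports and predictions.
#' @return Object of class `wbc_run_report`: list with `metrics` (tibble),
#'   `confusion`, `accuracy`, `fold_accuracy`, `n_images`, `failures`,
#'   `version`, `config_hash`.
#' @export
run_pipeline <- function(image_dir, config = pipeline_config(),
                         out_dir = file.path(image_dir, "wbc_out")) {
  stopifnot(inherits(config, "wbc_config"), dir.exists(image_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  imgs <- sort(list.files(image_dir, pattern = "^img_.*\\.png$",
                          full.names = TRUE))
  if (length(imgs) == 0L) stop("no img_*.png files in ", image_dir, call. = FALSE)
  labels_path <- file.path(image_dir, "labels.csv")
  label_map <- if (file.exists(labels_path)) {
    lb <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    stats::setNames(lb$label, lb$image)
  } else NULL

  seg <- config$segmentation
  metric_rows <- list()
  all_crops <- list(); crop_labels <- character(); failures <- character()
  for (path in imgs) {
    base <- basename(path)
    t0 <- Sys.time()
    res <- tryCatch({
      img <- read_rgb(path)
      mask <- segment_nucleus(img, seed = seg$seed,
                              min_area_frac = seg$min_area_frac,
                              n_sample = seg$n_sample,
                              on_no_contrast = "empty")
      write_mask_png(mask, file.path(out_dir, sub("^img_", "autoseg_", base)))
      manual_path <- file.path(image_dir, sub("^img_", "mask_", base))
      if (file.exists(manual_path)) {
        manual <- read_mask_png(manual_path)
        metric_rows[[base]] <- dplyr::mutate(
          evaluate_masks(mask, manual, config$metrics$rde_variant),
          image = base, .before = 1L)
      }
      cc <- crop_cells(img, mask, size = config$cnn$crop_size)
      if (!is.null(label_map) && base %in% names(label_map) &&
          length(cc$crops) > 0L) {
        all_crops <- c(all_crops, cc$crops)
        crop_labels <- c(crop_labels,
                          rep(label_map[[base]], length(cc$crops)))
      }
      TRUE
    }, error = function(e) {
      message("skipping ", base, ": ", conditionMessage(e))
      failures <<- c(failures, base)
      FALSE
    })
    message(sprintf("%s: %s (%.2fs)", base,
                    if (res) "ok" else "failed",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  metrics <- dplyr::bind_rows(metric_rows)
  if (nrow(metrics) > 0L) {
    utils::write.csv(metrics, file.path(out_dir, "segmentation_metrics.csv"),
                     row.names = FALSE)
  }

  confusion <- NULL; accuracy <- NA_real_; fold_acc <- NULL
  if (length(all_crops) > 0L && length(unique(crop_labels)) >= 2L) {
    cls <- classify_crops_cv(all_crops, factor(crop_labels), config)
    confusion <- cls$confusion
    accuracy <- cls$accuracy
    fold_acc <- cls$fold_accuracy
    utils::write.csv(cls$predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  report <- structure(list(metrics = metrics, confusion = confusion,
                           accuracy = accuracy, fold_accuracy = fold_acc,
                           n_images = length(imgs), failures = failures,
                           version = as.character(utils::packageVersion("wbcpipe")),
                           config_hash = config_hash(config)),
                      class = "wbc_run_report")
  summary_path <- file.path(out_dir, "run_report.csv")
  utils::write.csv(tibble::tibble(
    n_images = report$n_images, n_failures = length(failures),
    mean_ts = if (nrow(metrics)) mean(metrics$ts) else NA_real_,
    accuracy = accuracy, version = report$version,
    config_hash = report$config_hash
  ), summary_path, row.names = FALSE)
  report
}

# Per-fold CNN training + WTPTSSR classification of labeled crops.
classify_crops_cv <- function(crops, labels, config) {
  folds <- min(config$cv$folds, min(table(labels)))
  folds <- max(folds, 2L)
  fold_id <- stratified_folds(labels, folds, config$cv$seed)
  cnn_cfg <- config$cnn
  cls_cfg <- config$classifier
  sift_cfg <- config$sift
  sift_feats <- lapply(crops, function(cr) {
    kp <- sift_extract(cr, n_octaves = sift_cfg$n_octaves,
                       n_levels = sift_cfg$n_levels, sigma0 = sift_cfg$sigma0,
                       contrast_thr = sift_cfg$contrast_thr,
                       edge_ratio = sift_cfg$edge_ratio)
    descriptor_matrix(kp)
  })
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    fit <- cnn_train(crops[tr], labels[tr],
                     n_filters = cnn_cfg$n_filters, hidden = cnn_cfg$hidden,
                     lr = cnn_cfg$lr, epochs = cnn_cfg$epochs,
                     batch = cnn_cfg$batch, seed = cnn_cfg$seed)
    feats <- function(ids) {
      t(vapply(ids, function(i) {
        fuse_features(cnn_forward(as_channel_array(crops[[i]]), fit$params,
                                  mode = "feature"),
                      sift_feats[[i]])
      }, numeric(256L + cnn_cfg$hidden)))
    }
    Xtr <- feats(tr); Xte <- feats(te)
    keep <- colSums(abs(Xtr)) > 0  # drop all-zero features (dead units)
    if (!any(keep)) keep[1] <- TRUE
    args <- list(A = t(Xtr[, keep, drop = FALSE]), labels = labels[tr],
                 t = cls_cfg$t, k = cls_cfg$k, gamma = cls_cfg$gamma)
    if (!is.null(cls_cfg$M)) args$M <- cls_cfg$M
    w <- do.call(wtptssr, args)
    pred[te] <- predict(w, t(Xte[, keep, drop = FALSE]))
  }
  list(confusion = table(true = labels, predicted = pred),
       accuracy = mean(pred == labels),
       fold_accuracy = tibble::tibble(
         fold = seq_len(folds),
         accuracy = vapply(seq_len(folds), function(f) {
           mean(pred[fold_id == f] == labels[fold_id == f])
         }, numeric(1))),
       predictions = tibble::tibble(crop = seq_along(labels), true = labels,
                                    predicted = pred, fold = fold_id))
}

#' @export
print.wbc_run_report <- function(x, ...) {
  cat("WBC pipeline run report (wbcpipe ", x$version, ")\n", sep = "")
  cat("images:", x$n_images, " failures:", length(x$failures), "\n")
  if (nrow(x$metrics) > 0L) {
    cat(sprintf("segmentation: mean TS %.2f, mean RDE %.3f, mean ER %.4f over %d images\n",
                mean(x$metrics$ts), mean(x$metrics$rde), mean(x$metrics$er),
                nrow(x$metrics)))
  }
  if (!is.null(x$confusion)) {
    cat(sprintf("classification accuracy: %.4f\n", x$accuracy))
    print(x$confusion)
  }
  cat("config:", x$config_hash, "\n")
  invisible(x)
}

#' @export
tidy.wbc_run_report <- function(x, ...) x$metrics

#' @export
glance.wbc_run_report <- function(x, ...) {
  tibble::tibble(
    n_images = x$n_images,
    mean_ts = if (nrow(x$metrics)) mean(x$metrics$ts) else NA_real_,
    mean_rde = if (nrow(x$metrics)) mean(x$metrics$rde) else NA_real_,
    mean_er = if (nrow(x$metrics)) mean(x$metrics$er) else NA_real_,
    accuracy = x$accuracy,
    config_hash = x$config_hash
  )
}
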