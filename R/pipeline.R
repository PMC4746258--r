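# DataRawCompile schema helpers -------------------------------------------

# widen per-quadrant measures into the documented compiled-file schema:
# ROI-kind-major (C, L, W), then quadrant 1-4, stats mean/std/size per
# quadrant, e.g. C_mean_1, C_std_1, C_size_1, C_mean_2, ...
widen_quadrant_measures <- function(qm) {
  ordered_cols <- as.vector(t(outer(
    c("C", "L", "W"),
    as.vector(t(outer(1:4, c("mean", "std", "size"),
                      function(q, s) paste0(s, "_", q)))),
    paste, sep = "_")))
  qm |>
    tidyr::pivot_wider(
      id_cols = "cell_id",
      names_from = c("roi", "quadrant"),
      values_from = c("mean", "std", "size"),
      names_glue = "{roi}_{.value}_{quadrant}"
    ) |>
    dplyr::select("cell_id", dplyr::all_of(ordered_cols))
}

#' Quantify a single image with a trained classifier
#'
#' The per-image flow of the quantification stage: segment the counterstain
#' channel, compute the 22 features, classify with confidence scores,
#' background-correct the immunofluorescence channel, measure it per cell /
#' ROI kind / quadrant, and derive the per-cell fluorescence measures.
#'
#' @param image A [two_channel_image()].
#' @param center_xy Tissue center in pixels.
#' @param model A `cell_classifier`.
#' @param params A [segmentation_params()].
#' @return List with `seg`, `frame`, `features`, `predictions`,
#'   `quadrant_measures`, `derived`, and `cells` — the joined per-cell
#'   table in the compiled-file schema (class, confidence, features,
#'   wide quadrant measures, derived measures).
#' @export
quantify_image <- function(image, center_xy, model,
                           params = segmentation_params()) {
  seg <- segment_cells(image, params)
  frame <- tissue_frame(center_xy, image$pixel_size_um)
  features <- compute_feature_table(seg, attr(seg, "smoothed"), frame)
  preds <- predict_with_confidence(model, features)
  corrected <- background_correct(image$signal, seg$roic)
  quad <- suppressWarnings(assign_quadrants(seg, frame))
  qm <- quantify_roi_quadrants(corrected, seg, quad, frame)
  derived <- derive_measures(qm)
  cells <- preds[, c("cell_id", "class", "confidence")] |>
    dplyr::inner_join(features, by = "cell_id") |>
    dplyr::left_join(widen_quadrant_measures(qm), by = "cell_id") |>
    dplyr::left_join(derived, by = "cell_id")
  list(seg = seg, frame = frame, features = features, predictions = preds,
       quadrant_measures = qm, derived = derived, cells = cells)
}

# validate the images table used by the pipeline entry points
check_images_table <- function(images) {
  need <- c("image_id", "path", "center_x", "center_y")
  if (!all(need %in% names(images)))
    rc_abort(sprintf("images table must have columns: %s",
                     paste(need, collapse = ", ")), "rc_config_error")
  bad <- !is.finite(images$center_x) | !is.finite(images$center_y)
  if (any(bad))
    rc_abort(sprintf("missing tissue center for image(s): %s",
                     paste(images$image_id[bad], collapse = ", ")),
             "rc_config_error")
  invisible(images)
}

#' Run the training-set development stage
#'
#' Segments each training image, builds its feature table, trains the
#' Random Forest on the annotated cells, writes classification overlays at
#' 50/70/90% confidence (optional), and stores the iteration — model,
#' parameters and seed — in a time-stamped folder so it can be reproduced
#' and applied to test images.
#'
#' @param images Tibble with columns `image_id`, `path` (two-channel TIFF),
#'   `center_x`, `center_y`.
#' @param annotations Tibble (`image_id`, `cell_id`, `class`) or path to
#'   such a CSV.
#' @param pixel_size_um Pixel size of the images.
#' @param params A [segmentation_params()].
#' @param feature_subset Features to train on
#'   (default [default_feature_subset()]).
#' @param n_trees,seed Forest size and mandatory seed.
#' @param out_root Folder in which to create the iteration folder.
#' @param iteration_id Folder/iteration name; defaults to a time-stamped id.
#' @param plots Write per-image classification overlay PNGs at 50/70/90%.
#' @return A `training_iteration` list: `iteration_id`, `out_dir`,
#'   `model_path`, `params`, `feature_subset`, `class_names`, `seed`,
#'   `pixel_size_um`, `images`, and the fitted `model`.
#' @export
run_training <- function(images, annotations, pixel_size_um,
                         params = segmentation_params(),
                         feature_subset = default_feature_subset(),
                         n_trees = 500, seed, out_root = tempdir(),
                         iteration_id = NULL, plots = TRUE) {
  check_images_table(images)
  if (is.character(annotations))
    annotations <- readr::read_csv(annotations, show_col_types = FALSE)
  if (is.null(iteration_id))
    iteration_id <- paste0("iteration_",
                           format(Sys.time(), "%Y-%m-%dT%H-%M-%OS3"))
  out_dir <- file.path(out_root, iteration_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  per_image <- purrr::map(seq_len(nrow(images)), function(i) {
    id <- images$image_id[i]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) rc_abort(
        sprintf("stage '%s' failed for image '%s': %s",
                what, id, conditionMessage(e)), "rc_stage_error"))
    }
    img <- stage("load", load_two_channel_image(images$path[i],
                                                pixel_size_um))
    seg <- stage("segment", segment_cells(img, params))
    frame <- tissue_frame(c(images$center_x[i], images$center_y[i]),
                          pixel_size_um)
    feats <- stage("features",
                   compute_feature_table(seg, attr(seg, "smoothed"), frame))
    list(image_id = id, image = img, seg = seg,
         features = dplyr::bind_cols(tibble::tibble(image_id = id), feats))
  })
  features <- dplyr::bind_rows(purrr::map(per_image, "features"))
  model <- train_random_forest(features, annotations,
                               feature_subset = feature_subset,
                               n_trees = n_trees, seed = seed,
                               iteration_id = iteration_id)
  model_path <- file.path(out_dir, "model.rds")
  saveRDS(model, model_path)

  if (plots) {
    for (pi in per_image) {
      preds <- predict_with_confidence(model, pi$features)
      for (th in c(0.5, 0.7, 0.9)) {
        render_classification_overlay(
          pi$image$reference, pi$seg$roic,
          filter_by_confidence(preds, th), model$class_names,
          path = file.path(out_dir, sprintf("%s_classified_%02d.png",
                                            pi$image_id, round(th * 100))))
      }
    }
  }

  iteration <- list(
    iteration_id = iteration_id, out_dir = out_dir,
    model_path = model_path,
    params = params, feature_subset = feature_subset,
    class_names = model$class_names, seed = seed,
    pixel_size_um = pixel_size_um,
    images = images, model = model
  )
  jsonlite::write_json(
    list(iteration_id = iteration_id, model_path = model_path,
         smoothing_variance_px = params$smoothing_variance_px,
         merge_depth_threshold = params$merge_depth_threshold,
         feature_subset = feature_subset, seed = seed,
         pixel_size_um = pixel_size_um,
         images = as.data.frame(images)),
    file.path(out_dir, "iteration.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  class(iteration) <- "training_iteration"
  iteration
}

#' Load a stored training iteration
#' @param path Iteration folder (containing `iteration.json`).
#' @return A `training_iteration`.
#' @export
read_training_iteration <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "iteration.json"),
                              simplifyVector = TRUE)
  iteration <- list(
    iteration_id = meta$iteration_id, out_dir = path,
    model_path = meta$model_path,
    params = segmentation_params(meta$smoothing_variance_px,
                                 meta$merge_depth_threshold),
    feature_subset = meta$feature_subset, seed = meta$seed,
    pixel_size_um = meta$pixel_size_um,
    images = tibble::as_tibble(meta$images),
    model = readRDS(meta$model_path)
  )
  iteration$class_names <- iteration$model$class_names
  class(iteration) <- "training_iteration"
  iteration
}

#' Run the image-quantification stage
#'
#' Processes each test image with the segmentation parameters of the chosen
#' training iteration: segmentation, features, classification with
#' confidence scores, background-corrected channel-2 quantification per
#' quadrant, and derived measures; writes one per-cell CSV per image and,
#' when a catalogue is given, registers it there.
#'
#' @param images Tibble (`image_id`, `path`, `center_x`, `center_y`).
#' @param iteration A `training_iteration` (or folder path).
#' @param catalog Optional `experiment_catalog` to register outputs in.
#' @param out_dir Folder for the per-image CSVs (defaults to the
#'   iteration folder).
#' @param plots Write classification overlay PNGs at 50/70/90%.
#' @return List: `results` (named list of [quantify_image()] outputs),
#'   `paths` (per-image CSV paths), `catalog` (updated or `NULL`).
#' @export
run_quantification <- function(images, iteration, catalog = NULL,
                               out_dir = NULL, plots = FALSE) {
  check_images_table(images)
  if (is.character(iteration)) iteration <- read_training_iteration(iteration)
  if (is.null(out_dir)) out_dir <- iteration$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- iteration$model

  results <- list()
  paths <- character()
  for (i in seq_len(nrow(images))) {
    id <- images$image_id[i]
    img <- load_two_channel_image(images$path[i], iteration$pixel_size_um)
    res <- quantify_image(img, c(images$center_x[i], images$center_y[i]),
                          model, iteration$params)
    csv <- file.path(out_dir, paste0(id, "_quantified.csv"))
    readr::write_csv(res$cells, csv)
    if (plots) {
      for (th in c(0.5, 0.7, 0.9)) {
        render_classification_overlay(
          img$reference, res$seg$roic,
          filter_by_confidence(res$predictions, th), model$class_names,
          path = file.path(out_dir, sprintf("%s_classified_%02d.png",
                                            id, round(th * 100))))
      }
    }
    if (!is.null(catalog))
      catalog <- catalog_register_output(catalog, id, "quantified", csv)
    results[[id]] <- res
    paths[id] <- csv
  }
  list(results = results, paths = paths, catalog = catalog)
}

#' Run the data assembly stage
#'
#' Concatenates the registered per-image quantified tables into the
#' compiled per-cell file (see [export_compiled_data()]) and computes
#' per-class summaries for plotting.
#'
#' @param catalog An `experiment_catalog` with registered quantified
#'   outputs.
#' @param factor_filter Named list of metadata factors to allowed tokens.
#' @param confidence Confidence threshold for the per-class summary.
#' @param out Output CSV path (default `DataRawCompile.csv` in the
#'   catalogue folder).
#' @return List: `compiled` (per-cell tibble), `summary` (per-class
#'   tibble from [summarize_by_class()]).
#' @export
run_assembly <- function(catalog, factor_filter = NULL, confidence = 0.7,
                         out = NULL) {
  compiled <- export_compiled_data(catalog, factor_filter, out)
  derived_cols <- c("LumenRPA", "Lumensignal", "PvD", "WallRPA",
                    "Wallsignal", "CellRPA", "Cellsignal", "LumenRPAmean",
                    "Lumensignalmean", "WallRPAmean", "Wallsignalmean",
                    "CellRPAmean")
  summary <- summarize_by_class(
    compiled[, c("image_id", "cell_id",
                 intersect(derived_cols, names(compiled)), "s.area")],
    compiled[, c("image_id", "cell_id", "class", "confidence")],
    threshold = confidence
  )
  list(compiled = compiled, summary = summary)
}
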