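#' Train a Random Forest cell-type classifier
#'
#' Fits a Breiman Random Forest on annotated cells using untransformed
#' feature values (no scaling or normalisation — untransformed inputs give
#' the best fit for this classifier family) and records out-of-bag
#' permutation importance per feature alongside impurity-based importance.
#' The fit is fully reproducible from the recorded seed.
#'
#' @param features Feature table: tibble with `cell_id`, optionally
#'   `image_id`, and the feature columns (see [compute_feature_table()]).
#'   Multiple images' tables can be row-bound.
#' @param annotations Tibble with `cell_id`, `class` and, when `features`
#'   spans several images, `image_id`. Each annotated cell must resolve to
#'   exactly one feature row.
#' @param feature_subset Character vector of feature names to train on;
#'   defaults to the 18-feature set of [default_feature_subset()].
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; mandatory, recorded in the model.
#' @param class_names Optional explicit class list (>= 2 entries); every
#'   class must have at least one annotated cell. Defaults to the classes
#'   present in `annotations`.
#' @param iteration_id Optional training-iteration identifier stored with
#'   the model.
#' @return A `cell_classifier` object.
#' @export
train_random_forest <- function(features, annotations,
                                feature_subset = default_feature_subset(),
                                n_trees = 500, seed,
                                class_names = NULL, iteration_id = NULL) {
  if (missing(seed))
    rc_abort("`seed` is mandatory for reproducible training",
             "rc_param_error")
  feature_subset <- normalize_feature_names(feature_subset)
  if (length(feature_subset) < 1L)
    rc_abort("`feature_subset` must name at least one feature",
             "rc_feature_error")
  keys <- intersect(c("image_id", "cell_id"), names(annotations))
  joined <- dplyr::inner_join(annotations, features, by = keys)
  if (nrow(joined) < nrow(annotations))
    rc_abort("some annotations do not resolve to a feature-table row",
             "rc_annotation_error")
  if (is.null(class_names)) class_names <- sort(unique(annotations$class))
  if (length(class_names) < 2L)
    rc_abort("need at least 2 cell-type classes", "rc_annotation_error")
  missing_cls <- setdiff(class_names, joined$class)
  if (length(missing_cls) > 0)
    rc_abort(sprintf("class(es) with no annotated cells: %s",
                     paste(missing_cls, collapse = ", ")),
             "rc_annotation_error")
  x <- as.data.frame(joined[, feature_subset])
  y <- factor(joined$class, levels = class_names)
  forest <- withr::with_seed(seed,
    randomForest::randomForest(x = x, y = y, ntree = n_trees,
                               importance = TRUE))
  imp <- randomForest::importance(forest)
  importances <- tibble::tibble(
    feature = rownames(imp),
    permutation = as.numeric(imp[, "MeanDecreaseAccuracy"]),
    impurity = as.numeric(imp[, "MeanDecreaseGini"])
  )
  structure(
    list(forest = forest, feature_subset = feature_subset,
         class_names = class_names, importances = importances,
         n_trees = n_trees, seed = seed,
         n_training_cells = nrow(joined),
         oob_error = as.numeric(forest$err.rate[n_trees, "OOB"]),
         iteration_id = iteration_id),
    class = "cell_classifier"
  )
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf(
    "<cell_classifier> %d trees, %d features, %d classes, %d training cells\n",
    x$n_trees, length(x$feature_subset), length(x$class_names),
    x$n_training_cells))
  cat(sprintf("  OOB error: %.3f; seed %d\n", x$oob_error, x$seed))
  invisible(x)
}

#' Rank features by out-of-bag permutation importance
#'
#' @param model A `cell_classifier`.
#' @return Tibble (`feature`, `permutation`, `impurity`) sorted by
#'   descending permutation importance; ties broken by canonical feature
#'   order.
#' @export
rank_feature_importance <- function(model) {
  model$importances |>
    dplyr::arrange(dplyr::desc(.data$permutation),
                   match(.data$feature, feature_names()))
}

#' Predict cell types with per-cell confidence scores
#'
#' Every cell is classified; the confidence score is the fraction of trees
#' voting for the winning class (vote fractions over classes sum to 1).
#' Ties between classes resolve to the earlier class in the model's class
#' list.
#'
#' @param model A `cell_classifier`.
#' @param features Feature table containing every feature in
#'   `model$feature_subset` (extra columns are ignored).
#' @return Tibble with `cell_id` (and `image_id` if present in
#'   `features`), `class`, `confidence`, plus one `vote_<class>` column per
#'   class.
#' @export
predict_with_confidence <- function(model, features) {
  missing_cols <- setdiff(model$feature_subset, names(features))
  if (length(missing_cols) > 0)
    rc_abort(sprintf("feature table lacks model feature(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "rc_feature_error")
  x <- as.data.frame(features[, model$feature_subset])
  votes <- stats::predict(model$forest, newdata = x, type = "vote")
  votes <- votes[, model$class_names, drop = FALSE]
  win <- max.col(votes, ties.method = "first")
  keys <- intersect(c("image_id", "cell_id"), names(features))
  out <- dplyr::bind_cols(
    features[, keys],
    tibble::tibble(class = model$class_names[win],
                   confidence = votes[cbind(seq_len(nrow(votes)), win)])
  )
  vote_cols <- tibble::as_tibble(as.data.frame(votes))
  names(vote_cols) <- paste0("vote_", model$class_names)
  dplyr::bind_cols(out, vote_cols)
}

#' Filter predictions by confidence score
#'
#' Retains cells whose winning-class vote fraction is at least
#' `threshold`; the retained sets are nested across increasing thresholds.
#'
#' @param preds Predictions from [predict_with_confidence()].
#' @param threshold Confidence threshold in \[0, 1\] (e.g. 0.5, 0.7, 0.9).
#' @return The retained subset of `preds`.
#' @export
filter_by_confidence <- function(preds, threshold) {
  if (threshold < 0 || threshold > 1)
    rc_abort("`threshold` must be in [0, 1]", "rc_param_error")
  dplyr::filter(preds, .data$confidence >= threshold)
}

#' @describeIn train_random_forest Per-feature importance scores as a tidy
#'   tibble (broom-style), ranked as in [rank_feature_importance()].
#' @param x A `cell_classifier`.
#' @param ... Unused.
#' @export
tidy.cell_classifier <- function(x, ...) {
  rank_feature_importance(x)
}

#' @describeIn train_random_forest One-row model summary: number of trees,
#'   features, classes, training cells, and out-of-bag error.
#' @export
glance.cell_classifier <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    n_features = length(x$feature_subset),
    n_classes = length(x$class_names),
    n_training_cells = x$n_training_cells,
    oob_error = x$oob_error
  )
}

#' Seed feature list for a reduced classification subset
#'
#' Compact feature sets retain most classification power in radially
#' organised tissue; the radial coordinate, the median wall and cell
#' intensities, and the cell area are the consistently top-ranked features
#' and form the seed of a 5-feature iteration. The final membership of
#' reduced subsets is the user's choice (drop features judged redundant
#' after inspecting importance ranks and spatial feature maps).
#'
#' @return Character vector of the four seed feature names.
#' @export
reduced_subset_seed <- function() {
  c("radialV", "MedianROIW", "MedianROIC", "s.area")
}
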