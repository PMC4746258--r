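# Diagnostic rendering ----------------------------------------------------

# distinct colors for cell labels, deterministic
label_palette <- function(n) {
  grDevices::hcl(h = (seq_len(n) * 137.508) %% 360,
                 c = 70, l = 60)
}

# grayscale RGB array (rows x cols x 3) from a raster
raster_to_rgb <- function(raster) {
  rng <- range(raster)
  g <- if (rng[2] > rng[1]) (raster - rng[1]) / (rng[2] - rng[1])
       else raster * 0
  array(rep(g, 3), c(dim(raster), 3))
}

blend_labels <- function(rgb, labels, colors, alpha = 0.55) {
  pos <- which(labels > 0)
  if (length(pos) == 0) return(rgb)
  cmat <- t(grDevices::col2rgb(colors)) / 255
  npix <- length(labels)
  for (k in 1:3) {
    plane <- rgb[, , k]
    plane[pos] <- (1 - alpha) * plane[pos] + alpha * cmat[labels[pos], k]
    rgb[, , k] <- plane
  }
  rgb
}

#' Write a random-color cell-segmentation overlay PNG
#'
#' Counterstain channel in grayscale with each cell's ROIC footprint
#' blended in a distinct color.
#'
#' @param reference Counterstain raster.
#' @param roic ROIC label map.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_segmentation_overlay <- function(reference, roic, path) {
  n <- max(roic)
  rgb <- raster_to_rgb(reference)
  if (n > 0) rgb <- blend_labels(rgb, roic, label_palette(n))
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write a classification overlay PNG
#'
#' Counterstain channel in grayscale with retained cells blended in their
#' class color; cells filtered out by confidence stay uncolored.
#'
#' @param reference Counterstain raster.
#' @param roic ROIC label map.
#' @param predictions Predictions (already confidence-filtered as desired).
#' @param class_names Class list fixing the color order.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_classification_overlay <- function(reference, roic, predictions,
                                          class_names, path) {
  class_map <- matrix(0L, nrow(roic), ncol(roic))
  cls_idx <- match(predictions$class, class_names)
  lut <- integer(max(roic, 1L))
  lut[predictions$cell_id] <- cls_idx
  pos <- roic > 0 & roic %in% predictions$cell_id
  class_map[pos] <- lut[roic[pos]]
  rgb <- blend_labels(raster_to_rgb(reference), class_map,
                      label_palette(length(class_names)))
  png::writePNG(rgb, path)
  invisible(path)
}

# ggplot2 surfaces ---------------------------------------------------------

# long pixel tibble of a label map (nonzero pixels)
label_map_tbl <- function(labels, value_name = "label") {
  pos <- which(labels > 0)
  nr <- nrow(labels)
  tibble::tibble(
    x = ((pos - 1L) %/% nr) + 1L,
    y = ((pos - 1L) %% nr) + 1L,
    !!value_name := labels[pos]
  )
}

#' @describeIn cell_segmentation Random-color map of the segmented cells
#'   (ROIC), one color per cell.
#' @param object A `cell_segmentation`.
#' @param ... Unused.
#' @export
autoplot.cell_segmentation <- function(object, ...) {
  d <- label_map_tbl(object$roic)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  fill = factor(.data$label))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = label_palette(max(object$roic)),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Spatial heatmap of a per-cell quantity over the segmentation
#'
#' Paints each cell's ROIC footprint with the value of one feature or
#' derived measure, the spatial-map diagnostic used to judge which
#' features carry tissue-level structure.
#'
#' @param seg A [cell_segmentation()].
#' @param values Tibble with `cell_id` and the column named in `measure`.
#' @param measure Column name to map.
#' @return A ggplot object.
#' @export
plot_feature_map <- function(seg, values, measure) {
  d <- label_map_tbl(seg$roic, "cell_id") |>
    dplyr::inner_join(values[, c("cell_id", measure)], by = "cell_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  fill = .data[[measure]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = measure) +
    ggplot2::theme_void()
}

#' Bar chart of per-class means with standard-deviation error bars
#'
#' @param class_summary Output of [summarize_by_class()].
#' @param measure Which measure to plot (default `"Wallsignal"`).
#' @return A ggplot object.
#' @export
plot_class_summary <- function(class_summary, measure = "Wallsignal") {
  d <- dplyr::filter(class_summary, .data$measure == !!measure)
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn train_random_forest Bar chart of the ranked out-of-bag
#'   permutation importances.
#' @param object A `cell_classifier`.
#' @export
autoplot.cell_classifier <- function(object, ...) {
  d <- rank_feature_importance(object) |>
    dplyr::mutate(feature = factor(.data$feature,
                                   levels = rev(.data$feature)))
  ggplot2::ggplot(d, ggplot2::aes(.data$permutation, .data$feature)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "OOB permutation importance", y = NULL) +
    ggplot2::theme_minimal()
}
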