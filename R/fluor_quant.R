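#' Background-correct the immunofluorescence channel
#'
#' The background estimate is the median intensity over non-tissue pixels
#' (where ROIC = 0); it is subtracted from the whole raster and negative
#' values are clamped to 0. Applied once per image, before any masking.
#'
#' @param signal Immunofluorescence raster.
#' @param roic ROIC label map from the counterstain segmentation.
#' @return Corrected raster with attribute `"background"`.
#' @export
background_correct <- function(signal, roic) {
  if (!identical(dim(signal), dim(roic)))
    rc_abort("signal and label map dimensions differ", "rc_shape_error")
  bg_pix <- signal[roic == 0]
  if (length(bg_pix) == 0L) {
    rc_warn("no background pixels (tissue fills the frame); background = 0",
            "rc_no_background")
    bg <- 0
  } else {
    bg <- median(bg_pix)
  }
  out <- pmax(signal - bg, 0)
  attr(out, "background") <- bg
  out
}

#' Per-cell, per-ROI-kind, per-quadrant signal statistics
#'
#' For every combination of cell, ROI kind (C = whole cell, L = lumen,
#' W = wall) and radial quadrant 1-4, computes the mean, the population
#' (n-denominator) standard deviation, and the area (micrometres squared) of
#' the masked signal pixels. Combinations with no pixels get size 0 and
#' missing mean/std. Cells flagged by [assign_quadrants()] as having no
#' defined radial direction are excluded.
#'
#' @param signal Background-corrected immunofluorescence raster.
#' @param seg A [cell_segmentation()].
#' @param quad Quadrant map from [assign_quadrants()].
#' @param frame A [tissue_frame()] (supplies the pixel size).
#' @return Tibble with columns `cell_id`, `roi` ("C","L","W"),
#'   `quadrant` (1-4), `mean`, `std`, `size` (micrometres squared) and
#'   `n_pixels`.
#' @export
quantify_roi_quadrants <- function(signal, seg, quad, frame) {
  if (!identical(dim(signal), dim(seg$roic)) ||
      !identical(dim(signal), dim(quad)))
    rc_abort("signal, segmentation and quadrant map dimensions differ",
             "rc_shape_error")
  px_area <- frame$pixel_size_um^2
  undefined <- attr(quad, "undefined_cells")
  kinds <- c(C = "roic", L = "roil", W = "roiw")
  parts <- purrr::imap(kinds, function(map_name, kind) {
    lab_map <- seg[[map_name]]
    sel <- lab_map > 0
    tibble::tibble(cell_id = lab_map[sel], roi = kind,
                   quadrant = quad[sel], intensity = signal[sel])
  })
  cells <- segmentation_cell_ids(seg)
  cells <- setdiff(cells, undefined)
  dplyr::bind_rows(parts) |>
    dplyr::filter(.data$quadrant > 0, .data$cell_id %in% cells) |>
    dplyr::group_by(.data$cell_id, .data$roi, .data$quadrant) |>
    dplyr::summarise(
      mean = mean(.data$intensity),
      std = sqrt(mean((.data$intensity - mean(.data$intensity))^2)),
      size = dplyr::n() * px_area,
      n_pixels = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(
      cell_id = cells, roi = c("C", "L", "W"), quadrant = 1:4,
      fill = list(mean = NA_real_, std = NA_real_, size = 0,
                  n_pixels = 0L)
    ) |>
    dplyr::arrange(.data$cell_id, match(.data$roi, c("C", "L", "W")),
                   .data$quadrant)
}

# pooled mean/variance over quadrants from per-quadrant stats, weighted by
# integer pixel counts (exact for uniform input)
pool_quadrants <- function(mean, std, n_pixels) {
  ok <- n_pixels > 0
  n <- sum(n_pixels[ok])
  if (n == 0) return(c(mean = NA_real_, std = NA_real_, size = 0))
  m <- sum(mean[ok] * n_pixels[ok]) / n
  # within + between decomposition (no cancellation for uniform input)
  v <- sum(n_pixels[ok] * std[ok]^2) / n +
    sum(n_pixels[ok] * (mean[ok] - m)^2) / n
  c(mean = m, std = sqrt(v), size = n)
}

#' Derived per-cell fluorescence measures
#'
#' From the per-quadrant statistics, computes for each cell: the ratios of
#' periclinal (quadrants 3 + 4) to anticlinal (1 + 2) signal per ROI kind,
#' both as summed signal (`*RPA` = (mean3 size3 + mean4 size4) /
#' (mean1 size1 + mean2 size2)) and as mean intensity (`*RPAmean` =
#' (mean3 + mean4) / (mean1 + mean2)); the total summed signal per ROI kind
#' (`*signal` = sum over quadrants of mean x size, so `Cellsignal` =
#' `Lumensignal` + `Wallsignal` exactly); the mean intensity per ROI
#' (`*signalmean` = total / area); and `PvD`, the punctateness-versus-
#' diffuseness of the lumen signal, implemented as the coefficient of
#' variation (pooled population std / mean) of the ROIL pixel intensities —
#' 0 for a uniform lumen, large when the signal concentrates in puncta.
#' Measures with a zero denominator are flagged missing (`NA`); the cell
#' row is retained.
#'
#' @param qm Quadrant measures from [quantify_roi_quadrants()].
#' @return Tibble with one row per cell: `cell_id`, `LumenRPA`,
#'   `Lumensignal`, `PvD`, `WallRPA`, `Wallsignal`, `CellRPA`,
#'   `Cellsignal`, `LumenRPAmean`, `Lumensignalmean`, `WallRPAmean`,
#'   `Wallsignalmean`, `CellRPAmean`.
#' @export
derive_measures <- function(qm) {
  one_kind <- function(d) {
    m <- d$mean; s <- d$size
    ok <- s > 0
    m0 <- ifelse(ok, m, 0)
    peri <- sum((m0 * s)[d$quadrant %in% c(3, 4)])
    anti <- sum((m0 * s)[d$quadrant %in% c(1, 2)])
    peri_m <- sum(m0[d$quadrant %in% c(3, 4)])
    anti_m <- sum(m0[d$quadrant %in% c(1, 2)])
    total <- sum(m0 * s)
    area <- sum(s)
    tibble::tibble(
      rpa = if (anti > 0) peri / anti else NA_real_,
      rpa_mean = if (anti_m > 0) peri_m / anti_m else NA_real_,
      total = total,
      signal_mean = if (area > 0) total / area else NA_real_
    )
  }
  qm |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      kc <- one_kind(d[d$roi == "C", ])
      kl <- one_kind(d[d$roi == "L", ])
      kw <- one_kind(d[d$roi == "W", ])
      lum <- d[d$roi == "L", ]
      pl <- pool_quadrants(lum$mean, lum$std, lum$n_pixels)
      pvd <- if (!is.na(pl["mean"]) && pl["mean"] > 0)
        unname(pl["std"] / pl["mean"]) else NA_real_
      tibble::tibble(
        LumenRPA = kl$rpa, Lumensignal = kl$total, PvD = pvd,
        WallRPA = kw$rpa, Wallsignal = kw$total,
        CellRPA = kc$rpa, Cellsignal = kc$total,
        LumenRPAmean = kl$rpa_mean, Lumensignalmean = kl$signal_mean,
        WallRPAmean = kw$rpa_mean, Wallsignalmean = kw$signal_mean,
        CellRPAmean = kc$rpa_mean
      )
    }) |>
    dplyr::ungroup()
}

#' Per-class summaries of derived measures
#'
#' Filters predictions at the given confidence threshold, groups the
#' retained cells by predicted class, and reports the per-class cell count
#' and the mean and standard deviation of every numeric measure (missing
#' values excluded per measure, so each measure uses its own n). Classes
#' with no retained cells are omitted with a message. Optionally each class
#' mean is also expressed relative to the maximum class mean of that
#' measure.
#'
#' @param derived Per-cell measure table ([derive_measures()] output,
#'   optionally joined with feature columns).
#' @param preds Predictions from [predict_with_confidence()].
#' @param threshold Confidence threshold in \[0, 1\].
#' @param relative If `TRUE`, adds `rel_mean` = class mean / max class
#'   mean per measure.
#' @return Long tibble: `class`, `n_cells`, `measure`, `n`, `mean`, `sd`
#'   (and `rel_mean`).
#' @export
summarize_by_class <- function(derived, preds, threshold, relative = FALSE) {
  retained <- filter_by_confidence(preds, threshold)
  if (nrow(retained) == 0L)
    rc_abort("no cells retained at this confidence threshold",
             "rc_empty_result")
  keys <- intersect(c("image_id", "cell_id"), names(derived))
  keys <- intersect(keys, names(preds))
  joined <- dplyr::inner_join(retained[, c(keys, "class")], derived,
                              by = keys)
  dropped <- setdiff(unique(preds$class), unique(joined$class))
  if (length(dropped) > 0)
    message("classes with no retained cells omitted: ",
            paste(dropped, collapse = ", "))
  value_cols <- setdiff(names(joined),
                        c(keys, "class", "confidence"))
  value_cols <- value_cols[vapply(joined[value_cols], is.numeric, TRUE)]
  out <- joined |>
    tidyr::pivot_longer(dplyr::all_of(value_cols), names_to = "measure",
                        values_to = "value") |>
    dplyr::group_by(.data$class, .data$measure) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(measure = factor(.data$measure, levels = value_cols)) |>
    dplyr::arrange(.data$measure, .data$class) |>
    dplyr::mutate(measure = as.character(.data$measure),
                  sd = ifelse(.data$n <= 1, 0, .data$sd))
  if (relative) {
    out <- out |>
      dplyr::group_by(.data$measure) |>
      dplyr::mutate(rel_mean = .data$mean / max(.data$mean, na.rm = TRUE)) |>
      dplyr::ungroup()
  }
  out
}
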