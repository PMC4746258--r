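#' Segmentation parameters
#'
#' @param smoothing_variance_px Variance (pixels squared) of the Gaussian
#'   low-pass applied to the counterstain channel before watershed
#'   segmentation; the default of 1 suits well-stained low-noise sections,
#'   noisier material benefits from a larger value.
#' @param merge_depth_threshold Dam-saliency threshold (intensity units)
#'   below which adjacent watershed regions are merged; default 10.
#' @param crop_region Optional rectangle `c(x0, y0, x1, y1)` in pixel
#'   coordinates; cells whose centroid falls outside are discarded.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(smoothing_variance_px = 1,
                                merge_depth_threshold = 10,
                                crop_region = NULL) {
  if (smoothing_variance_px < 0)
    rc_abort("`smoothing_variance_px` must be >= 0", "rc_param_error")
  if (merge_depth_threshold < 0)
    rc_abort("`merge_depth_threshold` must be >= 0", "rc_param_error")
  structure(list(smoothing_variance_px = smoothing_variance_px,
                 merge_depth_threshold = merge_depth_threshold,
                 crop_region = crop_region),
            class = "segmentation_params")
}

#' Gaussian smoothing of the counterstain channel
#'
#' Separable Gaussian low-pass with the stated variance (sigma =
#' sqrt(variance)), reflective boundary handling, kernel truncated at
#' 4 sigma and renormalised so total intensity is conserved.
#'
#' @param reference Numeric matrix (counterstain raster).
#' @param smoothing_variance_px Variance in pixels squared; 0 is the
#'   identity.
#' @return Smoothed matrix, same shape.
#' @export
smooth_reference <- function(reference, smoothing_variance_px = 1) {
  stopifnot_matrix(reference)
  if (length(reference) == 0L)
    rc_abort("`reference` must be non-empty", "rc_type_error")
  if (smoothing_variance_px < 0)
    rc_abort("smoothing variance must be >= 0", "rc_param_error")
  if (smoothing_variance_px == 0) return(reference)
  sigma <- sqrt(smoothing_variance_px)
  radius <- max(1L, ceiling(4 * sigma))
  kernel <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  kernel <- kernel / sum(kernel)
  reference |>
    convolve_rows_reflect(kernel) |>
    t() |>
    convolve_rows_reflect(kernel) |>
    t()
}

# 1-D convolution along matrix columns (i.e. down each column) with
# reflective padding, vectorised over shifted copies
convolve_rows_reflect <- function(m, kernel) {
  nr <- nrow(m)
  radius <- (length(kernel) - 1L) / 2L
  # reflect indices: 1 2 3 ... padded as 2 1 | 1 2 3 | 3 2 (symmetric,
  # half-sample style via index folding)
  idx <- seq(1L - radius, nr + radius)
  idx <- ifelse(idx < 1L, 1L - idx, idx)
  idx <- ifelse(idx > nr, 2L * nr + 1L - idx, idx)
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, nr, ncol(m))
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * padded[seq(k, k + nr - 1L), , drop = FALSE]
  }
  out
}

#' Minima-seeded watershed segmentation of the counterstain channel
#'
#' Seeds are the regional minima (4-connected equal-value plateaus with no
#' lower neighbour) of the smoothed image; basins grow from the dark cell
#' lumens and dams form on the bright cell walls. Dam pixels are labelled 0.
#' Shallow neighbouring basins are then merged with
#' [merge_shallow_regions()] at `params$merge_depth_threshold`, and labels
#' relabelled to consecutive positive integers.
#'
#' @param smoothed Smoothed counterstain raster (see [smooth_reference()]).
#' @param params A [segmentation_params()].
#' @return Integer label map (ROIC): 0 = dam/background boundary, 1..K =
#'   cells.
#' @export
watershed_cells <- function(smoothed, params = segmentation_params()) {
  stopifnot_matrix(smoothed)
  seeds <- rcpp_regional_minima(smoothed)
  n_min <- max(seeds)
  if (n_min <= 1L) {
    rc_warn("image has a single regional minimum; producing one region",
            "rc_flat_image")
    return(matrix(1L, nrow(smoothed), ncol(smoothed)))
  }
  labels <- rcpp_watershed_flood(smoothed, seeds)
  labels <- merge_shallow_regions(labels, smoothed,
                                  params$merge_depth_threshold)
  labels
}

# dam-pixel adjacency table: one row per (dam pixel, adjacent region) with
# 8-connectivity; columns pix (dam pixel linear index), lab, val
dam_adjacency <- function(labels, smoothed) {
  nr <- nrow(labels); nc <- ncol(labels)
  dams <- which(labels == 0L)
  if (length(dams) == 0L)
    return(tibble::tibble(pix = integer(), lab = integer(), val = numeric()))
  r <- ((dams - 1L) %% nr) + 1L
  c <- ((dams - 1L) %/% nr) + 1L
  parts <- list()
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!any(ok)) next
    nb <- labels[cbind(rr[ok], cc[ok])]
    pos <- nb > 0L
    if (!any(pos)) next
    parts[[length(parts) + 1L]] <-
      tibble::tibble(pix = dams[ok][pos], lab = nb[pos])
  }
  dplyr::bind_rows(parts) |>
    dplyr::distinct() |>
    dplyr::mutate(val = smoothed[.data$pix])
}

#' Merge shallow watershed regions by dam saliency
#'
#' Over-segmentation is corrected by merging adjacent regions whose dam
#' saliency — the minimum intensity over the dam pixels shared by the two
#' regions minus the higher of the two regions' intensity minima — is below
#' `merge_depth_threshold`. Merging is iterative, lowest saliency first
#' (ties broken by lowest label pair), with region minima and adjacency
#' recomputed after every merge; dam pixels left between merged regions are
#' absorbed into the merged label. Labels are relabelled consecutively.
#'
#' @param labels Watershed label map (0 = dam).
#' @param smoothed The raster the watershed was computed on.
#' @param merge_depth_threshold Saliency threshold; regions with saliency
#'   strictly below it merge. 0 merges nothing.
#' @return Merged, consecutively relabelled label map.
#' @export
merge_shallow_regions <- function(labels, smoothed, merge_depth_threshold) {
  if (!identical(dim(labels), dim(smoothed)))
    rc_abort("label map and raster dimensions differ", "rc_shape_error")
  if (merge_depth_threshold < 0)
    rc_abort("`merge_depth_threshold` must be >= 0", "rc_param_error")
  storage.mode(labels) <- "integer"
  n_lab <- max(labels)
  if (n_lab <= 1L || merge_depth_threshold == 0)
    return(relabel_consecutive(labels))

  # region intensity minima
  minv <- rep(Inf, n_lab)
  agg <- tapply(smoothed[labels > 0L], labels[labels > 0L], min)
  minv[as.integer(names(agg))] <- as.numeric(agg)

  adj <- dam_adjacency(labels, smoothed)
  # all region pairs sharing a dam pixel (one entry per dam pixel per pair)
  pairs <- dplyr::inner_join(adj, adj, by = "pix",
                             relationship = "many-to-many") |>
    dplyr::filter(.data$lab.x < .data$lab.y) |>
    dplyr::arrange(.data$lab.x, .data$lab.y, .data$val.x)
  if (nrow(pairs) == 0L) return(relabel_consecutive(labels))
  pa <- pairs$lab.x; pb <- pairs$lab.y; pv <- pairs$val.x

  root <- seq_len(n_lab)
  repeat {
    ra <- root[pa]; rb <- root[pb]
    live <- ra != rb
    if (!any(live)) break
    sal <- pv - pmax(minv[ra], minv[rb])
    sal[!live] <- Inf
    i <- which.min(sal)
    if (sal[i] >= merge_depth_threshold) break
    a <- min(ra[i], rb[i]); b <- max(ra[i], rb[i])
    minv[a] <- min(minv[a], minv[b])
    root[root == b] <- a
  }

  out <- labels
  pos <- labels > 0L
  out[pos] <- root[labels[pos]]
  # absorb dam pixels now interior to a merged region
  if (nrow(adj) > 0L) {
    absorb <- adj |>
      dplyr::group_by(.data$pix) |>
      dplyr::summarise(n_orig = dplyr::n_distinct(.data$lab),
                       n_new = dplyr::n_distinct(root[.data$lab]),
                       lab = root[.data$lab[1]], .groups = "drop") |>
      dplyr::filter(.data$n_orig >= 2L, .data$n_new == 1L)
    out[absorb$pix] <- absorb$lab
  }
  relabel_consecutive(out)
}

#' Otsu's threshold over a sample of intensities
#'
#' Exhaustive search over `n_bins` equal-width bins of the sample's own
#' range for the split maximising the between-class variance; the smallest
#' threshold attaining the maximum is returned. Constant samples have no
#' split and return `NA`.
#'
#' @param x Numeric vector of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value (lower-edge convention: pixels strictly below it
#'   form the dark class), or `NA` for degenerate input.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  t_idx <- seq_len(n_bins - 1L)
  denom <- omega[t_idx] * (1 - omega[t_idx])
  sigma2b <- ifelse(denom > 0,
                    (mu_t * omega[t_idx] - mu[t_idx])^2 / denom, -Inf)
  best <- which.max(sigma2b)
  edges[best + 1L]
}

#' Extract per-cell lumens with Otsu's threshold
#'
#' Within each cell's own ROIC footprint, Otsu's criterion over the cell's
#' own intensity histogram yields a threshold; the lumen (ROIL) is the set
#' of pixels strictly below it. Constant-intensity cells get an empty lumen
#' (the whole cell is treated as wall).
#'
#' @param reference Counterstain raster (typically the smoothed channel the
#'   watershed ran on).
#' @param roic ROIC label map.
#' @return ROIL label map sharing cell ids with `roic`.
#' @export
extract_lumen <- function(reference, roic) {
  if (!identical(dim(reference), dim(roic)))
    rc_abort("raster and label map dimensions differ", "rc_shape_error")
  roil <- matrix(0L, nrow(roic), ncol(roic))
  for (id in sort(unique(roic[roic > 0]))) {
    idx <- which(roic == id)
    vals <- reference[idx]
    th <- otsu_threshold(vals)
    if (is.na(th)) next
    roil[idx[vals < th]] <- as.integer(id)
  }
  roil
}

#' Derive the cell-wall region as the set difference ROIC minus ROIL
#'
#' @param roic Whole-cell label map.
#' @param roil Lumen label map (cell-wise subset of `roic`).
#' @return ROIW label map with the same cell ids.
#' @export
derive_wall <- function(roic, roil) {
  if (!identical(dim(roic), dim(roil)))
    rc_abort("label map dimensions differ", "rc_shape_error")
  if (any(roil > 0 & roil != roic))
    rc_abort("ROIL pixel found outside its cell's ROIC footprint",
             "rc_consistency_error")
  roiw <- roic
  roiw[roil > 0] <- 0L
  empty <- setdiff(unique(roic[roic > 0]), unique(roiw[roiw > 0]))
  if (length(empty) > 0)
    rc_warn(sprintf("%d cell(s) have lumen = whole cell (empty wall)",
                    length(empty)), "rc_empty_wall")
  roiw
}

#' Bundle the three aligned label maps into a cell segmentation
#'
#' Validates the mutual-consistency invariants: ROIL and ROIW are nonzero
#' only where ROIC is, cell ids agree, and per cell ROIW = ROIC minus ROIL.
#'
#' @param roic,roil,roiw Integer label maps of identical shape.
#' @return A `cell_segmentation` object.
#' @export
cell_segmentation <- function(roic, roil, roiw) {
  if (!identical(dim(roic), dim(roil)) || !identical(dim(roic), dim(roiw)))
    rc_abort("label map dimensions differ", "rc_shape_error")
  if (any(roil > 0 & roil != roic) || any(roiw > 0 & roiw != roic))
    rc_abort("ROIL/ROIW inconsistent with ROIC", "rc_consistency_error")
  if (any(roil > 0 & roiw > 0))
    rc_abort("ROIL and ROIW overlap", "rc_consistency_error")
  if (!all((roic > 0) == (roil > 0 | roiw > 0)))
    rc_abort("ROIC must equal the union of ROIL and ROIW", "rc_consistency_error")
  structure(list(roic = roic, roil = roil, roiw = roiw),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("<cell_segmentation> %d x %d px, %d cells\n",
              nrow(x$roic), ncol(x$roic), max(x$roic)))
  invisible(x)
}

#' Cell ids present in a segmentation
#' @param seg A `cell_segmentation`.
#' @return Sorted integer vector of cell ids.
#' @export
segmentation_cell_ids <- function(seg) {
  sort(unique(seg$roic[seg$roic > 0]))
}

# per-cell centroids in pixel coordinates (x = column, y = row)
cell_centroids_px <- function(roic) {
  ids <- sort(unique(roic[roic > 0]))
  pix <- which(roic > 0)
  nr <- nrow(roic)
  lab <- roic[pix]
  r <- ((pix - 1L) %% nr) + 1L
  c <- ((pix - 1L) %/% nr) + 1L
  tibble::tibble(
    cell_id = ids,
    x = as.numeric(tapply(c, lab, mean)[as.character(ids)]),
    y = as.numeric(tapply(r, lab, mean)[as.character(ids)])
  )
}

#' Restrict a segmentation to cells whose centroid lies in a rectangle
#'
#' Cells with centroid outside `crop_region` are removed from all three
#' label maps; surviving cells keep their full pixel footprints and are
#' relabelled consecutively with a shared id mapping.
#'
#' @param seg A [cell_segmentation()].
#' @param crop_region Rectangle `c(x0, y0, x1, y1)` in pixel coordinates
#'   (x = column, y = row), inclusive.
#' @return The cropped `cell_segmentation`.
#' @export
crop_restrict <- function(seg, crop_region) {
  stopifnot(length(crop_region) == 4L)
  x0 <- crop_region[1]; y0 <- crop_region[2]
  x1 <- crop_region[3]; y1 <- crop_region[4]
  nr <- nrow(seg$roic); nc <- ncol(seg$roic)
  if (x0 < 1 || y0 < 1 || x1 > nc || y1 > nr || x0 > x1 || y0 > y1)
    rc_abort("crop rectangle outside image bounds", "rc_param_error")
  cen <- cell_centroids_px(seg$roic)
  keep <- cen$cell_id[cen$x >= x0 & cen$x <= x1 & cen$y >= y0 & cen$y <= y1]
  if (length(keep) == 0L)
    rc_abort("crop removes every cell", "rc_empty_result")
  drop_mask <- seg$roic > 0 & !(seg$roic %in% keep)
  roic <- seg$roic; roil <- seg$roil; roiw <- seg$roiw
  roic[drop_mask] <- 0L; roil[drop_mask] <- 0L; roiw[drop_mask] <- 0L
  # shared consecutive relabelling across the three maps
  lut <- integer(max(keep)); lut[sort(keep)] <- seq_along(keep)
  for (m in c("roic", "roil", "roiw")) {
    x <- get(m); pos <- x > 0L; x[pos] <- lut[x[pos]]; assign(m, x)
  }
  cell_segmentation(roic, roil, roiw)
}

#' Segment the counterstain channel into ROIC, ROIL and ROIW
#'
#' The full segmentation stage: Gaussian smoothing, minima-seeded watershed
#' with dam-saliency merging, per-cell Otsu lumen extraction, wall
#' derivation, and optional centroid-based cropping.
#'
#' @param image A [two_channel_image()] or a counterstain matrix.
#' @param params A [segmentation_params()].
#' @return A [cell_segmentation()] with the smoothed raster attached as
#'   attribute `"smoothed"`.
#' @export
segment_cells <- function(image, params = segmentation_params()) {
  reference <- if (inherits(image, "two_channel_image")) image$reference
               else image
  smoothed <- smooth_reference(reference, params$smoothing_variance_px)
  roic <- watershed_cells(smoothed, params)
  roil <- extract_lumen(smoothed, roic)
  roiw <- suppressWarnings(derive_wall(roic, roil))
  seg <- cell_segmentation(roic, roil, roiw)
  if (!is.null(params$crop_region))
    seg <- crop_restrict(seg, params$crop_region)
  attr(seg, "smoothed") <- smoothed
  seg
}
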