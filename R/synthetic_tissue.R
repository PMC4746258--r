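#' Specify a synthetic radially organised tissue
#'
#' Describes concentric rings of cells around a tissue center, emulating
#' the ringed cell-type organisation of a stem-like organ cross-section:
#' each ring has a cell-type class, target cell count, cell-size
#' distribution, wall thickness, channel-1 wall/lumen intensities with
#' additive Gaussian noise (clipped at 0), and channel-2 (immunolabel)
#' wall/lumen amplitudes.
#'
#' @param image_size Image side length in pixels (square image).
#' @param pixel_size_um Micrometres per pixel.
#' @param rings Tibble with one row per ring (inner to outer):
#'   `class`, `r_inner_um`, `r_outer_um`, `n_cells`, `cell_size_mean_um2`,
#'   `cell_size_cv`, `wall_thickness_px`, `wall_mean`, `wall_sd`,
#'   `lumen_mean`, `lumen_sd`, `signal_wall`, `signal_lumen`.
#' @param seed Integer seed; mandatory — generation is deterministic.
#' @param center_xy Tissue center in pixels; defaults to the image center.
#' @param background_level Channel-1 intensity outside the tissue.
#' @param signal_background Constant channel-2 background added everywhere.
#' @return A `tissue_spec` object.
#' @export
tissue_spec <- function(image_size, pixel_size_um, rings, seed,
                        center_xy = NULL, background_level = 5,
                        signal_background = 0) {
  if (missing(seed)) rc_abort("`seed` is mandatory", "rc_param_error")
  stopifnot(is.data.frame(rings), nrow(rings) >= 1L)
  if (any(diff(c(rbind(rings$r_inner_um, rings$r_outer_um))) < 0))
    rc_abort("ring radii must be increasing and non-overlapping",
             "rc_param_error")
  num_cols <- c("wall_mean", "wall_sd", "lumen_mean", "lumen_sd",
                "signal_wall", "signal_lumen")
  if (any(as.matrix(rings[num_cols]) < 0))
    rc_abort("intensities and noise sds must be >= 0", "rc_param_error")
  if (is.null(center_xy)) center_xy <- rep((image_size + 1) / 2, 2)
  # packing feasibility: requested cells must fit in each annulus
  ann_area <- pi * (rings$r_outer_um^2 - rings$r_inner_um^2)
  bad <- which(rings$n_cells * rings$cell_size_mean_um2 > ann_area)
  if (length(bad) > 0)
    rc_abort(sprintf("infeasible packing in ring '%s': %d cells x %.0f um^2 exceed the annulus area %.0f um^2",
                     rings$class[bad[1]], rings$n_cells[bad[1]],
                     rings$cell_size_mean_um2[bad[1]], ann_area[bad[1]]),
             "rc_packing_error")
  structure(list(image_size = as.integer(image_size),
                 pixel_size_um = pixel_size_um,
                 center_xy = as.numeric(center_xy),
                 rings = tibble::as_tibble(rings),
                 seed = as.integer(seed),
                 background_level = background_level,
                 signal_background = signal_background),
            class = "tissue_spec")
}

#' Default six-ring tissue specification
#'
#' Mimics (in ring topology only) the six cell-type organisation of a
#' 21-day hypocotyl cross-section — xylem vessels and parenchyma, cambium,
#' phloem fibers and parenchyma, cortex — as concentric rings on a
#' 512 x 512 image at 0.7 um/px, about 170 cells in total. Channel-1 wall
#' intensities sit on an 8-bit-like 0-255 scale (lumen 30, walls 150-240,
#' background 5), noiseless by default; channel-2 signal is confined to the
#' xylem-vessel ring walls (amplitude 150), emulating a secondary-cell-wall
#' epitope.
#'
#' @param seed Integer seed.
#' @param noise_snr Optional signal-to-noise ratio; when given, every
#'   ring's channel-1 noise sd is set to `wall_mean / noise_snr` (and the
#'   lumen sd to the same value). `NULL` = noiseless.
#' @param uniform_rings If `TRUE`, all rings share the same cell size, wall
#'   thickness and intensities, so the ring classes differ chiefly by
#'   radial position (used to probe radial-feature importance).
#' @return A [tissue_spec()].
#' @export
default_tissue_spec <- function(seed, noise_snr = NULL,
                                uniform_rings = FALSE) {
  rings <- tibble::tibble(
    class = c("xylem_vessel", "xylem_parenchyma", "cambium",
              "phloem_fiber", "phloem_parenchyma", "cortex"),
    r_inner_um = c(15, 60, 90, 110, 130, 155),
    r_outer_um = c(60, 90, 110, 130, 155, 175),
    n_cells = c(14L, 24L, 30L, 28L, 30L, 24L),
    cell_size_mean_um2 = c(600, 450, 320, 420, 580, 680),
    cell_size_cv = 0.25,
    wall_thickness_px = c(4, 2, 2, 4, 2, 2),
    wall_mean = c(230, 180, 160, 240, 170, 150),
    wall_sd = 0,
    lumen_mean = 30,
    lumen_sd = 0,
    signal_wall = c(150, 0, 0, 0, 0, 0),
    signal_lumen = 0
  )
  if (uniform_rings) {
    rings$cell_size_mean_um2 <- 450
    rings$wall_thickness_px <- 2
    rings$wall_mean <- 200
    rings$n_cells <- c(10L, 22L, 26L, 30L, 36L, 32L)
  }
  if (!is.null(noise_snr)) {
    rings$wall_sd <- rings$wall_mean / noise_snr
    rings$lumen_sd <- rings$wall_mean / noise_snr
  }
  tissue_spec(512L, 0.7, rings, seed)
}

#' Denser six-ring specification for classifier training
#'
#' Same ring layout as [default_tissue_spec()] on a larger raster
#' (896 x 896 px) with radii scaled by 1.7, giving at least 40 cells per
#' class while keeping the per-class wall intensities (vessels are drawn
#' slightly smaller so the requested count packs into the inner annulus).
#'
#' @param seed Integer seed.
#' @param radius_scale Multiplier on all ring radii (default 1.7); other
#'   values shift the ring boundaries, emulating a genotype with altered
#'   tissue proportions.
#' @return A [tissue_spec()].
#' @export
classification_tissue_spec <- function(seed, radius_scale = 1.7) {
  base <- default_tissue_spec(seed)
  rings <- base$rings
  rings$r_inner_um <- rings$r_inner_um * radius_scale
  rings$r_outer_um <- rings$r_outer_um * radius_scale
  rings$n_cells <- c(40L, 52L, 60L, 56L, 60L, 52L)
  rings$cell_size_mean_um2[1] <- 480
  tissue_spec(896L, 0.7, rings, seed)
}

# dart-throwing seed placement for one ring; returns x, y, diam (px)
place_ring_seeds <- function(ring, center, px, existing) {
  r0 <- ring$r_inner_um / px
  r1 <- ring$r_outer_um / px
  n <- ring$n_cells
  placed <- matrix(numeric(0), ncol = 3)
  attempts <- 0L
  max_attempts <- 600L * n
  while (nrow(placed) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    area <- rnorm(1, ring$cell_size_mean_um2,
                  ring$cell_size_cv * ring$cell_size_mean_um2)
    area <- min(max(area, 0.3 * ring$cell_size_mean_um2),
                3 * ring$cell_size_mean_um2)
    diam <- 2 * sqrt(area / pi) / px
    rad <- sqrt(runif(1, r0^2, r1^2))
    ang <- runif(1, 0, 2 * pi)
    pt <- center + rad * c(cos(ang), sin(ang))
    all_pts <- rbind(existing, placed)
    if (nrow(all_pts) > 0) {
      d <- sqrt((all_pts[, 1] - pt[1])^2 + (all_pts[, 2] - pt[2])^2)
      if (any(d < 0.45 * (all_pts[, 3] + diam))) next
    }
    placed <- rbind(placed, c(pt, diam))
  }
  if (nrow(placed) < n)
    rc_abort(sprintf("infeasible packing: placed only %d of %d seeds in ring '%s'",
                     nrow(placed), n, ring$class), "rc_packing_error")
  placed
}

#' Generate a ground-truthed synthetic two-channel tissue image
#'
#' Cell seed points are placed ring by ring with blue-noise (dart-throwing)
#' spacing drawn from each ring's cell-size distribution; cells are the
#' nearest-seed (Voronoi) regions clipped to their ring annulus. Channel 1
#' paints ring-specific wall intensity on a band around the region
#' boundaries (ring-specific thickness), lumen intensity elsewhere in the
#' tissue, and background outside, plus optional Gaussian noise clipped
#' at 0. Channel 2 paints class-specific wall/lumen amplitudes plus the
#' constant background and noise. Fully deterministic for a fixed seed.
#'
#' @param spec A [tissue_spec()].
#' @return List with `image` (a [two_channel_image()]) and `truth` (list:
#'   `label_map` integer matrix, `cells` tibble with `cell_id`, `class`,
#'   `ring`, centroid and pixel count, and the `spec`).
#' @export
generate_radial_tissue <- function(spec) {
  withr::with_seed(spec$seed, {
    n <- spec$image_size
    px <- spec$pixel_size_um
    center <- spec$center_xy
    rings <- spec$rings

    seeds <- matrix(numeric(0), ncol = 3)
    ring_of_seed <- integer(0)
    for (i in seq_len(nrow(rings))) {
      placed <- place_ring_seeds(rings[i, ], center, px, seeds)
      seeds <- rbind(seeds, placed)
      ring_of_seed <- c(ring_of_seed, rep(i, nrow(placed)))
    }

    X <- matrix(rep(seq_len(n), each = n), n)   # column index
    Y <- matrix(rep(seq_len(n), times = n), n)  # row index
    rad_px <- sqrt((X - center[1])^2 + (Y - center[2])^2)
    edges_px <- c(rings$r_inner_um[1], rings$r_outer_um) / px
    ring_map <- matrix(findInterval(rad_px, edges_px), n)
    ring_map[ring_map > nrow(rings) | rad_px < edges_px[1]] <- 0L

    label_map <- matrix(0L, n, n)
    for (i in seq_len(nrow(rings))) {
      in_ring <- which(ring_map == i)
      if (length(in_ring) == 0L) next
      sidx <- which(ring_of_seed == i)
      best_d <- rep(Inf, length(in_ring))
      best_s <- integer(length(in_ring))
      for (s in sidx) {
        d <- (X[in_ring] - seeds[s, 1])^2 + (Y[in_ring] - seeds[s, 2])^2
        better <- d < best_d
        best_d[better] <- d[better]
        best_s[better] <- s
      }
      label_map[in_ring] <- best_s
    }

    # boundary pixels: any 4-neighbour with a different label; both sides
    # of every transition are flagged, including the tissue edge, so the
    # organ-surface wall has the same cross-section as interior walls
    padded <- matrix(0L, n + 2L, n + 2L)
    padded[2:(n + 1L), 2:(n + 1L)] <- label_map
    ctr <- padded[2:(n + 1L), 2:(n + 1L)]
    boundary <- (ctr != padded[1:n, 2:(n + 1L)]) |
      (ctr != padded[3:(n + 2L), 2:(n + 1L)]) |
      (ctr != padded[2:(n + 1L), 1:n]) |
      (ctr != padded[2:(n + 1L), 3:(n + 2L)])
    in_tissue <- ring_map > 0L

    max_th <- max(rings$wall_thickness_px)
    dist <- rcpp_cityblock_distance(boundary, as.integer(max_th) + 2L)
    th_map <- matrix(0, n, n)
    th_map[in_tissue] <- rings$wall_thickness_px[ring_map[in_tissue]]
    # give edge-adjacent background pixels the thickness (and intensity)
    # of the nearest ring so surface walls are painted at full width
    shift4 <- function(m, fill = 0) {
      p <- matrix(fill, n + 2L, n + 2L)
      p[2:(n + 1L), 2:(n + 1L)] <- m
      pmax(p[1:n, 2:(n + 1L)], p[3:(n + 2L), 2:(n + 1L)],
           p[2:(n + 1L), 1:n], p[2:(n + 1L), 3:(n + 2L)])
    }
    ring_ext <- ring_map
    th_ext <- th_map
    for (k in seq_len(ceiling(max_th / 2))) {
      grow <- !(ring_ext > 0L) & shift4(ring_ext) > 0L
      ring_ext[grow] <- shift4(ring_ext)[grow]
      th_ext[grow] <- shift4(th_ext)[grow]
    }
    wall <- ring_ext > 0L & dist <= pmax(0, (th_ext - 2) / 2)

    lut <- function(col) {
      out <- matrix(0, n, n)
      sel <- ring_ext > 0L
      out[sel] <- rings[[col]][ring_ext[sel]]
      out
    }
    ch1 <- matrix(spec$background_level, n, n)
    ch1[in_tissue & !wall] <- lut("lumen_mean")[in_tissue & !wall]
    ch1[wall] <- lut("wall_mean")[wall]
    sd1 <- matrix(0, n, n)
    noisy <- in_tissue | wall
    sd1[noisy] <- ifelse(wall[noisy],
                         lut("wall_sd")[noisy],
                         lut("lumen_sd")[noisy])
    ch1 <- pmax(ch1 + rnorm(n * n) * sd1, 0)

    ch2 <- matrix(spec$signal_background, n, n)
    ch2[in_tissue & !wall] <- spec$signal_background +
      lut("signal_lumen")[in_tissue & !wall]
    ch2[wall] <- spec$signal_background + lut("signal_wall")[wall]
    ch2 <- pmax(ch2 + rnorm(n * n) * sd1, 0)

    # drop seeds that received no pixels (crowded out) and relabel
    counts <- tabulate(label_map[label_map > 0L], nbins = nrow(seeds))
    keep <- which(counts > 0L)
    label_map <- relabel_consecutive(label_map)
    cen <- cell_centroids_px(label_map)
    cells <- tibble::tibble(
      cell_id = cen$cell_id,
      class = rings$class[ring_of_seed[keep]],
      ring = ring_of_seed[keep],
      centroid_x = cen$x, centroid_y = cen$y,
      n_pixels = counts[keep]
    )

    image <- two_channel_image(matrix(ch1, n), matrix(ch2, n), px)
    list(image = image,
         truth = list(label_map = label_map, cells = cells, spec = spec))
  })
}

#' Build a segmentation from ground-truth cell labels
#'
#' Uses the generator's label map as ROIC and derives ROIL/ROIW with the
#' standard per-cell Otsu split of the counterstain channel. Useful to
#' exercise downstream stages independently of watershed quality.
#'
#' @param truth The `truth` element of [generate_radial_tissue()].
#' @param reference Counterstain raster of the matching image.
#' @return A [cell_segmentation()].
#' @export
truth_segmentation <- function(truth, reference) {
  roic <- truth$label_map
  roil <- extract_lumen(reference, roic)
  roiw <- suppressWarnings(derive_wall(roic, roil))
  cell_segmentation(roic, roil, roiw)
}

#' Match predicted cells to ground-truth cells by intersection-over-union
#'
#' Greedy one-to-one matching by descending IoU between predicted and true
#' label footprints.
#'
#' @param pred_labels Predicted label map (e.g. ROIC from [segment_cells()]).
#' @param true_labels Ground-truth label map.
#' @param iou_threshold IoU above which a match counts as recovered
#'   (default 0.7).
#' @return List: `matches` tibble (`true_id`, `pred_id`, `iou`),
#'   `recovered_fraction` (fraction of true cells matched at or above the
#'   threshold), `n_true`, `n_pred`.
#' @export
match_segmentation <- function(pred_labels, true_labels,
                               iou_threshold = 0.7) {
  if (!identical(dim(pred_labels), dim(true_labels)))
    rc_abort("label map dimensions differ", "rc_shape_error")
  both <- pred_labels > 0 & true_labels > 0
  ov <- tibble::tibble(pred = pred_labels[both], true = true_labels[both]) |>
    dplyr::count(.data$pred, .data$true, name = "inter")
  area_p <- tabulate(pred_labels[pred_labels > 0], nbins = max(pred_labels))
  area_t <- tabulate(true_labels[true_labels > 0], nbins = max(true_labels))
  ov <- ov |>
    dplyr::mutate(iou = .data$inter /
                    (area_p[.data$pred] + area_t[.data$true] - .data$inter)) |>
    dplyr::arrange(dplyr::desc(.data$iou), .data$true, .data$pred)
  used_p <- logical(max(pred_labels))
  used_t <- logical(max(true_labels))
  keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    p <- ov$pred[i]; t <- ov$true[i]
    if (!used_p[p] && !used_t[t]) {
      keep[i] <- TRUE
      used_p[p] <- TRUE
      used_t[t] <- TRUE
    }
  }
  matches <- ov[keep, c("true", "pred", "iou")]
  names(matches) <- c("true_id", "pred_id", "iou")
  n_true <- sum(area_t > 0)
  list(matches = matches,
       recovered_fraction = sum(matches$iou >= iou_threshold) / n_true,
       n_true = n_true,
       n_pred = sum(area_p > 0))
}
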