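#' Canonical names of the 22 per-cell morphometric features
#'
#' Position (`m.cx`, `m.cy`, `Xnew`, `Ynew`, `radialV`, `angleV`), shape
#' (`m.majoraxes`, `m.eccentricity`, `m.theta`, `s.area`, `perimeter`,
#' `s.radius.mean`, `s.radius.min`, `s.radius.max`, `extv`, `inclV`, `P2A`,
#' `m.theta.real`) and counterstain-intensity features (`MedianROIC`,
#' `MeanROIC`, `MedianROIW`, `MeanROIW`). The historical misspelling
#' `"m.eccenticity"` is accepted as an input alias wherever feature names
#' are resolved.
#'
#' @return Character vector of length 22 in canonical column order.
#' @export
feature_names <- function() {
  c("m.cx", "m.cy", "Xnew", "Ynew", "radialV", "angleV",
    "m.majoraxes", "m.eccentricity", "m.theta", "s.area", "perimeter",
    "s.radius.mean", "s.radius.min", "s.radius.max", "extv", "inclV",
    "P2A", "MedianROIC", "MeanROIC", "m.theta.real",
    "MedianROIW", "MeanROIW")
}

#' Default classification feature subset
#'
#' All 22 features except the Cartesian coordinates (`m.cx`, `m.cy`,
#' `Xnew`, `Ynew`), which carry no information about cell identity in a
#' radially symmetric organ.
#'
#' @return Character vector of 18 feature names.
#' @export
default_feature_subset <- function() {
  setdiff(feature_names(), c("m.cx", "m.cy", "Xnew", "Ynew"))
}

# resolve user-supplied feature names, accepting the legacy alias
normalize_feature_names <- function(x) {
  x[x == "m.eccenticity"] <- "m.eccentricity"
  bad <- setdiff(x, feature_names())
  if (length(bad) > 0)
    rc_abort(sprintf("unknown feature name(s): %s. Valid names: %s",
                     paste(bad, collapse = ", "),
                     paste(feature_names(), collapse = ", ")),
             "rc_feature_error")
  x
}

# Moore-neighbour boundary walk of a logical mask; returns the walk length
# in pixel units (1 per axial step, sqrt(2) per diagonal step). Isolated
# single pixels have length 0.
trace_perimeter_px <- function(mask) {
  nr <- nrow(mask) + 2L
  m <- matrix(FALSE, nr, ncol(mask) + 2L)
  m[2:(nr - 1L), 2:(ncol(mask) + 1L)] <- mask
  start <- which(m)[1]
  if (is.na(start)) return(0)
  sr <- ((start - 1L) %% nr) + 1L
  sc <- ((start - 1L) %/% nr) + 1L
  # clockwise 8-neighbour offsets (row, col) starting at W, screen frame
  offs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  step_len <- ifelse(rowSums(abs(offs)) == 2L, sqrt(2), 1)
  p <- c(sr, sc)
  back <- 1L                     # entered from the W (guaranteed empty)
  total <- 0
  first_move <- NA_integer_
  max_iter <- 4L * sum(m) + 8L
  for (iter in seq_len(max_iter)) {
    found <- 0L
    for (k in 0:7) {
      j <- ((back - 1L + k) %% 8L) + 1L
      q <- p + offs[j, ]
      if (m[q[1], q[2]]) { found <- j; break }
    }
    if (found == 0L) return(0)   # isolated pixel
    if (all(p == c(sr, sc))) {
      if (!is.na(first_move) && found == first_move) break
      if (is.na(first_move)) first_move <- found
    }
    total <- total + step_len[found]
    prev_j <- ((found - 2L) %% 8L) + 1L
    bcoord <- p + offs[prev_j, ]
    p <- p + offs[found, ]
    d <- bcoord - p
    back <- which(offs[, 1] == d[1] & offs[, 2] == d[2])
    if (iter == max_iter) break
  }
  total
}

# acute angle in [0, pi/2] between a vector and an axis direction
acute_angle <- function(vx, vy, ax, ay) {
  nv <- sqrt(vx^2 + vy^2)
  na <- sqrt(ax^2 + ay^2)
  if (nv == 0 || na == 0) return(0)
  acos(pmin(1, abs(vx * ax + vy * ay) / (nv * na)))
}

#' Compute the 22 morphometric features for one cell
#'
#' Centroid from the ROIC pixel mean; major/minor axis lengths and
#' orientation from principal-component analysis of the ROIC pixel
#' coordinates (full axis length = 4 sqrt(eigenvalue), which recovers the
#' true axes of a filled ellipse); eccentricity
#' sqrt(1 - minor^2 / major^2); area = pixel count times pixel area;
#' perimeter from a Moore boundary walk with sqrt(2)-weighted diagonal
#' steps; radius statistics over border-pixel-to-centroid distances;
#' `extv` = major x minor; `inclV` / `m.theta.real` = acute angle between
#' the outward radial vector and the major axis; `P2A` = perimeter / area;
#' counterstain intensity statistics over ROIC and ROIW.
#'
#' @param cell_id Cell id present in `seg`.
#' @param seg A [cell_segmentation()].
#' @param reference Counterstain raster the intensity features are read
#'   from.
#' @param frame A [tissue_frame()] (supplies the tissue center and the
#'   pixel size).
#' @return One-row tibble with `cell_id` and the 22 features of
#'   [feature_names()].
#' @export
compute_features <- function(cell_id, seg, reference, frame) {
  px <- frame$pixel_size_um
  idx <- which(seg$roic == cell_id)
  if (length(idx) == 0L)
    rc_abort(sprintf("cell %s not present in segmentation", cell_id),
             "rc_missing_cell")
  nr <- nrow(seg$roic)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  n <- length(idx)
  x_um <- c * px
  y_um <- r * px
  m_cx <- mean(x_um); m_cy <- mean(y_um)
  pol <- polar_coordinates(cbind(mean(c), mean(r)), frame)

  if (n == 1L) {
    rc_warn(sprintf("cell %d is a single pixel; shape features degenerate",
                    cell_id), "rc_degenerate_cell")
    major <- minor <- 0; theta <- 0; ecc <- 0
    v1 <- c(1, 0)
  } else {
    cx <- x_um - m_cx; cy <- y_um - m_cy
    cov <- matrix(c(mean(cx^2), mean(cx * cy), mean(cx * cy), mean(cy^2)), 2)
    eig <- eigen(cov, symmetric = TRUE)
    major <- 4 * sqrt(max(eig$values[1], 0))
    minor <- 4 * sqrt(max(eig$values[2], 0))
    v1 <- eig$vectors[, 1]
    theta <- atan2(v1[2], v1[1])
    if (theta <= -pi / 2) theta <- theta + pi
    if (theta > pi / 2) theta <- theta - pi
    ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0
  }

  # border pixels: at least one 4-neighbour outside the cell (or image edge)
  inside <- matrix(FALSE, nr, ncol(seg$roic))
  inside[idx] <- TRUE
  on_border <- !(r > 1 & r < nr & c > 1 & c < ncol(seg$roic))
  interior <- !on_border
  if (any(interior)) {
    i2 <- idx[interior]
    interior[interior] <- inside[i2 - 1L] & inside[i2 + 1L] &
      inside[i2 - nr] & inside[i2 + nr]
  }
  border <- !interior
  rad <- sqrt((x_um[border] - m_cx)^2 + (y_um[border] - m_cy)^2)
  if (length(rad) == 0L || n == 1L) rad <- 0

  bb_mask <- inside[min(r):max(r), min(c):max(c), drop = FALSE]
  perim <- trace_perimeter_px(bb_mask) * px
  area <- n * px^2

  incl <- acute_angle(pol$Xnew, pol$Ynew, v1[1], v1[2])

  widx <- which(seg$roiw == cell_id)
  wall_vals <- reference[widx]
  cell_vals <- reference[idx]

  tibble::tibble(
    cell_id = as.integer(cell_id),
    m.cx = m_cx, m.cy = m_cy,
    Xnew = pol$Xnew, Ynew = pol$Ynew,
    radialV = pol$radialV, angleV = pol$angleV,
    m.majoraxes = major, m.eccentricity = ecc, m.theta = theta,
    s.area = area, perimeter = perim,
    s.radius.mean = mean(rad), s.radius.min = min(rad),
    s.radius.max = max(rad),
    extv = major * minor, inclV = incl, P2A = perim / area,
    MedianROIC = median(cell_vals), MeanROIC = mean(cell_vals),
    m.theta.real = incl,
    MedianROIW = if (length(wall_vals)) median(wall_vals) else NA_real_,
    MeanROIW = if (length(wall_vals)) mean(wall_vals) else NA_real_
  )
}

#' Compute the feature table for every cell of a segmentation
#'
#' @param seg A [cell_segmentation()].
#' @param reference Counterstain raster.
#' @param frame A [tissue_frame()].
#' @return Tibble with one row per ROIC cell: `cell_id` plus the 22
#'   features of [feature_names()].
#' @export
compute_feature_table <- function(seg, reference, frame) {
  ids <- segmentation_cell_ids(seg)
  if (length(ids) == 0L)
    rc_abort("segmentation contains no cells", "rc_empty_result")
  purrr::map(ids, compute_features, seg = seg, reference = reference,
             frame = frame) |>
    dplyr::bind_rows()
}
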