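#' Radial tissue coordinate frame
#'
#' The radial organisation of a transverse section is anchored on a
#' user-supplied tissue center (the pith/origin of the organ), given in
#' pixel coordinates (x = column, y = row, origin top-left).
#'
#' @param center_xy Numeric length-2 vector `c(x, y)` in pixels.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @return A `tissue_frame` object.
#' @export
tissue_frame <- function(center_xy, pixel_size_um) {
  if (length(center_xy) != 2L || !is.numeric(center_xy))
    rc_abort("`center_xy` must be c(x, y)", "rc_type_error")
  if (pixel_size_um <= 0)
    rc_abort("`pixel_size_um` must be > 0", "rc_param_error")
  structure(list(center_xy = as.numeric(center_xy),
                 pixel_size_um = pixel_size_um),
            class = "tissue_frame")
}

#' Polar coordinates of cell centers relative to the tissue center
#'
#' Converts pixel-coordinate centroids to the tissue-centred frame:
#' `Xnew`/`Ynew` are the centroid offsets from the tissue center in
#' micrometres, `radialV` the radial distance, and `angleV` the angular
#' coordinate `atan2(Ynew, Xnew)` in (-pi, pi] (0 by convention at the
#' exact center).
#'
#' @param centroid_xy Two-column matrix or data frame of centroids in
#'   pixels (x = column, y = row), one row per cell.
#' @param frame A [tissue_frame()].
#' @return Tibble with columns `Xnew`, `Ynew`, `radialV`, `angleV`.
#' @export
polar_coordinates <- function(centroid_xy, frame) {
  m <- as.matrix(centroid_xy)
  px <- frame$pixel_size_um
  xn <- (m[, 1] - frame$center_xy[1]) * px
  yn <- (m[, 2] - frame$center_xy[2]) * px
  r <- sqrt(xn^2 + yn^2)
  a <- ifelse(r == 0, 0, atan2(yn, xn))
  tibble::tibble(Xnew = xn, Ynew = yn, radialV = r, angleV = a)
}

# quadrant of pixel offsets d (n x 2, x/y) w.r.t. outward radial unit
# vector u (length-2): 3 = outer periclinal, 4 = inner periclinal,
# 1/2 = anticlinal; boundary angles (exactly 45/135 deg) resolve periclinal
quadrant_of <- function(dx, dy, ux, uy) {
  dot <- dx * ux + dy * uy
  crs <- ux * dy - uy * dx
  phi <- atan2(crs, dot)           # (-pi, pi]
  aphi <- abs(phi)
  q <- integer(length(phi))
  q[aphi <= pi / 4 + 1e-12] <- 3L
  q[aphi >= 3 * pi / 4 - 1e-12] <- 4L
  rest <- q == 0L
  q[rest & phi > 0] <- 1L
  q[rest & phi < 0] <- 2L
  q
}

#' Divide every cell's ROIs into four radially defined quadrants
#'
#' For each cell, the outward radial unit vector u runs from the tissue
#' center through the cell centroid. Each ROIC pixel p is classified by the
#' angle phi between (p - centroid) and u: within 45 degrees of u it belongs
#' to the outer periclinal quadrant 3, within 45 degrees of -u to the inner
#' periclinal quadrant 4, and the two remaining lateral sectors are the
#' anticlinal quadrants 1 and 2 (1 on the counter-clockwise side of u in the
#' x-right / y-down pixel frame). Pixels at exactly 45 degrees resolve to
#' the periclinal sector. ROIL and ROIW inherit the ROIC assignment, so a
#' pixel carries the same quadrant in every ROI kind.
#'
#' Cells whose centroid coincides with the tissue center have no defined
#' radial direction: their pixels are left 0 and their ids are returned in
#' attribute `"undefined_cells"`.
#'
#' @param seg A [cell_segmentation()].
#' @param frame A [tissue_frame()].
#' @return Integer matrix over the image, values 1-4 on ROIC pixels and 0
#'   elsewhere, with attribute `"undefined_cells"`.
#' @export
assign_quadrants <- function(seg, frame) {
  roic <- seg$roic
  nr <- nrow(roic)
  quad <- matrix(0L, nr, ncol(roic))
  cen <- cell_centroids_px(roic)
  undefined <- integer()
  pix <- which(roic > 0)
  lab <- roic[pix]
  py <- ((pix - 1L) %% nr) + 1L
  px <- ((pix - 1L) %/% nr) + 1L
  for (i in seq_len(nrow(cen))) {
    id <- cen$cell_id[i]
    ux <- cen$x[i] - frame$center_xy[1]
    uy <- cen$y[i] - frame$center_xy[2]
    nrm <- sqrt(ux^2 + uy^2)
    sel <- lab == id
    if (nrm == 0) {
      undefined <- c(undefined, id)
      next
    }
    ux <- ux / nrm; uy <- uy / nrm
    quad[pix[sel]] <- quadrant_of(px[sel] - cen$x[i], py[sel] - cen$y[i],
                                  ux, uy)
  }
  if (length(undefined) > 0)
    rc_warn(sprintf(
      "%d cell(s) have centroid at the tissue center; quadrants undefined",
      length(undefined)), "rc_undefined_quadrant")
  attr(quad, "undefined_cells") <- undefined
  quad
}
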