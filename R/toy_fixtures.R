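#' Tiny deterministic toy rasters with embedded expected outputs
#'
#' Hand-specified fixtures exercising individual operations; no randomness
#' involved. Each element carries the inputs and the expected outputs the
#' construction forces:
#'
#' * `two_basin`: 16 x 16 raster with two dark basins (value 10) split by a
#'   bright ridge (value 200); merge threshold 10 keeps 2 regions.
#' * `shallow_ridge`: same geometry with ridge value 15 (saliency 5), which
#'   merges into 1 region at threshold 10.
#' * `chain`: three basins A-B-C with dam saliencies 4 and 6, all merging
#'   into one region at threshold 10.
#' * `bimodal_cell`: a 12 x 12 cell with wall intensity 200 and interior
#'   20; the per-cell Otsu lumen is exactly the interior.
#' * `radial_rect`, `tangential_rect`: 21 x 21 masks of a 5 x 15 rectangle
#'   whose major axis is aligned with / perpendicular to the radial vector
#'   from a far-away tissue center, forcing `inclV` near 0 / pi/2.
#' * `east_cell`: a square cell due east of the tissue center, with the
#'   expected quadrant of four probe pixels.
#'
#' @return Named list of fixtures.
#' @export
generate_toy_fixtures <- function() {
  two_basin <- matrix(10, 16, 16)
  two_basin[, 8:9] <- 200           # bright vertical ridge
  shallow_ridge <- matrix(10, 16, 16)
  shallow_ridge[, 8:9] <- 15        # saliency 5 < 10

  chain <- matrix(0, 12, 18)
  chain[, 1:5] <- 10                # basin A, min 10
  chain[, 6] <- 16                  # dam A-B: 16 - max(10, 12) = 4
  chain[, 7:11] <- 12               # basin B, min 12
  chain[, 12] <- 17                 # dam B-C: 17 - max(12, 11) = 6
  chain[, 13:18] <- 11              # basin C, min 11

  bimodal_cell <- matrix(200, 12, 12)
  bimodal_cell[3:10, 3:10] <- 20
  bimodal_lumen <- matrix(FALSE, 12, 12)
  bimodal_lumen[3:10, 3:10] <- TRUE

  rect_mask <- function(wide) {
    m <- matrix(FALSE, 21, 21)
    if (wide) m[9:13, 4:18] <- TRUE else m[4:18, 9:13] <- TRUE
    m
  }

  list(
    two_basin = list(raster = two_basin, n_regions = 2L),
    shallow_ridge = list(raster = shallow_ridge, n_regions = 1L,
                         saliency = 5),
    chain = list(raster = chain, n_regions = 1L, saliencies = c(4, 6)),
    bimodal_cell = list(raster = bimodal_cell, lumen_mask = bimodal_lumen,
                        modes = c(20, 200)),
    # tissue center far to the west: the radial vector at the mask is ~ +x
    radial_rect = list(mask = rect_mask(TRUE), center = c(-1000, 11),
                       expected_inclV = 0),
    tangential_rect = list(mask = rect_mask(FALSE), center = c(-1000, 11),
                           expected_inclV = pi / 2),
    east_cell = list(
      center = c(1, 8),             # tissue center west of the cell
      cell_rows = 4:12, cell_cols = 16:24, image_size = c(15, 30),
      # probe pixels (row, col) relative to the 9 x 9 cell centered (8, 20)
      probes = tibble::tibble(
        row = c(8, 8, 5, 11), col = c(23, 17, 20, 20),
        quadrant = c(3L, 4L, NA, NA)  # north/south fall in the two
      )                               # anticlinal sectors (1 and 2)
    )
  )
}
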