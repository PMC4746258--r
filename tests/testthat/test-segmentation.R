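# independent Otsu oracle: exhaustive scan of every candidate split of the
# 256-bin histogram, maximising between-class variance computed from first
# principles (class weights and means)
brute_otsu <- function(x, n_bins = 256L) {
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  best <- -Inf; best_t <- NA
  for (t in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / n0
    mu1 <- sum(counts[(t + 1):n_bins] * mids[(t + 1):n_bins]) / n1
    s2b <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (s2b > best) { best <- s2b; best_t <- t }
  }
  edges[best_t + 1L]
}

test_that("Gaussian smoothing conserves intensity and has exact edge cases", {
  const <- matrix(7, 9, 13)
  expect_equal(smooth_reference(const, 1), const)

  impulse <- matrix(0, 21, 21); impulse[11, 11] <- 1
  sm <- smooth_reference(impulse, 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # center region must equal the outer product of the normalised 1-D kernel
  sigma <- 1; radius <- 4
  k <- exp(-(-radius:radius)^2 / (2 * sigma^2)); k <- k / sum(k)
  expect_equal(sm[11 + (-radius:radius), 11 + (-radius:radius)],
               outer(k, k), tolerance = 1e-12)

  r <- matrix(runif(120), 10, 12)
  expect_identical(smooth_reference(r, 0), r)
  expect_error(smooth_reference(r, -1), class = "rc_param_error")
})

test_that("deep dams split basins and shallow dams merge", {
  tf <- toys()
  lab <- watershed_cells(smooth_reference(tf$two_basin$raster, 0),
                         segmentation_params(0, 10))
  expect_equal(max(lab), tf$two_basin$n_regions)

  lab2 <- watershed_cells(tf$shallow_ridge$raster, segmentation_params(0, 10))
  expect_equal(max(lab2), tf$shallow_ridge$n_regions)

  # the same shallow geometry survives when its saliency exceeds the
  # threshold
  lab3 <- watershed_cells(tf$shallow_ridge$raster, segmentation_params(0, 5))
  expect_equal(max(lab3), 2)

  # flat image: single region with a warning
  expect_warning(flat <- watershed_cells(matrix(3, 8, 8),
                                         segmentation_params(0, 10)),
                 class = "rc_flat_image")
  expect_equal(max(flat), 1)
})

test_that("merge decisions follow the saliency rule, iteratively", {
  tf <- toys()
  # chain A(10)-B(12)-C(11) with dams 16 and 17: saliencies 4 and 6, both
  # below 10, so everything collapses to one region
  lab <- watershed_cells(tf$chain$raster, segmentation_params(0, 10))
  expect_equal(max(lab), tf$chain$n_regions)

  # exhaustive pairwise oracle on a 3-region toy: dams at 25 (saliency
  # 25 - 12 = 13, kept) and 19 (saliency 19 - 10 = 9, merged)
  toy <- matrix(0, 10, 15)
  toy[, 1:4] <- 12; toy[, 5] <- 25; toy[, 6:9] <- 10
  toy[, 10] <- 19; toy[, 11:15] <- 11
  raw <- radialcells:::rcpp_watershed_flood(
    toy, radialcells:::rcpp_regional_minima(toy))
  expect_equal(max(raw), 3)
  merged <- merge_shallow_regions(raw, toy, 10)
  expect_equal(max(merged), 2)
  # the merged pair is the one with sub-threshold saliency: columns 6..15
  # share one label, columns 1..4 keep another
  expect_equal(length(unique(as.vector(merged[, c(6:9, 11:15)]))), 1)
  expect_false(merged[5, 2] == merged[5, 7])

  # threshold 0 merges nothing
  expect_equal(max(merge_shallow_regions(raw, toy, 0)), 3)
  expect_error(merge_shallow_regions(raw[, 1:10], toy, 10),
               class = "rc_shape_error")
})

test_that("merging is monotone in the threshold and watershed is
           shift-invariant", {
  img <- smooth_reference(mini_gen()$image$reference, 1)
  base <- radialcells:::rcpp_watershed_flood(
    img, radialcells:::rcpp_regional_minima(img))
  counts <- vapply(c(0, 5, 10, 20, 40, 80),
                   function(th) max(merge_shallow_regions(base, img, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  # shift invariance is exact on integer-valued rasters (floating-point
  # ties in a smoothed image can legitimately reorder plateau flooding)
  raw <- mini_gen()$image$reference
  lab1 <- watershed_cells(raw, segmentation_params(0, 10))
  lab2 <- watershed_cells(raw + 37, segmentation_params(0, 10))
  expect_identical(lab1, lab2)
})

test_that("per-cell Otsu matches the brute-force scan and the bimodal toy", {
  tf <- toys()
  th <- otsu_threshold(tf$bimodal_cell$raster[tf$bimodal_cell$raster > 0])
  expect_gt(th, tf$bimodal_cell$modes[1])
  expect_lt(th, tf$bimodal_cell$modes[2])

  withr::with_seed(4, {
    for (i in 1:5) {
      x <- c(rnorm(200, 30, 5 + i), rnorm(150, 150 + 10 * i, 20))
      expect_equal(otsu_threshold(x), brute_otsu(x))
    }
  })

  expect_true(is.na(otsu_threshold(rep(5, 10))))
})

test_that("lumen extraction is per cell, with degenerate cells empty", {
  # two cells with different contrast ranges in one map
  roic <- matrix(0L, 10, 21)
  roic[2:9, 2:10] <- 1L; roic[2:9, 12:20] <- 2L
  ref <- matrix(0, 10, 21)
  ref[roic == 1L] <- 200; ref[3:8, 3:9] <- 20      # cell 1: 20 vs 200
  ref[roic == 2L] <- 90; ref[3:8, 13:19] <- 50     # cell 2: 50 vs 90
  roil <- extract_lumen(ref, roic)
  expect_setequal(unique(roil[roil > 0]), c(1L, 2L))
  # each per-cell threshold equals its own brute-force scan
  for (id in 1:2) {
    vals <- ref[roic == id]
    th <- brute_otsu(vals)
    expect_identical(roil[roic == id] == id, vals < th)
  }
  # thresholds genuinely differ between the two cells
  expect_false(isTRUE(all.equal(brute_otsu(ref[roic == 1]),
                                brute_otsu(ref[roic == 2]))))

  # constant-intensity cell: empty lumen (whole cell treated as wall)
  roic3 <- matrix(1L, 5, 5)
  expect_equal(max(extract_lumen(matrix(42, 5, 5), roic3)), 0)
})

test_that("wall derivation is an exact set difference with consistency
           checks", {
  gen <- mini_gen()
  seg <- mini_seg()
  ids <- segmentation_cell_ids(seg)
  for (id in sample(ids, 5)) {
    expect_equal(sum(seg$roil == id) + sum(seg$roiw == id),
                 sum(seg$roic == id))
  }
  # empty lumen leaves the wall equal to the whole cell
  roic <- matrix(1L, 4, 4)
  roil <- matrix(0L, 4, 4)
  expect_equal(derive_wall(roic, roil), roic)
  # lumen covering the whole cell warns and empties the wall
  expect_warning(w <- derive_wall(roic, roic), class = "rc_empty_wall")
  expect_equal(max(w), 0)
  # lumen outside its cell is a consistency error
  bad <- matrix(0L, 4, 4); bad[1, 1] <- 2L
  expect_error(derive_wall(roic, bad), class = "rc_consistency_error")
})

test_that("cropping keeps exactly the centroid-inside cells", {
  seg <- mini_seg()
  nr <- nrow(seg$roic); nc <- ncol(seg$roic)
  whole <- crop_restrict(seg, c(1, 1, nc, nr))
  expect_equal(max(whole$roic), max(seg$roic))

  cen <- radialcells:::cell_centroids_px(seg$roic)
  left <- crop_restrict(seg, c(1, 1, nc / 2, nr))
  expect_equal(max(left$roic), sum(cen$x <= nc / 2))

  # a 1x1 rectangle on one centroid keeps exactly that cell
  target <- cen[3, ]
  one <- crop_restrict(seg, c(floor(target$x), floor(target$y),
                              ceiling(target$x), ceiling(target$y)))
  expect_equal(max(one$roic), 1)
  expect_equal(sum(one$roic > 0), sum(seg$roic == target$cell_id))

  expect_error(crop_restrict(seg, c(0, 0, 5, 5)), class = "rc_param_error")
})

test_that("label maps stay mutually consistent through the full stage", {
  seg <- mini_seg()
  expect_true(all(seg$roil[seg$roil > 0] == seg$roic[seg$roil > 0]))
  expect_true(all(seg$roiw[seg$roiw > 0] == seg$roic[seg$roiw > 0]))
  expect_true(all((seg$roic > 0) == (seg$roil > 0 | seg$roiw > 0)))
  expect_false(any(seg$roil > 0 & seg$roiw > 0))
  # labels consecutive from 1
  expect_equal(sort(unique(as.vector(seg$roic[seg$roic > 0]))),
               seq_len(max(seg$roic)))
})

test_that("noiseless synthetic tissue is recovered cell for cell", {
  gen <- mini_gen()
  m <- match_segmentation(mini_seg()$roic, gen$truth$label_map, 0.7)
  expect_equal(m$recovered_fraction, 1)
  # watershed adds only the background and pith basins beyond true cells
  expect_lte(m$n_pred, m$n_true + 3)
})
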