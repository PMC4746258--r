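# quadrant-measure context shared by several blocks: the mini fixture with
# a reproducible random signal channel
quant_ctx <- function() {
  fixture("quant_ctx", function() {
    seg <- mini_seg()
    frame <- mini_frame()
    quad <- suppressWarnings(assign_quadrants(seg, frame))
    signal <- withr::with_seed(31, {
      matrix(runif(length(seg$roic), 0, 120), nrow(seg$roic))
    })
    qm <- quantify_roi_quadrants(signal, seg, quad, frame)
    list(seg = seg, frame = frame, quad = quad, signal = signal, qm = qm)
  })
}

test_that("background correction removes an additive constant exactly", {
  roic <- matrix(0L, 20, 20); roic[5:15, 5:15] <- 1L
  pattern <- matrix(0, 20, 20); pattern[roic == 1L] <- seq_len(121)
  signal <- pattern + 30
  corrected <- background_correct(signal, roic)
  expect_equal(attr(corrected, "background"), 30)
  expect_equal(corrected, pattern, ignore_attr = TRUE)

  # zero-median background leaves the raster unchanged
  sig2 <- pattern
  expect_equal(background_correct(sig2, roic), pattern,
               ignore_attr = TRUE)

  # all-background image comes out all zero
  expect_true(all(background_correct(matrix(17, 8, 8),
                                     matrix(0L, 8, 8)) == 0))

  # tissue filling the frame: warned, background 0
  full <- matrix(1L, 6, 6)
  expect_warning(out <- background_correct(matrix(9, 6, 6), full),
                 class = "rc_no_background")
  expect_equal(attr(out, "background"), 0)
})

test_that("per-quadrant statistics match a brute-force pixel recomputation
           exactly", {
  ctx <- quant_ctx()
  seg <- ctx$seg; quad <- ctx$quad; signal <- ctx$signal
  px_area <- ctx$frame$pixel_size_um^2
  maps <- list(C = seg$roic, L = seg$roil, W = seg$roiw)
  ids <- sample(segmentation_cell_ids(seg), 6)
  for (id in ids) {
    for (kind in names(maps)) {
      for (q in 1:4) {
        pix <- maps[[kind]] == id & quad == q
        row <- ctx$qm[ctx$qm$cell_id == id & ctx$qm$roi == kind &
                        ctx$qm$quadrant == q, ]
        expect_equal(row$size, sum(pix) * px_area)
        if (sum(pix) > 0) {
          v <- signal[pix]
          expect_equal(row$mean, mean(v))
          expect_equal(row$std, sqrt(mean((v - mean(v))^2)))
        } else {
          expect_true(is.na(row$mean))
        }
      }
    }
  }
})

test_that("uniform signal yields mean v, std 0, and quadrant locality
           holds", {
  seg <- mini_seg(); frame <- mini_frame()
  quad <- suppressWarnings(assign_quadrants(seg, frame))
  uni <- matrix(55, nrow(seg$roic), ncol(seg$roic))
  qm <- quantify_roi_quadrants(uni, seg, quad, frame)
  nonempty <- qm[qm$size > 0, ]
  expect_true(all(nonempty$mean == 55))
  expect_true(all(nonempty$std == 0))

  # signal restricted to quadrant 3 of one cell's wall: the other wall
  # quadrants read 0
  id <- segmentation_cell_ids(seg)[4]
  sig <- matrix(0, nrow(seg$roic), ncol(seg$roic))
  sig[seg$roiw == id & quad == 3L] <- 80
  qm2 <- quantify_roi_quadrants(sig, seg, quad, frame)
  w <- qm2[qm2$cell_id == id & qm2$roi == "W", ]
  expect_gt(w$mean[w$quadrant == 3], 0)
  expect_true(all(w$mean[w$quadrant != 3 & w$size > 0] == 0))

  expect_error(quantify_roi_quadrants(uni[, 1:10], seg, quad, frame),
               class = "rc_shape_error")
})

test_that("quadrant sizes partition each ROI's area", {
  ctx <- quant_ctx()
  px_area <- ctx$frame$pixel_size_um^2
  sizes <- ctx$qm |>
    dplyr::group_by(cell_id, roi) |>
    dplyr::summarise(size = sum(size), .groups = "drop")
  maps <- list(C = ctx$seg$roic, L = ctx$seg$roil, W = ctx$seg$roiw)
  for (kind in names(maps)) {
    areas <- table(maps[[kind]][maps[[kind]] > 0]) * px_area
    got <- sizes[sizes$roi == kind & sizes$cell_id %in% names(areas), ]
    expect_equal(got$size,
                 as.numeric(areas[as.character(got$cell_id)]))
  }
})

# helper: cells whose wall has pixels in all four quadrants
derive_complete_cells <- function(qm) {
  qm |>
    dplyr::filter(roi == "W") |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(ok = all(size > 0)) |>
    dplyr::filter(ok) |>
    dplyr::pull(cell_id)
}

test_that("derived measures obey their closed forms", {
  ctx <- quant_ctx()
  der <- derive_measures(ctx$qm)
  # total-signal additivity is exact: C = L + W per cell
  expect_equal(der$Cellsignal, der$Lumensignal + der$Wallsignal)
  expect_true(all(der$Cellsignal >= 0))

  # uniform wall signal: RPAmean is exactly 1
  seg <- ctx$seg; frame <- ctx$frame; quad <- ctx$quad
  uni <- matrix(20, nrow(seg$roic), ncol(seg$roic))
  der_u <- derive_measures(quantify_roi_quadrants(uni, seg, quad, frame))
  full_quads <- derive_complete_cells(ctx$qm)
  expect_true(all(abs(der_u$WallRPAmean[der_u$cell_id %in% full_quads] - 1)
                  < 1e-9))
  # uniform lumen: PvD is exactly 0
  expect_true(all(der_u$PvD[!is.na(der_u$PvD)] == 0))

  # signal confined to periclinal quadrants: anticlinal sum 0, RPA flagged
  id <- segmentation_cell_ids(seg)[5]
  sig <- matrix(0, nrow(seg$roic), ncol(seg$roic))
  sig[seg$roiw == id & quad %in% c(3L, 4L)] <- 50
  der_p <- derive_measures(quantify_roi_quadrants(sig, seg, quad, frame))
  expect_true(is.na(der_p$WallRPA[der_p$cell_id == id]))
  expect_gt(der_p$Wallsignal[der_p$cell_id == id], 0)
})

test_that("PvD follows the closed-form coefficient of variation", {
  # one cell, lumen of n pixels with a single bright pixel: CV = sqrt(n-1)
  roic <- matrix(0L, 12, 12); roic[2:11, 2:11] <- 1L
  roil <- matrix(0L, 12, 12); roil[4:9, 4:9] <- 1L
  roiw <- roic; roiw[roil > 0] <- 0L
  seg <- cell_segmentation(roic, roil, roiw)
  frame <- tissue_frame(c(-500, 6.5), 1)
  quad <- assign_quadrants(seg, frame)
  sig <- matrix(0, 12, 12)
  sig[5, 5] <- 1                       # one bright lumen pixel
  qm <- quantify_roi_quadrants(sig, seg, quad, frame)
  der <- derive_measures(qm)
  n <- sum(roil > 0)
  expect_equal(der$PvD, sqrt(n - 1), tolerance = 1e-9)
})

test_that("linearity and mask locality hold exactly", {
  ctx <- quant_ctx()
  der1 <- derive_measures(ctx$qm)
  qm_scaled <- quantify_roi_quadrants(ctx$signal * 3, ctx$seg, ctx$quad,
                                      ctx$frame)
  der3 <- derive_measures(qm_scaled)
  expect_equal(qm_scaled$mean, ctx$qm$mean * 3)
  expect_equal(qm_scaled$std, ctx$qm$std * 3)
  expect_equal(qm_scaled$size, ctx$qm$size)
  expect_equal(der3$Wallsignal, der1$Wallsignal * 3)
  expect_equal(der3$WallRPA, der1$WallRPA)
  expect_equal(der3$PvD, der1$PvD)

  # adding signal outside a cell leaves that cell's measures untouched
  id <- segmentation_cell_ids(ctx$seg)[2]
  outside <- ctx$signal
  outside[ctx$seg$roic != id] <- outside[ctx$seg$roic != id] + 500
  qm_out <- quantify_roi_quadrants(outside, ctx$seg, ctx$quad, ctx$frame)
  expect_equal(qm_out[qm_out$cell_id == id, ],
               ctx$qm[ctx$qm$cell_id == id, ])
})

test_that("class summaries aggregate retained cells only", {
  der <- tibble::tibble(cell_id = 1:6,
                        Wallsignal = c(10, 12, 30, 31, 29, 100))
  preds <- tibble::tibble(cell_id = 1:6,
                          class = c("a", "a", "b", "b", "b", "c"),
                          confidence = c(0.95, 0.6, 0.8, 0.9, 0.95, 0.4))
  s <- suppressMessages(summarize_by_class(der, preds, 0.7))
  ws <- s[s$measure == "Wallsignal", ]
  expect_setequal(ws$class, c("a", "b"))        # class c dropped (logged)
  expect_equal(ws$n_cells[ws$class == "a"], 1)
  expect_equal(ws$sd[ws$class == "a"], 0)       # single retained cell
  expect_equal(ws$mean[ws$class == "b"], 30)

  # raising the threshold never increases a class's n
  s5 <- suppressMessages(summarize_by_class(der, preds, 0.5))
  for (cl in ws$class) {
    expect_lte(ws$n_cells[ws$class == cl],
               s5$n_cells[s5$measure == "Wallsignal" & s5$class == cl])
  }
  # relative scaling normalises by the max class mean
  sr <- suppressMessages(summarize_by_class(der, preds, 0.7,
                                            relative = TRUE))
  wr <- sr[sr$measure == "Wallsignal", ]
  expect_equal(max(wr$rel_mean), 1)

  expect_error(summarize_by_class(der, preds, 0.99),
               class = "rc_empty_result")
})
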