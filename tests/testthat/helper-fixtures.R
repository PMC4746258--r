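# Shared fixtures, built once per test run and cached lazily.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fix)) assign(name, builder(), envir = .fix)
  get(name, envir = .fix)
}

toys <- function() fixture("toys", generate_toy_fixtures)

# compact 3-ring tissue for fast unit tests (~32 cells, 256 px)
mini_spec <- function(seed = 11, ...) {
  rings <- tibble::tibble(
    class = c("inner", "mid", "outer"),
    r_inner_um = c(10, 40, 65),
    r_outer_um = c(40, 65, 85),
    n_cells = c(8L, 12L, 12L),
    cell_size_mean_um2 = c(380, 430, 470),
    cell_size_cv = 0.25,
    wall_thickness_px = c(3, 2, 2),
    wall_mean = c(230, 170, 150),
    wall_sd = 0,
    lumen_mean = 30,
    lumen_sd = 0,
    signal_wall = c(120, 0, 0),
    signal_lumen = 0
  )
  tissue_spec(256L, 0.7, rings, seed = seed, ...)
}

mini_gen <- function() fixture("mini_gen",
                               function() generate_radial_tissue(mini_spec()))

mini_seg <- function() fixture("mini_seg", function() {
  suppressWarnings(segment_cells(mini_gen()$image, segmentation_params(1, 10)))
})

mini_frame <- function() tissue_frame(mini_gen()$truth$spec$center_xy, 0.7)

mini_features <- function() fixture("mini_features", function() {
  seg <- mini_seg()
  compute_feature_table(seg, attr(seg, "smoothed"), mini_frame())
})

# ground-truth class for each watershed cell of the mini fixture (by IoU)
mini_truth_classes <- function() fixture("mini_truth_classes", function() {
  gen <- mini_gen()
  m <- match_segmentation(mini_seg()$roic, gen$truth$label_map, 0.7)
  m$matches |>
    dplyr::filter(.data$iou >= 0.7) |>
    dplyr::inner_join(
      dplyr::select(gen$truth$cells, true_id = "cell_id", "class"),
      by = "true_id") |>
    dplyr::transmute(cell_id = .data$pred_id, class = .data$class)
})

# the mini fixture written out as TIFF training/test images, plus a
# trained iteration, shared by the pipeline and acceptance tests
pipeline_ctx <- function() {
  fixture("pipeline_ctx", function() {
    root <- file.path(tempdir(), "rc_pipeline_fixture")
    dir.create(root, showWarnings = FALSE)
    gen_a <- mini_gen()
    gen_b <- generate_radial_tissue(mini_spec(seed = 23))
    path_a <- file.path(root, "P1_LM10_Col_21d_Hyp_BR1.tif")
    path_b <- file.path(root, "P2_LM10_Col_21d_Hyp_BR2.tif")
    write_two_channel_image(gen_a$image, path_a)
    write_two_channel_image(gen_b$image, path_b)
    ctr <- gen_a$truth$spec$center_xy
    images <- tibble::tibble(
      image_id = c("img_a", "img_b"),
      path = c(path_a, path_b),
      center_x = ctr[1], center_y = ctr[2])
    ann <- dplyr::mutate(mini_truth_classes(), image_id = "img_a",
                         .before = 1)
    list(root = root, images = images, annotations = ann,
         gen_a = gen_a, gen_b = gen_b)
  })
}

trained_iteration <- function() {
  fixture("trained_iteration", function() {
    ctx <- pipeline_ctx()
    run_training(ctx$images[1, ], ctx$annotations, pixel_size_um = 0.7,
                 n_trees = 200, seed = 41, out_root = ctx$root,
                 iteration_id = "it_main", plots = TRUE)
  })
}

# a synthetic feature table with a single informative feature (s.area);
# all other features are standard-normal noise
synthetic_feature_table <- function(n_per_class = 100, seed = 99,
                                    shift = 6) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    tbl <- tibble::as_tibble(
      setNames(as.data.frame(matrix(rnorm(n * 22), n, 22)), feature_names()))
    tbl$s.area <- rnorm(n, rep(c(0, shift), each = n_per_class))
    dplyr::bind_cols(tibble::tibble(cell_id = seq_len(n)), tbl)
  })
}

synthetic_annotations <- function(n_per_class = 100) {
  tibble::tibble(cell_id = seq_len(2 * n_per_class),
                 class = rep(c("a", "b"), each = n_per_class))
}

# disk mask of radius r (pixels) centered in a square matrix
disk_mask <- function(r, size = 2 * r + 5) {
  ctr <- (size + 1) / 2
  x <- matrix(rep(seq_len(size), each = size), size)
  y <- matrix(rep(seq_len(size), times = size), size)
  (x - ctr)^2 + (y - ctr)^2 <= r^2
}

# build a one-cell segmentation from a mask (whole cell = wall, no lumen)
mask_segmentation <- function(mask) {
  roic <- matrix(0L, nrow(mask), ncol(mask))
  roic[mask] <- 1L
  cell_segmentation(roic, matrix(0L, nrow(mask), ncol(mask)), roic)
}
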