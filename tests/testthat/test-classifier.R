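test_that("a single informative feature drives accuracy and importance", {
  ft <- synthetic_feature_table()
  ann <- synthetic_annotations()
  model <- train_random_forest(ft, ann, n_trees = 300, seed = 5)
  expect_gte(1 - model$oob_error, 0.98)
  ranked <- rank_feature_importance(model)
  expect_equal(ranked$feature[1], "s.area")
  expect_equal(nrow(ranked), length(default_feature_subset()))
})

test_that("pure-noise feature scores sit below the permutation null", {
  ft <- synthetic_feature_table(n_per_class = 60)
  ann <- synthetic_annotations(n_per_class = 60)
  model <- train_random_forest(ft, ann, n_trees = 150, seed = 5)
  ranked <- rank_feature_importance(model)
  noise_scores <- ranked$permutation[ranked$feature != "s.area"]

  # permutation-null oracle: retrain with class labels shuffled, so every
  # feature is noise; the 95th percentile of those scores bounds what
  # chance alone produces
  null_scores <- unlist(lapply(1:8, function(i) {
    ann_p <- ann
    ann_p$class <- withr::with_seed(1000 + i, sample(ann_p$class))
    m <- train_random_forest(ft, ann_p, n_trees = 150, seed = 5)
    m$importances$permutation
  }))
  cutoff <- quantile(null_scores, 0.95)
  expect_gte(mean(noise_scores <= cutoff), 0.8)
  expect_gt(ranked$permutation[1], max(null_scores))
})

test_that("the default subset is the 18 features minus Cartesian
           coordinates", {
  expect_equal(length(default_feature_subset()), 18)
  expect_setequal(setdiff(feature_names(), default_feature_subset()),
                  c("m.cx", "m.cy", "Xnew", "Ynew"))
  # the misspelt historical alias is accepted and canonicalised
  m <- train_random_forest(synthetic_feature_table(30),
                           synthetic_annotations(30),
                           feature_subset = c("s.area", "m.eccenticity"),
                           n_trees = 50, seed = 1)
  expect_setequal(m$feature_subset, c("s.area", "m.eccentricity"))
})

test_that("training errors are specific and early", {
  ft <- synthetic_feature_table(20)
  ann <- synthetic_annotations(20)
  expect_error(train_random_forest(ft, ann, n_trees = 10, seed = 1,
                                   feature_subset = c("s.area", "bogus")),
               "bogus", class = "rc_feature_error")
  expect_error(train_random_forest(ft, ann, n_trees = 10, seed = 1,
                                   class_names = c("a", "b", "ghost")),
               "ghost", class = "rc_annotation_error")
  expect_error(train_random_forest(ft, ann, n_trees = 10),
               class = "rc_param_error")   # seed is mandatory
  bad_ann <- rbind(ann, tibble::tibble(cell_id = 9999L, class = "a"))
  expect_error(train_random_forest(ft, bad_ann, n_trees = 10, seed = 1),
               class = "rc_annotation_error")
})

test_that("identical seeds reproduce identical models and predictions", {
  ft <- synthetic_feature_table(40)
  ann <- synthetic_annotations(40)
  holdout <- synthetic_feature_table(25, seed = 123)
  m1 <- train_random_forest(ft, ann, n_trees = 100, seed = 7)
  m2 <- train_random_forest(ft, ann, n_trees = 100, seed = 7)
  expect_equal(predict_with_confidence(m1, holdout),
               predict_with_confidence(m2, holdout))
  expect_equal(m1$importances, m2$importances)
})

test_that("confidence is the winning-class vote fraction", {
  ft <- synthetic_feature_table(80, shift = 10)
  ann <- synthetic_annotations(80)
  model <- train_random_forest(ft, ann, n_trees = 200, seed = 3)
  preds <- predict_with_confidence(model, ft)
  votes <- as.matrix(preds[, paste0("vote_", model$class_names)])
  expect_equal(rowSums(votes), rep(1, nrow(preds)), tolerance = 1e-9)
  expect_equal(preds$confidence, apply(votes, 1, max))

  # deep inside a well-separated class: near-unanimous
  deep <- ft[c(1, 160), ]
  pd <- predict_with_confidence(model, deep)
  expect_true(all(pd$confidence >= 0.9))

  # a probe far from both classes along s.area's midpoint: ambivalent
  probe <- ft[1, ]
  probe$s.area <- 5   # midpoint of the 0 / 10 class means
  probe[setdiff(feature_names(), "s.area")] <- 0
  pm <- predict_with_confidence(model, probe)
  expect_gte(pm$confidence, 0.35)
  expect_lte(pm$confidence, 0.65)

  # unanimity: classes separated in every feature, so each tree's first
  # split isolates them and an extreme point gets every vote: exactly 1
  ft_sep <- synthetic_feature_table(40)
  ft_sep[41:80, feature_names()] <- ft_sep[41:80, feature_names()] + 50
  m_sep <- train_random_forest(ft_sep, synthetic_annotations(40),
                               n_trees = 150, seed = 2)
  extreme <- ft_sep[1, ]
  extreme[feature_names()] <- 200
  expect_equal(predict_with_confidence(m_sep, extreme)$confidence, 1.0)

  expect_error(predict_with_confidence(model, ft[, 1:5]),
               class = "rc_feature_error")
})

test_that("confidence filtering is nested and monotone in retention", {
  ft <- synthetic_feature_table(60, shift = 2)  # overlapping classes
  model <- train_random_forest(ft, synthetic_annotations(60),
                               n_trees = 200, seed = 9)
  preds <- predict_with_confidence(model, synthetic_feature_table(60, seed = 77,
                                                                  shift = 2))
  r0 <- filter_by_confidence(preds, 0)
  r5 <- filter_by_confidence(preds, 0.5)
  r7 <- filter_by_confidence(preds, 0.7)
  r9 <- filter_by_confidence(preds, 0.9)
  expect_equal(nrow(r0), nrow(preds))
  expect_true(all(r9$cell_id %in% r7$cell_id))
  expect_true(all(r7$cell_id %in% r5$cell_id))
  r1 <- filter_by_confidence(preds, 1.0)
  expect_true(all(r1$confidence == 1))
  expect_error(filter_by_confidence(preds, 1.5), class = "rc_param_error")
})

test_that("tidy and glance expose the fitted forest broom-style", {
  model <- train_random_forest(synthetic_feature_table(30),
                               synthetic_annotations(30),
                               n_trees = 50, seed = 2)
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("feature", "permutation", "impurity"))
  gl <- glance(model)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_trees, 50)
  expect_equal(gl$n_classes, 2)
})

test_that("ring classes are recovered on held-out synthetic tissue", {
  gen <- mini_gen()
  ft <- mini_features()
  ann <- mini_truth_classes()
  model <- train_random_forest(ft, ann, n_trees = 300, seed = 13)
  # held-out tissue from the same spec, different seed
  gen2 <- generate_radial_tissue(mini_spec(seed = 23))
  seg2 <- suppressWarnings(segment_cells(gen2$image,
                                         segmentation_params(1, 10)))
  ft2 <- compute_feature_table(seg2, attr(seg2, "smoothed"),
                               tissue_frame(gen2$truth$spec$center_xy, 0.7))
  preds <- predict_with_confidence(model, ft2)
  m2 <- match_segmentation(seg2$roic, gen2$truth$label_map, 0.7)
  truth2 <- m2$matches |>
    dplyr::filter(iou >= 0.7) |>
    dplyr::inner_join(dplyr::select(gen2$truth$cells, true_id = cell_id,
                                    true = class), by = "true_id")
  joined <- dplyr::inner_join(filter_by_confidence(preds, 0.7),
                              dplyr::select(truth2, cell_id = pred_id, true),
                              by = "cell_id")
  expect_gte(mean(joined$class == joined$true), 0.95)
})
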