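test_that("CellTracker expansion reproduces ground-truth types when separable", {
  sc <- shared_scene()
  cells <- shared_scene_cells()
  truth <- sc$truth[match(cells$id, sc$truth$id), ]
  ann_ids <- seq_len(nrow(cells)) %in% seq(1, nrow(cells), by = 2)
  ann <- tibble::tibble(id = cells$id[ann_ids],
                        celltracker_positive =
                          truth$type[ann_ids] == "fibroblast")
  ct <- celltracker_svm(cells, ann, seed = 0L)
  types <- expand_labels_with_celltracker(cells, ct)
  expect_equal(types, truth$type)
  # labels partition the record set
  expect_equal(sum(types == "tumor") + sum(types == "fibroblast"),
               nrow(cells))
  # deterministic given the model
  expect_identical(types, expand_labels_with_celltracker(cells, ct))
  expect_error(expand_labels_with_celltracker(
    cells, train_marker_svm(matrix(rnorm(20), ncol = 1),
                            rep(c(TRUE, FALSE), 10), marker = "ki67")),
    "CellTracker")
})

test_that("cell-type features expose volume, shape and collagen context", {
  cells <- shared_scene_cells()
  f <- celltype_features(cells)
  expect_equal(ncol(f), 4L)
  expect_equal(unname(f[2, 1:2]),
               unname(c(cells$volume_um3[2], cells$elongation[2])))
  one <- cells[1, ]
  one$outer_empty <- TRUE
  expect_equal(unname(celltype_features(one)[1, 3]), 0)
  # volume modes alone separate typical fibroblast vs tumor records
  sc <- shared_scene()
  truth <- sc$truth[match(cells$id, sc$truth$id), ]
  expect_gt(mean(f[truth$type == "tumor", 1]),
            mean(f[truth$type == "fibroblast", 1]))
})

test_that("collagen context beats a volume-only rule when volumes overlap", {
  # broader volume laws force small round tumor nuclei into the fibroblast
  # volume range, the confusion case that motivates the multi-feature design
  sc <- generate_scene(scene_params(radius_um = 48, n_tumor = 40L,
                                    n_fibroblast = 60L, volume_gsd = 1.6,
                                    noise_sd = 2, seed = 2L))
  filt <- filter_nuclei_by_volume(sc$labels)
  cells <- build_cell_table(sc$volume, filt$labels, analysis_config(seed = 2L))
  truth <- sc$truth[match(cells$id, sc$truth$id), ]
  f <- celltype_features(cells)
  set.seed(2)
  tr <- sample(nrow(cells), floor(nrow(cells) * 0.6))
  full <- train_celltype_svm(f[tr, ], truth$type[tr], seed = 2L)
  acc_full <- mean(predict_celltype(full, f[-tr, , drop = FALSE]) ==
                     truth$type[-tr])
  vol_only <- train_celltype_svm(f[tr, 1, drop = FALSE], truth$type[tr],
                                 seed = 2L)
  acc_vol <- mean(predict_celltype(vol_only, f[-tr, 1, drop = FALSE]) ==
                    truth$type[-tr])
  expect_gte(acc_full, 0.95)
  expect_gt(acc_full, acc_vol)
  # retraining under the same seed gives identical parameters
  expect_identical(tidy(full),
                   tidy(train_celltype_svm(f[tr, ], truth$type[tr],
                                           seed = 2L)))
  expect_error(train_celltype_svm(f[tr, ], rep("tumor", length(tr))),
               "both classes|tumor")
})

test_that("CNN crops are centered, padded and carry the focal mask only", {
  sc <- shared_scene()
  vol <- sc$volume
  lab <- sc$labels
  id <- label_ids(lab)[1]
  crop <- crop_for_cnn(vol, lab, id)
  expect_equal(dim(crop), c(3L, 48L, 64L, 64L))
  # third channel is the binary focal-nucleus mask
  expect_true(all(crop[3, , , ] %in% c(0, 1)))
  expect_lte(sum(crop[3, , , ]), sum(lab$labels == id))
  expect_gt(sum(crop[3, , , ]), 0)
  # a nucleus at the image corner still yields a full zero-padded crop
  corner_lab <- array(0L, c(30, 30, 30))
  corner_lab[1:4, 1:4, 1:4] <- 1L
  clv <- label_volume(corner_lab, iso1())
  cvol <- multichannel_volume(list(nuclei = array(7, c(30, 30, 30)),
                                   collagen1 = array(3, c(30, 30, 30))),
                              iso1())
  cc <- crop_for_cnn(cvol, clv, 1L)
  expect_equal(dim(cc), c(3L, 48L, 64L, 64L))
  expect_equal(sum(cc[3, , , ]), 64)            # all focal voxels inside
  expect_true(all(cc[1, 1:10, , ] == 0))        # padded region exactly 0
  expect_error(crop_for_cnn(cvol, clv, 9L), "not present")
})

test_that("corrected counts decompose totals and conserve them", {
  rec <- tibble::tibble(id = 1:2000)
  preds <- c(rep("fibroblast", 1500), rep("tumor", 500))
  cc <- corrected_counts(rec, preds)
  expect_equal(cc$n_tumor, 500)
  expect_equal(cc$n_fibroblast + cc$n_tumor, cc$total)
  mono <- corrected_counts(tibble::tibble(id = 1:100), rep("tumor", 100))
  expect_equal(mono$n_fibroblast, 0)
  expect_equal(mono$n_tumor, 100)
  expect_error(corrected_counts(rec, preds[-1]), "do not match")
  agg <- aggregate_corrected_counts(list(cc, cc))
  expect_equal(agg$sd[agg$metric == "total"], 0)
})

test_that("an end-to-end synthetic co-culture recovers the seeded split", {
  sc <- shared_scene()                         # 15 tumor : 45 fibroblast
  cells <- shared_scene_cells()
  truth <- sc$truth[match(cells$id, sc$truth$id), ]
  set.seed(0)
  tr <- sample(nrow(cells), floor(nrow(cells) * 0.6))
  model <- train_celltype_svm(celltype_features(cells)[tr, ],
                              truth$type[tr], seed = 0L)
  cc <- corrected_counts(cells, predict_celltype(model, cells))
  true_t <- sum(truth$type == "tumor")
  true_f <- sum(truth$type == "fibroblast")
  expect_lte(abs(cc$n_tumor - true_t) / true_t, 0.05)
  expect_lte(abs(cc$n_fibroblast - true_f) / true_f, 0.05)
})
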