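test_that("linear SVM separates a clean toy problem deterministically", {
  set.seed(1)
  x <- matrix(c(rnorm(25, 0, 0.1), rnorm(25, 10, 0.1)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 25)
  m1 <- train_marker_svm(x, y, seed = 2L, marker = "toy")
  expect_true(all(m1$core$train_pred == y))              # 100% on training
  m2 <- train_marker_svm(x, y, seed = 2L, marker = "toy")
  expect_identical(tidy(m1), tidy(m2))                   # same parameters
  # standardization round trip: model reproduces training predictions
  expect_identical(predict_marker(m1, x)$positive, m1$core$train_pred)
  expect_error(train_marker_svm(x, rep(TRUE, 50), seed = 1L), "both classes")
})

test_that("gate fractions use the full denominator and stay consistent", {
  set.seed(2)
  x <- matrix(c(rnorm(20, 0), rnorm(20, 10)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 20)
  m <- train_marker_svm(x, y, seed = 1L)
  all_pos <- matrix(rnorm(30, 10), ncol = 1)
  g <- predict_marker(m, all_pos)
  expect_equal(gate_fraction(g), 1.0)
  all_neg <- matrix(rnorm(30, 0), ncol = 1)
  g0 <- predict_marker(m, all_neg)
  expect_equal(gate_fraction(g0), 0.0)
  mixed <- matrix(c(rnorm(7, 0), rnorm(13, 10)), ncol = 1)
  gm <- predict_marker(m, mixed)
  expect_equal(gate_fraction(gm) * nrow(gm), round(gate_fraction(gm) * nrow(gm)))
})

test_that("marker gates recover ground truth on synthetic scenes", {
  sc <- shared_scene()            # noise_sd 2, marker amplitude 10 (5x)
  cells <- shared_scene_cells()
  truth <- sc$truth[match(cells$id, sc$truth$id), ]
  set.seed(0)
  tr <- sample(nrow(cells), floor(nrow(cells) / 2))
  for (marker in c("ki67", "lod")) {
    feats <- marker_features(cells, marker)
    states <- truth[[marker]]
    m <- train_marker_svm(feats[tr, , drop = FALSE], states[tr],
                          seed = 0L, marker = marker)
    pred <- predict_marker(m, cells[-tr, ])
    expect_gte(mean(pred$positive == states[-tr]), 0.95)
  }
  # gating invariant under relabeling: predictions depend on features only
  m <- train_marker_svm(ki67_features(cells)[tr, ], truth$ki67[tr],
                        seed = 0L, marker = "ki67")
  shuffled <- cells
  shuffled$id <- shuffled$id + 1000L
  expect_equal(predict_marker(m, shuffled)$positive,
               predict_marker(m, cells)$positive)
})

test_that("feature extractors project the documented columns in order", {
  cells <- shared_scene_cells()
  f3 <- ki67_features(cells)
  expect_equal(ncol(f3), 3L)
  expect_equal(unname(f3[1, ]),
               unname(c(cells$nuclei_nuc_smooth_mean[1],
                        cells$ki67_nuc_smooth_mean[1],
                        cells$ki67_out_smooth_mean[1])))
  f2 <- lod_features(cells)
  expect_equal(ncol(f2), 2L)
  # a missing channel is reported by name
  expect_error(lod_features(dplyr::select(cells, -dplyr::starts_with("lod"))),
               "lod")
  # empty outer region zeroes the outer feature
  one <- cells[1, ]
  one$outer_empty <- TRUE
  expect_equal(unname(ki67_features(one)[1, 3]), 0)
})

test_that("CellTracker SVM thresholds a bimodal signal near-perfectly", {
  set.seed(0)
  n <- 130                                     # annotation-sized toy
  pos <- rbinom(n, 1, 0.5) == 1
  feat <- matrix(ifelse(pos, rnorm(n, 100, 5), rnorm(n, 10, 5)), ncol = 1)
  m <- train_marker_svm(feat, pos, seed = 0L, marker = "celltracker")
  # decision threshold lies between the modes
  resample_pos <- rbinom(500, 1, 0.5) == 1
  resample <- matrix(ifelse(resample_pos, rnorm(500, 100, 5),
                            rnorm(500, 10, 5)), ncol = 1)
  acc <- mean(predict_marker(m, resample)$positive == resample_pos)
  expect_gte(acc, 0.99)
  # the cell-table interface defaults to sigma = 1
  cells <- shared_scene_cells()
  sc <- shared_scene()
  ann <- tibble::tibble(
    id = cells$id,
    celltracker_positive = sc$truth$type[match(cells$id, sc$truth$id)] ==
      "fibroblast")
  ct <- celltracker_svm(cells, ann, seed = 0L)
  expect_equal(ct$sigma, 1)
  expect_error(celltracker_svm(cells,
                               dplyr::mutate(ann, celltracker_positive = TRUE),
                               seed = 0L), "both classes")
})

test_that("Cas3 index is aggregate intensity per nucleus", {
  ch <- array(0, c(5, 5, 5))
  ch[1:10] <- 100                       # total above-threshold = 1000
  expect_equal(cas3_index(ch, 10, 10), 100)
  expect_equal(cas3_index(ch, 10, 20), 50)          # doubling nuclei halves
  expect_equal(cas3_index(array(5, c(4, 4, 4)), 10, 7), 0)  # all background
  expect_error(cas3_index(ch, 10, 0), ">= 1")
})

test_that("models survive the YAML sidecar round trip exactly", {
  set.seed(3)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 5), ncol = 2))
  y <- rep(c(FALSE, TRUE), each = 30)
  colnames(x) <- c("a", "b")
  m <- train_marker_svm(x, y, seed = 1L, marker = "ki67")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  back <- read_model(path)
  newx <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(predict_marker(back, newx)$positive,
                   predict_marker(m, newx)$positive)
  expect_equal(tidy(back), tidy(m))
})
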