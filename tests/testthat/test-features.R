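test_that("volume filter excludes strictly outside 300-3000 um3 with reasons", {
  # cuboids of exactly 250, 300, 1500, 3000, 3200 um^3 at 1 um spacing
  lv <- make_cuboid_labels(list(c(5L, 5L, 10L),    # 250
                                c(5L, 6L, 10L),    # 300
                                c(10L, 10L, 15L),  # 1500
                                c(10L, 15L, 20L),  # 3000
                                c(10L, 16L, 20L))) # 3200
  res <- filter_nuclei_by_volume(lv, 300, 3000)
  expect_setequal(label_ids(res$labels), c(2L, 3L, 4L))  # 300/1500/3000 kept
  expect_equal(nrow(res$excluded), 2L)
  expect_equal(res$excluded$reason[res$excluded$id == 1L], "small")
  expect_equal(res$excluded$reason[res$excluded$id == 5L], "large")
  expect_equal(sort(res$excluded$volume_um3), c(250, 3200))
  # retained + excluded partition the original ids
  expect_setequal(c(label_ids(res$labels), res$excluded$id), label_ids(lv))
  # survivors untouched
  kept <- lv$labels
  kept[kept %in% c(1L, 5L)] <- 0L
  expect_identical(res$labels$labels, kept)
  # all-in-range input passes through unchanged
  ok <- filter_nuclei_by_volume(make_cuboid_labels(list(c(8L, 8L, 8L))))
  expect_equal(nrow(ok$excluded), 0L)
  # filtering away everything is an error
  expect_error(filter_nuclei_by_volume(make_cuboid_labels(list(c(4L, 5L, 5L)))),
               "every nucleus")
  expect_error(filter_nuclei_by_volume(
    label_volume(array(0L, c(3, 3, 3)), iso1())), "no nuclei")
})

test_that("masked smoothing matches a brute-force normalized convolution", {
  # bright 5^3 cube (100) in zero background, threshold 10, sigma 1
  img <- array(0, c(15, 15, 15))
  img[6:10, 6:10, 6:10] <- 100
  sm <- masked_gaussian_smooth(img, 10, 1)
  inside <- sm[6:10, 6:10, 6:10]
  expect_true(all(inside >= 90 & inside <= 100 + 1e-9))
  # no spill of magnitude > 1 beyond 4 voxels from the cube
  far <- array(TRUE, c(15, 15, 15))
  far[2:14, 2:14, 2:14] <- FALSE
  expect_true(all(abs(sm[far]) <= 1))
  # oracle equivalence on a small noisy image
  set.seed(21)
  small <- array(runif(6^3, 0, 50), c(6, 6, 6))
  expect_equal(masked_gaussian_smooth(small, 20, 1),
               bf_masked_gaussian(small, 20, 1), tolerance = 1e-10)
})

test_that("per-nucleus intensity statistics use interpolated percentiles", {
  lab <- array(0L, c(5, 5, 8))
  lab[1:5, 1:5, 1:4] <- 1L
  lv <- label_volume(lab, iso1())
  ch <- array(0, c(5, 5, 8))
  ch[lab == 1L] <- 1:100
  st <- nucleus_intensity_stats(ch, lv, 1L)
  expect_equal(st$p95, 95.05)
  expect_equal(st$median, 50.5)
  expect_equal(st$max, 100)
  # constant nucleus
  ch7 <- array(7, c(5, 5, 8))
  st7 <- nucleus_intensity_stats(ch7, lv, 1L)
  expect_equal(unlist(st7[c("mean", "median", "max", "p95")]),
               c(mean = 7, median = 7, max = 7, p95 = 7))
  expect_equal(st7$sd, 0)
  # invariance under relabeling of other nuclei
  lab2 <- lab
  lab2[1, 1, 8] <- 9L
  st_b <- nucleus_intensity_stats(ch, label_volume(lab2, iso1()), 1L)
  expect_equal(st_b, st)
  expect_error(nucleus_intensity_stats(ch, lv, 42L), "not present")
})

test_that("outer region is the dilation ring minus every nucleus", {
  # isolated 1-voxel nucleus: 6-connected distance-<=4 ball minus center
  lab <- array(0L, c(11, 11, 11)); lab[6, 6, 6] <- 1L
  lv <- label_volume(lab, iso1())
  outer <- outer_region_mask(lv, 1L, 4L)
  expect_equal(sum(outer), 128L)   # 129-voxel L1 ball minus the nucleus
  expect_false(outer[6, 6, 6])
  # a nucleus enclosed by a thick shell of other nuclei has no outer region
  enc <- array(0L, c(13, 13, 13))
  enc[3:11, 3:11, 3:11] <- 2L
  enc[7, 7, 7] <- 1L
  outer2 <- outer_region_mask(label_volume(enc, iso1()), 1L, 4L)
  expect_equal(sum(outer2), 0L)
  # outer region never intersects any label
  sc <- shared_scene()
  for (id in utils::head(label_ids(sc$labels), 5)) {
    om <- outer_region_mask(sc$labels, id)
    expect_equal(sum(om & (sc$labels$labels > 0L)), 0L)
  }
})

test_that("morphology recovers volume, centroid and axis ratio", {
  lab <- array(0L, c(14, 14, 14))
  lab[3:12, 3:12, 3:12] <- 1L                 # 10^3 cube
  lv <- label_volume(lab, iso1())
  m <- nucleus_morphology(lv, 1L)
  expect_equal(m$volume_um3, 1000)
  expect_equal(m$elongation, 1, tolerance = 1e-6)
  expect_equal(c(m$centroid_z_um, m$centroid_y_um, m$centroid_x_um),
               c(7.5, 7.5, 7.5), tolerance = 0.5)
  # axis-aligned ellipsoid with semi-axes (10, 4, 4) um -> ratio 2.5
  n <- 25; ctr <- 13
  co <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  ell <- ((co$z - ctr) / 10)^2 + ((co$y - ctr) / 4)^2 + ((co$x - ctr) / 4)^2 <= 1
  lab2 <- array(as.integer(ell), c(n, n, n))
  m2 <- nucleus_morphology(label_volume(lab2, iso1()), 1L)
  expect_lt(abs(m2$elongation - 2.5) / 2.5, 0.10)
  expect_error(nucleus_morphology(lv, 3L), "not present")
})

test_that("cell table has one exact record per surviving nucleus", {
  sc <- shared_scene()
  cells <- shared_scene_cells()
  filt <- shared_scene_filtered()
  expect_equal(nrow(cells), n_instances(filt$labels))
  expect_identical(cells$id, label_ids(filt$labels))     # ordered by id
  # volumes match the truth table (voxel-count oracle) exactly
  truth <- sc$truth[match(cells$id, sc$truth$id), ]
  expect_equal(cells$volume_um3, truth$volume_um3)
  # Ki-67 signal sits in positive nuclei
  pos <- truth$ki67
  if (any(pos) && any(!pos)) {
    expect_gt(mean(cells$ki67_nuc_raw_mean[pos]),
              mean(cells$ki67_nuc_raw_mean[!pos]))
  }
  # shape mismatch errors
  bad <- multichannel_volume(list(nuclei = array(1, c(4, 4, 4))), iso1())
  expect_error(build_cell_table(bad, filt$labels), "shapes differ")
})
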