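test_that("closure of a convex solid is a near-identity", {
  ball <- make_ball(25)
  lv <- label_volume(array(as.integer(ball), dim(ball)), iso1())
  mask <- build_spheroid_mask(lv, n_iter = 40L)
  v0 <- sum(ball); v1 <- sum(mask)
  expect_lt(abs(v1 - v0) / v0, 0.01)
  expect_true(all(mask[ball]))                          # contains the nuclei
  expect_equal(max(label_connected(mask)), 1L)          # one component
})

test_that("spheroid mask keeps only the largest aggregate", {
  # main aggregate: a ball-shaped nucleus; far away: a tiny detached one
  ball <- make_ball(8)
  lab <- array(0L, c(dim(ball)[1], dim(ball)[2], 100))
  lab[, , seq_len(dim(ball)[3])][ball] <- 1L
  lab[10, 10, 95] <- 2L                                 # detached fragment
  lv <- label_volume(lab, iso1())
  mask <- build_spheroid_mask(lv, n_iter = 10L)
  expect_equal(max(label_connected(mask)), 1L)          # connected output
  expect_true(all(mask[lab == 1L]))                     # main aggregate kept
  expect_false(any(mask[lab == 2L]))                    # fragment dropped
  # two 1-voxel nuclei far apart: the larger-component rule keeps one
  two <- array(0L, c(7, 7, 120))
  two[4, 4, 5] <- 1L; two[4, 4, 110] <- 2L
  m2 <- build_spheroid_mask(label_volume(two, iso1()), n_iter = 10L)
  expect_equal(max(label_connected(m2)), 1L)
  expect_equal(sum(m2[two > 0L]), 1L)
  expect_error(build_spheroid_mask(
    label_volume(array(0L, c(4, 4, 4)), iso1())), "no nuclei")
})

test_that("void fraction and density follow their definitions", {
  mask <- array(FALSE, c(20, 20, 20))
  mask[1:10, 1:20, 1:20] <- TRUE                        # 4000 voxels
  lab <- array(0L, c(20, 20, 20))
  lab[1:10, 1:10, 1:10] <- 1L                           # 1000 voxels
  lv <- label_volume(lab, iso1())
  expect_equal(void_fraction(mask, lv), 0.75)
  full <- label_volume(array(1L, c(20, 20, 20)), iso1())
  expect_equal(void_fraction(mask, full), 0)
  expect_equal(nuclei_density(100, 1e6), 1e-4)
  expect_equal(nuclei_density(100, 2e6), 0.5e-4)        # volume doubles
  expect_equal(nuclei_density(0, 1e6), 0)
})

test_that("largest equivalent xy diameter matches the analytic sphere", {
  ball <- make_ball(50)
  d <- largest_equivalent_xy_diameter(ball, iso1())
  expect_lt(abs(d - 100) / 100, 0.02)
  # translation invariance
  shifted <- array(FALSE, dim(ball) + c(0L, 4L, 4L))
  shifted[, 5:(4 + dim(ball)[2]), 5:(4 + dim(ball)[3])] <- ball
  expect_equal(largest_equivalent_xy_diameter(shifted, iso1()), d)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(largest_equivalent_xy_diameter(one, iso1()), 2 / sqrt(pi))
})

test_that("center and hull distances decompose the ball radius", {
  R <- 40
  ball <- make_ball(R)
  ctr <- (dim(ball)[1] + 1) / 2
  at_center <- nucleus_distances(ball, c(ctr, ctr, ctr), iso1())
  expect_lt(at_center$dist_center_um, 0.5)
  expect_lt(abs(at_center$dist_hull_um - R), 1.5)
  set.seed(8)
  for (i in 1:25) {
    repeat {
      p <- runif(3, -0.9, 0.9) * R
      if (sqrt(sum(p^2)) < 0.9 * R) break
    }
    dd <- nucleus_distances(ball, p + ctr, iso1())
    expect_lt(abs(dd$dist_center_um + dd$dist_hull_um - R), 2)
  }
  # centroid outside the mask: flagged, hull distance 0
  out <- nucleus_distances(ball, c(1, 1, 1), iso1())
  expect_true(out$outside_mask)
  expect_equal(out$dist_hull_um, 0)
})

test_that("equi-volumetric shells tile the mask and nest monotonically", {
  ball <- make_ball(30)
  part <- partition_shells(ball, 3L, iso1())
  counts <- vapply(part$masks, sum, numeric(1))
  expect_equal(sum(counts), sum(ball))                  # exact tiling
  inter <- part$masks$outer & part$masks$middle
  expect_false(any(inter))
  expect_false(any(part$masks$middle & part$masks$inner))
  expect_false(any(part$masks$outer & part$masks$inner))
  # inner shell of a ball is itself a (connected) ball
  expect_equal(max(label_connected(part$masks$inner)), 1L)
  # nesting: inner inside mask-minus-outer inside mask
  expect_true(all(ball[part$masks$inner]))
  expect_true(all(!part$masks$inner[part$masks$outer]))
  expect_error(partition_shells(array(FALSE, c(4, 4, 4))), "empty")
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_error(partition_shells(one, 3L), "non-empty shells")
})

test_that("shell statistics distribute uniform nuclei evenly", {
  R <- 40
  ball <- make_ball(R)
  part <- partition_shells(ball, 3L, iso1())
  ctr <- (dim(ball)[1] + 1) / 2
  set.seed(0)
  pts <- matrix(runif(3 * 3000, -1, 1), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 1, , drop = FALSE][1:400, ] * R + ctr
  rec <- tibble::tibble(centroid_z_um = pts[, 1], centroid_y_um = pts[, 2],
                        centroid_x_um = pts[, 3], volume_um3 = 500,
                        rim_marker = FALSE)
  # tag nuclei near the surface as marker-positive
  r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  rec$rim_marker <- r > 0.95 * R
  st <- shell_statistics(part, rec, markers = "rim_marker")
  expect_equal(sum(st$n_nuclei), nrow(rec))
  # equal shell volumes -> equal expected counts under uniformity
  chi <- stats::chisq.test(st$n_nuclei, p = st$achieved_fraction)
  expect_gt(chi$p.value, 0.01)
  # rim markers land in the outer shell, percentages sum to 100
  expect_equal(st$pct_rim_marker[st$shell == "outer"], 100)
  expect_equal(sum(st$pct_rim_marker), 100, tolerance = 1e-9)
  expect_equal(st$density_per_um3, st$n_nuclei / st$volume_um3)
})
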