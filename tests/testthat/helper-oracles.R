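# Independent brute-force oracles. These deliberately avoid the package's
# compiled/vectorized code paths: plain R loops over voxel sets.

# direct masked normalized convolution with a full (non-separable) Gaussian
# kernel, truncated at 4 sigma
bf_masked_gaussian <- function(channel, threshold, sigma) {
  d <- dim(channel)
  r <- ceiling(4 * sigma)
  fg <- channel > threshold
  out <- array(0, dim = d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    num <- 0; den <- 0
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3])
        next
      if (!fg[zz, yy, xx]) next
      w <- exp(-(dz^2 + dy^2 + dx^2) / (2 * sigma^2))
      num <- num + w * channel[zz, yy, xx]
      den <- den + w
    }
    if (den > 1e-12) out[z, y, x] <- num / den
  }
  out
}

# brute-force SEG/DET on integer label arrays via explicit voxel sets
bf_seg_det <- function(gt, pred) {
  gt_ids <- setdiff(sort(unique(as.vector(gt))), 0L)
  pred_ids <- setdiff(sort(unique(as.vector(pred))), 0L)
  gt_sets <- lapply(gt_ids, function(i) which(gt == i))
  pred_sets <- lapply(pred_ids, function(j) which(pred == j))
  jacc <- numeric(length(gt_ids))
  match_of <- rep(NA_integer_, length(gt_ids))
  for (i in seq_along(gt_ids)) {
    for (j in seq_along(pred_ids)) {
      ov <- length(intersect(gt_sets[[i]], pred_sets[[j]]))
      if (ov > 0.5 * length(gt_sets[[i]])) {
        match_of[i] <- j
        jacc[i] <- ov / length(union(gt_sets[[i]], pred_sets[[j]]))
      }
    }
  }
  seg <- if (length(gt_ids)) mean(jacc) else NA_real_
  matched_pred <- unique(match_of[!is.na(match_of)])
  fn <- sum(is.na(match_of))
  fp <- length(pred_ids) - length(matched_pred)
  ns <- 0L
  for (i in seq_along(gt_ids)) {
    overlapping <- 0L
    for (j in matched_pred)
      if (length(intersect(gt_sets[[i]], pred_sets[[j]])) > 0)
        overlapping <- overlapping + 1L
    if (overlapping >= 2L) ns <- ns + 1L
  }
  aogm <- 10 * fn + 1 * fp + 5 * ns
  aogm0 <- 10 * length(gt_ids)
  list(SEG = seg, DET = 1 - min(aogm, aogm0) / aogm0,
       FN = fn, FP = fp, NS = ns)
}

# random label image with up to k cuboid objects (may touch/overlap in the
# pred case); returns an integer array
random_label_image <- function(n = 16L, k = 5L) {
  arr <- array(0L, dim = c(n, n, n))
  n_obj <- sample.int(k, 1)
  for (i in seq_len(n_obj)) {
    sz <- sample(2:5, 3, replace = TRUE)
    lo <- vapply(sz, function(s) sample.int(n - s, 1), integer(1))
    arr[lo[1]:(lo[1] + sz[1]), lo[2]:(lo[2] + sz[2]),
        lo[3]:(lo[3] + sz[3])] <- i
  }
  arr
}

# perturb a label image into a plausible "prediction": shift objects,
# drop some, add a spurious one
perturb_labels <- function(gt, drop_prob = 0.2, shift_max = 1L) {
  d <- dim(gt)
  ids <- setdiff(sort(unique(as.vector(gt))), 0L)
  out <- array(0L, dim = d)
  nxt <- 1L
  for (i in ids) {
    if (runif(1) < drop_prob) next
    sh <- sample(seq(-shift_max, shift_max), 3, replace = TRUE)
    idx <- arrayInd(which(gt == i), d)
    idx <- sweep(idx, 2, sh, `+`)
    keep <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
      idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) == 0) next
    out[idx[, 1] + d[1] * (idx[, 2] - 1 + d[2] * (idx[, 3] - 1))] <- nxt
    nxt <- nxt + 1L
  }
  if (runif(1) < 0.7) {
    sz <- sample(2:3, 3, replace = TRUE)
    lo <- vapply(sz, function(s) sample.int(d[1] - s, 1), integer(1))
    out[lo[1]:(lo[1] + sz[1]), lo[2]:(lo[2] + sz[2]),
        lo[3]:(lo[3] + sz[3])] <- nxt
  }
  out
}
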