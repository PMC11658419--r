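#' Filter nuclei by physical volume
#'
#' Segmented nuclei with a volume strictly smaller than `vmin` or strictly
#' larger than `vmax` (defaults 300 and 3000 \eqn{\mu m^3}) are treated as
#' debris or segmentation errors and removed from the mask; nuclei exactly
#' at a bound are retained. Volumes are voxel count times voxel volume.
#'
#' @param labels A [label_volume()] on an isotropic grid.
#' @param vmin,vmax Volume bounds in \eqn{\mu m^3}.
#' @return A list with `labels` (filtered [label_volume()]) and `excluded`
#'   (tibble: id, volume_um3, reason in `"small"`/`"large"`).
#' @export
filter_nuclei_by_volume <- function(labels, vmin = 300, vmax = 3000) {
  stopifnot(inherits(labels, "label_volume"))
  assert_that(vmin < vmax, "volume bounds must satisfy vmin < vmax")
  counts <- label_voxel_counts(labels)
  assert_that(length(counts) > 0, "label volume contains no nuclei")
  vv <- voxel_volume_um3(labels$spacing)
  vols <- counts * vv
  ids <- as.integer(names(counts))
  small <- vols < vmin
  large <- vols > vmax
  excluded <- tibble::tibble(
    id = ids[small | large],
    volume_um3 = unname(vols[small | large]),
    reason = c(rep("small", sum(small)), rep("large", sum(large)))[
      order(c(which(small), which(large)))]
  )
  lab <- labels$labels
  if (nrow(excluded) > 0) lab[lab %in% excluded$id] <- 0L
  assert_that(any(lab > 0L),
              "volume filter removed every nucleus (", nrow(excluded),
              " excluded)")
  list(labels = label_volume(lab, labels$spacing), excluded = excluded)
}

#' Intensity statistics over one nucleus
#'
#' Mean, median, maximum, 95th percentile (linear-interpolated) and
#' population SD of a channel over exactly the voxels of one instance id.
#'
#' @param channel 3D intensity array (z, y, x).
#' @param labels A [label_volume()] or integer array of the same shape.
#' @param id Instance id.
#' @return A one-row tibble: mean, median, max, p95, sd.
#' @export
nucleus_intensity_stats <- function(channel, labels, id) {
  lab <- if (inherits(labels, "label_volume")) labels$labels else labels
  assert_that(all(dim(channel) == dim(lab)),
              "channel and labels shapes differ")
  x <- channel[lab == id]
  assert_that(length(x) > 0, "id ", id, " not present in labels")
  region_stats(x)
}

region_stats <- function(x) {
  if (length(x) == 0)
    return(tibble::tibble(mean = NA_real_, median = NA_real_, max = NA_real_,
                          p95 = NA_real_, sd = NA_real_))
  tibble::tibble(mean = mean(x), median = stats::median(x), max = max(x),
                 p95 = unname(quantile(x, 0.95, type = 7)), sd = pop_sd(x))
}

#' Proximate outer region of a nucleus
#'
#' Four binary dilations (connectivity 1) of one nucleus mask, excluding
#' the nucleus itself and every voxel belonging to any nucleus. The region
#' may be empty under extreme crowding.
#'
#' @param labels A [label_volume()].
#' @param id Instance id.
#' @param n_dilations Number of 6-connected dilations (default 4).
#' @return 3D logical array.
#' @export
outer_region_mask <- function(labels, id, n_dilations = 4L) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  nuc <- lab == id
  assert_that(any(nuc), "id ", id, " not present in labels")
  dil <- binary_dilate(nuc, n_dilations)
  out <- dil & !(lab > 0L)
  dim(out) <- dim(lab)
  out
}

#' Morphology of one nucleus
#'
#' Volume (voxel count times voxel volume), centroid, ellipsoid-equivalent
#' principal axis lengths from the eigenvalues of the voxel-coordinate
#' covariance (full axis length \eqn{2\sqrt{5\lambda}}), and elongation
#' (major/minor axis ratio).
#'
#' @param labels A [label_volume()] on an isotropic grid.
#' @param id Instance id.
#' @return A one-row tibble: volume_um3, centroid_z_um, centroid_y_um,
#'   centroid_x_um, axis_major_um, axis_mid_um, axis_minor_um, elongation.
#' @export
nucleus_morphology <- function(labels, id) {
  stopifnot(inherits(labels, "label_volume"))
  w <- which(labels$labels == id)
  assert_that(length(w) > 0, "id ", id, " not present in labels")
  sp <- labels$spacing
  coords <- arrayInd(w, dim(labels$labels))
  coords_um <- sweep(coords, 2, c(sp$dz, sp$dy, sp$dx), `*`)
  ctr <- colMeans(coords_um)
  vol <- length(w) * voxel_volume_um3(sp)
  if (length(w) == 1L) {
    axes <- c(0, 0, 0)
    elong <- 1
  } else {
    cc <- sweep(coords_um, 2, ctr)
    cov <- crossprod(cc) / length(w)          # population covariance
    ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
    axes <- 2 * sqrt(5 * ev)
    elong <- if (ev[3] > 1e-12) sqrt(ev[1] / ev[3]) else NA_real_
  }
  tibble::tibble(volume_um3 = vol,
                 centroid_z_um = ctr[1], centroid_y_um = ctr[2],
                 centroid_x_um = ctr[3],
                 axis_major_um = axes[1], axis_mid_um = axes[2],
                 axis_minor_um = axes[3], elongation = elong)
}

#' Build the per-nucleus feature table
#'
#' One record per surviving nucleus: morphology plus, for every configured
#' channel, intensity statistics (mean, median, max, p95, population SD) of
#' the raw and the foreground-masked-smoothed image, each over the nucleus
#' and over its proximate outer region (4 dilations, all nuclei excluded).
#' Rows are ordered by id. Column names follow
#' `<channel>_<nuc|out>_<raw|smooth>_<stat>`.
#'
#' @param volume A [multichannel_volume()], isotropic, co-registered with
#'   `labels`.
#' @param labels A [label_volume()], typically already volume-filtered.
#' @param config An [analysis_config()].
#' @return A tibble with one row per nucleus and an `outer_empty` flag.
#' @export
build_cell_table <- function(volume, labels, config = analysis_config()) {
  stopifnot(inherits(volume, "multichannel_volume"),
            inherits(labels, "label_volume"))
  d <- dim(labels$labels)
  assert_that(all(dim(volume$channels[[1]]) == d),
              "image and label shapes differ")
  assert_that(is_isotropic(labels$spacing),
              "labels must be isotropic; call rescale_to_isotropic() first")
  ids <- label_ids(labels)
  assert_that(length(ids) > 0, "no nuclei present")
  lab <- labels$labels

  ch_names <- names(volume$channels)
  smoothed <- lapply(ch_names, function(nm) {
    th <- resolve_fg_threshold(config, nm, volume$channels[[nm]])
    masked_gaussian_smooth(volume$channels[[nm]], th, config$smooth_sigma)
  })
  names(smoothed) <- ch_names

  pad <- config$outer_dilations + 1L
  rows <- lapply(ids, function(id) {
    morph <- nucleus_morphology(labels, id)
    bb <- mask_bbox(lab == id, pad = pad)
    labc <- crop_bbox(lab, bb)
    nuc <- labc == id
    outm <- binary_dilate(nuc, config$outer_dilations) & !(labc > 0L)
    nuc_idx <- which(nuc)
    out_idx <- which(outm)
    stat_row <- list()
    for (nm in ch_names) {
      for (form in c("raw", "smooth")) {
        src <- if (form == "raw") volume$channels[[nm]] else smoothed[[nm]]
        chc <- crop_bbox(src, bb)
        for (reg in c("nuc", "out")) {
          idx <- if (reg == "nuc") nuc_idx else out_idx
          st <- region_stats(chc[idx])
          names(st) <- paste(nm, reg, form, names(st), sep = "_")
          stat_row <- c(stat_row, as.list(st))
        }
      }
    }
    dplyr::bind_cols(tibble::tibble(id = id), morph,
                     tibble::as_tibble(stat_row),
                     tibble::tibble(outer_empty = length(out_idx) == 0L))
  })
  dplyr::bind_rows(rows)
}
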