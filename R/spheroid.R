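#' Whole-spheroid mask from the nuclei segmentation
#'
#' Morphological closure of the union of nuclei: `n_iter` binary dilations
#' followed by `n_iter` erosions (6-connected element), which closes
#' inter-nuclear spaces without enlarging the segmented volume; remaining
#' interior voids are filled and only the largest connected structure is
#' kept. The image is padded by `n_iter + 1` voxels during the morphology so
#' dilation never clips at the boundary.
#'
#' @param labels A [label_volume()] with at least one nucleus, isotropic.
#' @param n_iter Closure iterations (default 40).
#' @return 3D logical spheroid mask, same shape as the labels.
#' @export
build_spheroid_mask <- function(labels, n_iter = 40L) {
  stopifnot(inherits(labels, "label_volume"))
  fg <- labels$labels > 0L
  assert_that(any(fg), "label volume contains no nuclei")
  d <- dim(fg)
  pad <- as.integer(n_iter) + 1L
  m <- pad_array(fg, pad)
  m <- binary_dilate(m, n_iter)
  m <- binary_erode(m, n_iter)
  m <- fill_holes(m)
  m <- largest_component(m)
  unpad_array(m, pad, d)
}

#' Void fraction of a spheroid
#'
#' Proportion of the spheroid mask not occupied by segmented nuclei — the
#' inter-nuclear space, an index of how loosely the cells pack.
#'
#' @param mask 3D logical spheroid mask.
#' @param labels A [label_volume()] (only nuclei inside the mask count).
#' @return Fraction in `[0, 1)`.
#' @export
void_fraction <- function(mask, labels) {
  stopifnot(inherits(labels, "label_volume"))
  n_mask <- sum(mask)
  assert_that(n_mask > 0, "spheroid mask is empty")
  n_nuc <- sum(labels$labels > 0L & mask)
  (n_mask - n_nuc) / n_mask
}

#' Nuclei density
#'
#' @param n_nuclei Nucleus count (volume-filtered count by convention).
#' @param volume_um3 Spheroid volume in \eqn{\mu m^3}.
#' @return Density in nuclei per \eqn{\mu m^3}.
#' @export
nuclei_density <- function(n_nuclei, volume_um3) {
  assert_that(volume_um3 > 0, "spheroid volume must be > 0")
  n_nuclei / volume_um3
}

#' Largest equivalent xy diameter
#'
#' For each z-plane, the diameter of the circle whose area equals the
#' segmented plane area; the maximum over planes is returned.
#'
#' @param mask 3D logical spheroid mask.
#' @param spacing A [voxel_spacing()].
#' @return Diameter in µm.
#' @export
largest_equivalent_xy_diameter <- function(mask, spacing = voxel_spacing(1, 1, 1)) {
  assert_that(any(mask), "spheroid mask is empty")
  areas <- apply(mask, 1, sum) * spacing$dy * spacing$dx
  2 * sqrt(max(areas) / pi)
}

#' Distances of a nucleus to spheroid center and hull
#'
#' The spheroid center is the mask's center of mass; the hull distance is
#' the Euclidean distance from the nucleus centroid to the nearest
#' background-adjacent surface voxel of the mask (the segmented surface,
#' not a convex hull). A centroid outside the mask gets hull distance 0 and
#' is flagged.
#'
#' @param mask 3D logical spheroid mask.
#' @param centroid_um Nucleus centroid, c(z, y, x) in µm.
#' @param spacing A [voxel_spacing()].
#' @return A one-row tibble: dist_center_um, dist_hull_um, outside_mask.
#' @export
nucleus_distances <- function(mask, centroid_um, spacing = voxel_spacing(1, 1, 1)) {
  assert_that(any(mask), "spheroid mask is empty")
  surf <- spheroid_surface_um(mask, spacing)
  ctr <- spheroid_center_um(mask, spacing)
  d_center <- sqrt(sum((centroid_um - ctr)^2))
  idx <- pmin(pmax(round(centroid_um / c(spacing$dz, spacing$dy, spacing$dx)), 1),
              dim(mask))
  inside <- mask[idx[1], idx[2], idx[3]]
  d_hull <- if (!inside) 0 else
    sqrt(min(colSums((t(surf) - centroid_um)^2)))
  tibble::tibble(dist_center_um = d_center, dist_hull_um = d_hull,
                 outside_mask = !inside)
}

spheroid_center_um <- function(mask, spacing) {
  w <- which(mask)
  coords <- arrayInd(w, dim(mask))
  colMeans(coords) * c(spacing$dz, spacing$dy, spacing$dx)
}

# surface voxels (mask voxels with a background 6-neighbour), µm coordinates
spheroid_surface_um <- function(mask, spacing) {
  interior <- binary_erode(mask, 1L)
  surf <- mask & !interior
  coords <- arrayInd(which(surf), dim(mask))
  sweep(coords, 2, c(spacing$dz, spacing$dy, spacing$dx), `*`)
}

#' Partition a spheroid into equi-volumetric shells
#'
#' Sequential 6-connected erosion of the spheroid mask until the remaining
#' volume first drops to (at or below) two thirds and one third of the
#' original: outer shell = mask minus the 2/3 state, middle = 2/3 minus 1/3
#' state, inner = the 1/3 state. Erosion follows the actual distance to the
#' spheroid hull, so shells track the real (possibly non-spherical) surface
#' geometry; the first state at-or-below each target is used, so achieved
#' fractions can overshoot by one erosion ring and are always reported.
#'
#' @param mask 3D logical spheroid mask (connected, non-empty).
#' @param n_shells Number of shells (default 3).
#' @param spacing A [voxel_spacing()].
#' @return An object of class `shell_partition`: list of logical `masks`
#'   (outermost first), tibble `fractions` (shell, target_fraction,
#'   achieved_fraction, volume_um3, erosion_depth).
#' @export
partition_shells <- function(mask, n_shells = 3L, spacing = voxel_spacing(1, 1, 1)) {
  total <- sum(mask)
  assert_that(total > 0, "spheroid mask is empty")
  n_shells <- as.integer(n_shells)
  assert_that(n_shells >= 1L, "n_shells must be >= 1")
  states <- vector("list", n_shells - 1L)
  depths <- integer(n_shells - 1L)
  cur <- mask
  depth <- 0L
  for (k in seq_len(n_shells - 1L)) {
    target <- total * (n_shells - k) / n_shells
    cur <- erode_to_count(cur, target)
    depth <- depth + attr(cur, "iterations")
    states[[k]] <- cur
    depths[k] <- depth
  }
  bounds <- c(list(mask), states, list(array(FALSE, dim(mask))))
  shells <- lapply(seq_len(n_shells), function(k) {
    s <- bounds[[k]] & !bounds[[k + 1L]]
    dim(s) <- dim(mask)
    s
  })
  counts <- vapply(shells, sum, numeric(1))
  if (any(counts == 0))
    abort_sq("mask too small for ", n_shells, " non-empty shells ",
             "(achieved fractions: ",
             paste(sprintf("%.3f", counts / total), collapse = ", "), ")")
  shell_names <- if (n_shells == 3L) c("outer", "middle", "inner") else
    paste0("shell", seq_len(n_shells))
  fr <- tibble::tibble(
    shell = shell_names,
    target_fraction = rep(1 / n_shells, n_shells),
    achieved_fraction = counts / total,
    volume_um3 = counts * voxel_volume_um3(spacing),
    erosion_depth = c(0L, depths)
  )
  structure(list(masks = stats::setNames(shells, shell_names),
                 fractions = fr, spacing = spacing),
            class = "shell_partition")
}

#' @export
print.shell_partition <- function(x, ...) {
  cat("<shell_partition>\n")
  print(as.data.frame(x$fractions))
  invisible(x)
}

# shell index (1 = outermost) containing a µm position; 0 if outside all
shell_index_at <- function(partition, pos_um) {
  sp <- partition$spacing
  d <- dim(partition$masks[[1]])
  idx <- pmin(pmax(round(pos_um / c(sp$dz, sp$dy, sp$dx)), 1), d)
  for (k in seq_along(partition$masks))
    if (partition$masks[[k]][idx[1], idx[2], idx[3]]) return(k)
  0L
}

#' Per-shell statistics
#'
#' Assigns each nucleus to the shell containing its centroid (centroids
#' that fall outside every shell are assigned to the outer shell) and
#' reports per-shell nucleus count, density, mean nuclear volume and, for
#' any logical marker columns passed via `markers`, the percentage of
#' marker-positive cells per shell (percentages sum to 100 across shells).
#'
#' @param partition A [partition_shells()] result.
#' @param records Cell table with centroid and volume columns.
#' @param markers Optional character vector of logical columns in `records`
#'   (e.g. `"ki67_positive"`) whose spatial distribution is reported.
#' @return A tibble, one row per shell.
#' @export
shell_statistics <- function(partition, records, markers = character()) {
  stopifnot(inherits(partition, "shell_partition"))
  need <- c("centroid_z_um", "centroid_y_um", "centroid_x_um", "volume_um3")
  assert_that(all(need %in% names(records)),
              "records lack centroid/volume columns")
  n_shells <- length(partition$masks)
  idx <- vapply(seq_len(nrow(records)), function(i) {
    k <- shell_index_at(partition, c(records$centroid_z_um[i],
                                     records$centroid_y_um[i],
                                     records$centroid_x_um[i]))
    if (k == 0L) 1L else k   # numerically outside -> outer shell
  }, integer(1))
  out <- partition$fractions %>%
    dplyr::mutate(shell_index = dplyr::row_number())
  per <- tibble::tibble(shell_index = idx,
                        volume_nuc = records$volume_um3) %>%
    dplyr::group_by(.data$shell_index) %>%
    dplyr::summarise(n_nuclei = dplyr::n(),
                     mean_nucleus_volume_um3 = mean(.data$volume_nuc),
                     .groups = "drop")
  out <- dplyr::left_join(out, per, by = "shell_index") %>%
    dplyr::mutate(
      n_nuclei = ifelse(is.na(.data$n_nuclei), 0L, .data$n_nuclei),
      density_per_um3 = .data$n_nuclei / .data$volume_um3)
  for (mk in markers) {
    assert_that(mk %in% names(records), "marker column not found: ", mk)
    pos_by_shell <- vapply(seq_len(n_shells), function(k)
      sum(records[[mk]][idx == k], na.rm = TRUE), numeric(1))
    tot <- sum(pos_by_shell)
    out[[paste0("pct_", mk)]] <-
      if (tot > 0) 100 * pos_by_shell / tot else rep(NA_real_, n_shells)
  }
  dplyr::select(out, "shell", "shell_index", dplyr::everything())
}

#' Whole-spheroid morphometry
#'
#' Builds the spheroid mask and computes volume, void fraction, nuclei
#' density, largest equivalent xy diameter and center.
#'
#' @param labels A [label_volume()] (volume-filtered), isotropic.
#' @param config An [analysis_config()].
#' @return An object of class `spheroid_metrics`: list with `mask` and a
#'   one-row tibble `metrics`.
#' @export
spheroid_morphometry <- function(labels, config = analysis_config()) {
  stopifnot(inherits(labels, "label_volume"))
  mask <- build_spheroid_mask(labels, config$closure_iterations)
  sp <- labels$spacing
  vol <- sum(mask) * voxel_volume_um3(sp)
  n_nuc <- n_instances(labels)
  ctr <- spheroid_center_um(mask, sp)
  metrics <- tibble::tibble(
    volume_um3 = vol,
    n_nuclei = n_nuc,
    void_fraction = void_fraction(mask, labels),
    density_per_um3 = nuclei_density(n_nuc, vol),
    equivalent_xy_diameter_um = largest_equivalent_xy_diameter(mask, sp),
    center_z_um = ctr[1], center_y_um = ctr[2], center_x_um = ctr[3])
  structure(list(mask = mask, metrics = metrics, spacing = sp),
            class = "spheroid_metrics")
}

#' @export
print.spheroid_metrics <- function(x, ...) {
  cat("<spheroid_metrics>\n")
  print(as.data.frame(x$metrics))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.spheroid_metrics <- function(x, ...) x$metrics
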