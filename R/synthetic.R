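#' Parameters of a synthetic spheroid scene
#'
#' The generator emulates the structure of nuclei-segmented co-culture
#' spheroids: two nuclear-volume populations — a fibroblast-like mode around
#' 500 \eqn{\mu m^3} with elongated nuclei, and a tumor-like mode around
#' 1200 \eqn{\mu m^3} with rounder nuclei — packed without overlap inside a
#' spherical aggregate, a collagen-1 halo surrounding fibroblast nuclei
#' only, nuclear Ki-67 / Live-or-Dye / cleaved caspase-3 positivity at
#' configurable fractions, additive Gaussian noise and optional blur and
#' depth attenuation. Nuclear volumes follow lognormal laws parameterized by
#' mode and geometric SD (strictly positive, right-skewed, single mode).
#'
#' @param radius_um Spheroid radius in µm.
#' @param n_tumor,n_fibroblast Nuclei counts per cell type (default 1:3
#'   tumor:fibroblast, the co-culture seeding ratio).
#' @param tumor_volume_mode,fibroblast_volume_mode Modes of the nuclear
#'   volume distributions, \eqn{\mu m^3}.
#' @param volume_gsd Geometric SD of the lognormal volume laws.
#' @param tumor_elongation,fibroblast_elongation Major/minor axis ratio of
#'   the ellipsoidal nuclei.
#' @param ki67_fraction,lod_fraction,cas3_fraction Named vectors
#'   `c(tumor = , fibroblast = )` of marker positivity probabilities.
#' @param nuclei_level Nuclear stain intensity above background (a.u.).
#' @param marker_amplitude Intensity added inside marker-positive nuclei for
#'   the Ki-67, Live-or-Dye and Cas3 channels (a.u.).
#' @param celltracker_amplitude CellTracker intensity inside fibroblast
#'   nuclei (a.u.); the fibroblasts are the CellTracker-labeled population.
#' @param collagen_amplitude Peak amplitude of the collagen-1 halo (a.u.).
#' @param collagen_width_um Width of the Gaussian-profile halo shell, µm.
#' @param background Baseline intensity of every channel (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.); intensities are
#'   clamped at 0.
#' @param blur_sigma Optional Gaussian blur (voxels) applied last; 0 = off.
#' @param depth_attenuation Optional exponential intensity decay per µm of
#'   depth; 0 = off (stacks are assumed acquired with z-compensation).
#' @param spacing_um Isotropic voxel edge length of the rendered grid, µm.
#' @param max_attempts Placement attempts per nucleus before the packing is
#'   declared infeasible.
#' @param seed Integer seed; all randomness of generation + rendering flows
#'   from it.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(radius_um = 55,
                         n_tumor = 50L,
                         n_fibroblast = 150L,
                         tumor_volume_mode = 1200,
                         fibroblast_volume_mode = 500,
                         volume_gsd = 1.3,
                         tumor_elongation = 1.2,
                         fibroblast_elongation = 2.5,
                         ki67_fraction = c(tumor = 0.6, fibroblast = 0.05),
                         lod_fraction = c(tumor = 0.10, fibroblast = 0.05),
                         cas3_fraction = c(tumor = 0.05, fibroblast = 0.02),
                         nuclei_level = 100,
                         marker_amplitude = 25,
                         celltracker_amplitude = 50,
                         collagen_amplitude = 30,
                         collagen_width_um = 3,
                         background = 10,
                         noise_sd = 2,
                         blur_sigma = 0,
                         depth_attenuation = 0,
                         spacing_um = 1,
                         max_attempts = 400L,
                         seed = 1L) {
  assert_that(radius_um > 0, "radius_um must be > 0")
  assert_that(n_tumor >= 0 && n_fibroblast >= 0, "counts must be >= 0")
  assert_that(n_tumor + n_fibroblast >= 1, "at least one nucleus is required")
  assert_that(tumor_volume_mode > 0 && fibroblast_volume_mode > 0 &&
                volume_gsd > 1, "volume laws must have positive support")
  assert_that(tumor_elongation >= 1 && fibroblast_elongation >= 1,
              "elongation factors must be >= 1")
  for (fr in list(ki67_fraction, lod_fraction, cas3_fraction))
    assert_that(all(fr >= 0 & fr <= 1) &&
                  all(c("tumor", "fibroblast") %in% names(fr)),
                "marker fractions must be named c(tumor=, fibroblast=) in [0,1]")
  assert_that(noise_sd >= 0 && blur_sigma >= 0 && depth_attenuation >= 0,
              "noise/blur/attenuation must be >= 0")
  p <- as.list(environment())
  structure(p, class = "scene_params")
}

# lognormal parameterized by mode m and geometric SD g:
# sdlog = log(g), meanlog = log(m) + sdlog^2  (mode = exp(mu - sigma^2))
sample_volumes <- function(n, mode, gsd) {
  sdlog <- log(gsd)
  rlnorm(n, meanlog = log(mode) + sdlog^2, sdlog = sdlog)
}

# random proper rotation matrix
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# semi-axes (a, b, b) in µm of an ellipsoid with volume v and axis ratio e
ellipsoid_axes <- function(v, e) {
  b <- (3 * v / (4 * pi * e))^(1 / 3)
  c(e * b, b, b)
}

#' Generate a synthetic spheroid scene with ground truth
#'
#' Places ellipsoidal nuclei by rejection sampling without voxel overlap
#' inside a sphere (fibroblasts elongated, randomly oriented), draws marker
#' states per the configured fractions, and renders the fluorescence
#' channels. Fully deterministic for a fixed seed.
#'
#' @param params A [scene_params()].
#' @param render Also render the fluorescence channels (default `TRUE`).
#' @return An object of class `synthetic_scene` with elements `truth`
#'   (tibble: id, type, marker states, center, axes, analytic and
#'   voxel-count volumes), `labels` (a [label_volume()]), `volume` (a
#'   [multichannel_volume()], if rendered) and `params`.
#' @export
generate_scene <- function(params = scene_params(), render = TRUE) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  sp <- params$spacing_um
  R <- params$radius_um
  n_grid <- as.integer(2 * ceiling(R / sp) + 3L)
  d <- c(n_grid, n_grid, n_grid)
  center0 <- (d + 1) / 2                     # grid center, index units

  type <- c(rep("tumor", params$n_tumor),
            rep("fibroblast", params$n_fibroblast))
  n <- length(type)
  vol <- ifelse(type == "tumor",
                sample_volumes(n, params$tumor_volume_mode, params$volume_gsd),
                sample_volumes(n, params$fibroblast_volume_mode,
                               params$volume_gsd))
  elong <- ifelse(type == "tumor", params$tumor_elongation,
                  params$fibroblast_elongation)

  # place larger nuclei first, then restore the original id order
  ord <- order(vol, decreasing = TRUE)
  labels <- array(0L, dim = d)
  centers <- matrix(NA_real_, n, 3)
  axes <- matrix(NA_real_, n, 3)
  vox_count <- integer(n)
  placed <- 0L
  for (k in ord) {
    ax <- ellipsoid_axes(vol[k], elong[k])
    amax <- ax[1]
    ok <- FALSE
    for (try in seq_len(params$max_attempts)) {
      # uniform point in the ball of radius R - amax (centers stay inside)
      repeat {
        u <- runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      ctr_um <- u * max(R - amax, 0)
      rot <- random_rotation()
      ctr_idx <- center0 + ctr_um / sp
      r_idx <- ceiling(amax / sp) + 1L
      lo <- pmax(floor(ctr_idx - r_idx), 1)
      hi <- pmin(ceiling(ctr_idx + r_idx), d)
      if (any(lo > hi)) next
      gz <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gx <- lo[3]:hi[3]
      pts <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
      rel <- sweep(pts, 2, ctr_idx) * sp          # µm offsets
      u3 <- rel %*% rot                            # into ellipsoid frame
      inside <- (u3[, 1] / ax[1])^2 + (u3[, 2] / ax[2])^2 +
        (u3[, 3] / ax[3])^2 <= 1
      if (!any(inside)) next
      vox <- pts[inside, , drop = FALSE]
      lin <- vox[, 1] + d[1] * (vox[, 2] - 1 + d[2] * (vox[, 3] - 1))
      if (any(labels[lin] != 0L)) next
      labels[lin] <- k
      centers[k, ] <- ctr_um
      axes[k, ] <- ax
      vox_count[k] <- length(lin)
      ok <- TRUE
      break
    }
    if (!ok)
      abort_sq("packing infeasible: placed ", placed, " of ", n,
               " nuclei in a radius-", R, " um spheroid")
    placed <- placed + 1L
  }

  draw_state <- function(frac) rbinom(n, 1, frac[type]) == 1
  truth <- tibble::tibble(
    id = seq_len(n),
    type = type,
    center_z_um = centers[, 1], center_y_um = centers[, 2],
    center_x_um = centers[, 3],
    axis_major_um = axes[, 1], axis_minor_um = axes[, 3],
    elongation = elong,
    volume_analytic_um3 = vol,
    volume_um3 = vox_count * sp^3,    # voxel-count volume: feature oracle
    ki67 = draw_state(params$ki67_fraction),
    lod = draw_state(params$lod_fraction),
    cas3 = draw_state(params$cas3_fraction)
  )

  scene <- structure(
    list(truth = truth,
         labels = label_volume(labels, voxel_spacing(sp, sp, sp)),
         volume = NULL, params = params),
    class = "synthetic_scene")
  if (render) scene$volume <- render_channels(scene, params)
  scene
}

#' Render the fluorescence channels of a synthetic scene
#'
#' The nuclei channel carries the nuclear stain inside every label; Ki-67,
#' Live-or-Dye and Cas3 channels are elevated only inside positive nuclei;
#' collagen-1 is an additive Gaussian-profile shell outside fibroblast
#' nuclei only (collagen is secreted, so it must be detectable by the
#' outer-region features and not by the nuclear mask); CellTracker marks the
#' fibroblast nuclei. Gaussian noise of the configured SD is added and an
#' optional blur is applied last.
#'
#' @param scene A `synthetic_scene`.
#' @param params A [scene_params()]; defaults to the scene's own.
#' @return A [multichannel_volume()] with channels `nuclei`, `ki67`, `lod`,
#'   `cas3`, `collagen1`, `celltracker`.
#' @export
render_channels <- function(scene, params = scene$params) {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(params$seed + 1000L)
  lab <- scene$labels$labels
  d <- dim(lab)
  truth <- scene$truth
  bg <- params$background
  any_nuc <- lab > 0L

  # per-nucleus nuclear stain brightness (mild biological variation)
  lvl <- params$nuclei_level * runif(nrow(truth), 0.9, 1.1)
  nuclei <- array(bg, dim = d)
  nuclei[any_nuc] <- bg + lvl[lab[any_nuc]]

  marker_channel <- function(state) {
    ch <- array(bg, dim = d)
    pos <- which(state)
    if (length(pos)) {
      sel <- any_nuc & array(lab %in% pos, dim = d)
      ch[sel] <- bg + params$marker_amplitude
    }
    ch
  }
  ki67 <- marker_channel(truth$ki67)
  lod <- marker_channel(truth$lod)
  cas3 <- marker_channel(truth$cas3)

  celltracker <- array(bg, dim = d)
  fib <- which(truth$type == "fibroblast")
  if (length(fib)) {
    sel <- any_nuc & array(lab %in% fib, dim = d)
    celltracker[sel] <- bg + params$celltracker_amplitude
  }

  # collagen-1 halo: Gaussian-profile rings grown from fibroblast nuclei,
  # never inside any nucleus
  collagen <- array(bg, dim = d)
  if (length(fib)) {
    cur <- array(lab %in% fib, dim = d)
    w <- max(1L, round(params$collagen_width_um / params$spacing_um))
    for (k in seq_len(w)) {
      nxt <- binary_dilate(cur, 1L)
      ring <- nxt & !cur & !any_nuc
      collagen[ring] <- collagen[ring] +
        params$collagen_amplitude * exp(-0.5 * ((k - 1) / (w / 2))^2)
      cur <- nxt
    }
  }

  chans <- list(nuclei = nuclei, ki67 = ki67, lod = lod, cas3 = cas3,
                collagen1 = collagen, celltracker = celltracker)
  if (params$depth_attenuation > 0) {
    depth <- (seq_len(d[1]) - 1) * params$spacing_um
    att <- exp(-params$depth_attenuation * depth)
    chans <- lapply(chans, function(ch) ch * att)  # z is the fastest dim
  }
  if (params$noise_sd > 0)
    chans <- lapply(chans, function(ch)
      pmax(ch + array(rnorm(length(ch), 0, params$noise_sd), dim = d), 0))
  if (params$blur_sigma > 0)
    chans <- lapply(chans, gaussian_smooth_3d, sigma = params$blur_sigma)
  multichannel_volume(chans, scene$labels$spacing,
                      metadata = list(source = "synthetic",
                                      seed = as.character(params$seed)))
}

#' Ground-truth table of a synthetic scene
#'
#' Per-nucleus truth with the volume computed from the rendered label mask
#' (voxel count times voxel volume), so the table serves as the oracle for
#' feature extraction.
#'
#' @param scene A `synthetic_scene`.
#' @return A tibble, one row per nucleus, ids strictly increasing.
#' @export
scene_truth_table <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  scene$truth
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d nuclei (%d tumor, %d fibroblast), seed %d\n",
              nrow(x$truth), sum(x$truth$type == "tumor"),
              sum(x$truth$type == "fibroblast"), x$params$seed))
  invisible(x)
}
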