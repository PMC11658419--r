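# Shared fixtures, built in code at test time.

iso1 <- function() voxel_spacing(1, 1, 1)

# digital ball mask of given radius (voxels), centered in a cube grid
make_ball <- function(radius, margin = 2L) {
  n <- as.integer(2 * radius + 2 * margin + 1)
  ctr <- (n + 1) / 2
  co <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  array((co$z - ctr)^2 + (co$y - ctr)^2 + (co$x - ctr)^2 <= radius^2,
        dim = c(n, n, n))
}

# label volume of separated cuboid nuclei with exact voxel counts; each
# element of `dims` is c(nz, ny, nx) of one cuboid (1 um spacing)
make_cuboid_labels <- function(dims, gap = 3L) {
  nz <- max(vapply(dims, `[`, integer(1), 1)) + 2L
  ny <- max(vapply(dims, `[`, integer(1), 2)) + 2L
  widths <- vapply(dims, `[`, integer(1), 3)
  nx <- sum(widths) + gap * (length(dims) + 1L)
  lab <- array(0L, dim = c(nz, ny, nx))
  x0 <- gap
  for (i in seq_along(dims)) {
    d <- dims[[i]]
    lab[2:(1 + d[1]), 2:(1 + d[2]), (x0 + 1):(x0 + d[3])] <- i
    x0 <- x0 + d[3] + gap
  }
  label_volume(lab, iso1())
}

# small rendered co-culture scene shared across tests (cached per session)
.scene_cache <- new.env(parent = emptyenv())
shared_scene <- function() {
  if (is.null(.scene_cache$scene)) {
    .scene_cache$scene <- generate_scene(scene_params(
      radius_um = 48, n_tumor = 20L, n_fibroblast = 60L,
      lod_fraction = c(tumor = 0.3, fibroblast = 0.15),
      noise_sd = 2, marker_amplitude = 10, seed = 0L))
  }
  .scene_cache$scene
}
shared_scene_cells <- function() {
  if (is.null(.scene_cache$cells)) {
    sc <- shared_scene()
    filt <- filter_nuclei_by_volume(sc$labels)
    .scene_cache$filtered <- filt
    .scene_cache$cells <- build_cell_table(sc$volume, filt$labels,
                                           analysis_config(seed = 0L))
  }
  .scene_cache$cells
}
shared_scene_filtered <- function() {
  invisible(shared_scene_cells())
  .scene_cache$filtered
}
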