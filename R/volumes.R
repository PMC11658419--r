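#' Voxel spacing in physical units
#'
#' Physical edge lengths of a voxel along the axial (z) and lateral (y, x)
#' directions. Confocal z-stacks are typically anisotropic (z-step larger
#' than the lateral pixel size), which is why spacing is carried explicitly
#' on every volumetric container and all physical quantities (volumes in
#' \eqn{\mu m^3}, distances in \eqn{\mu m}) are computed from it.
#'
#' @param dz,dy,dx Voxel edge lengths in micrometres, all strictly positive.
#' @return An object of class `voxel_spacing`.
#' @examples
#' voxel_spacing(1, 0.38, 0.38)
#' @export
voxel_spacing <- function(dz, dy, dx) {
  vals <- c(dz = dz, dy = dy, dx = dx)
  assert_that(all(is.finite(vals)) && all(vals > 0),
              "voxel spacing must be finite and strictly positive")
  structure(list(dz = dz, dy = dy, dx = dx), class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("<voxel_spacing> dz=%g dy=%g dx=%g um%s\n", x$dz, x$dy, x$dx,
              if (is_isotropic(x)) " (isotropic)" else ""))
  invisible(x)
}

#' Is a voxel grid isotropic?
#'
#' @param spacing A [voxel_spacing()].
#' @param tol Relative tolerance on the comparison.
#' @return `TRUE` if dz, dy and dx agree within `tol` relative tolerance.
#' @export
is_isotropic <- function(spacing, tol = 1e-9) {
  v <- c(spacing$dz, spacing$dy, spacing$dx)
  diff(range(v)) <= tol * max(v)
}

#' Physical volume of one voxel
#'
#' @param spacing A [voxel_spacing()].
#' @return Voxel volume in \eqn{\mu m^3}.
#' @export
voxel_volume_um3 <- function(spacing) spacing$dz * spacing$dy * spacing$dx

#' Multi-channel fluorescence volume
#'
#' A set of named fluorescence channels sharing one (z, y, x) voxel grid with
#' known physical spacing. Intensities are arbitrary units, finite and
#' non-negative.
#'
#' @param channels Named list of 3D numeric arrays (z, y, x), identical dims.
#' @param spacing A [voxel_spacing()].
#' @param metadata Optional named list of free-form provenance strings.
#' @return An object of class `multichannel_volume`.
#' @export
multichannel_volume <- function(channels, spacing, metadata = list()) {
  assert_that(is.list(channels) && length(channels) > 0 &&
                !is.null(names(channels)) && all(nzchar(names(channels))),
              "channels must be a non-empty named list")
  dims <- lapply(channels, dim3, what = "each channel")
  ref <- dims[[1]]
  assert_that(all(vapply(dims, function(d) all(d == ref), logical(1))),
              "all channels must share one (z,y,x) shape")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    assert_that(all(is.finite(ch)) && all(ch >= 0),
                "channel '", nm, "' has non-finite or negative intensities")
  }
  structure(list(channels = channels, spacing = spacing, metadata = metadata),
            class = "multichannel_volume")
}

#' @export
print.multichannel_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_volume> %d channel(s) [%s], shape (%d,%d,%d)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  print(x$spacing)
  invisible(x)
}

#' Nuclei instance label volume
#'
#' An integer (z, y, x) array in which each segmented nucleus carries a
#' unique positive id and 0 is background. Ids need not be consecutive;
#' masks from any external instance segmentation network can be used.
#'
#' @param labels 3D array of non-negative integers (z, y, x).
#' @param spacing A [voxel_spacing()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing) {
  dim3(labels, "labels")
  assert_that(all(is.finite(labels)), "labels must be finite")
  assert_that(all(labels == round(labels)), "labels must be integer-valued")
  assert_that(all(labels >= 0), "labels must be non-negative (0 = background)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d instance(s), shape (%d,%d,%d)\n",
              n_instances(x), d[1], d[2], d[3]))
  print(x$spacing)
  invisible(x)
}

#' Instance ids and counts of a label volume
#'
#' @param x A [label_volume()].
#' @return `label_ids()`: sorted vector of positive ids present;
#'   `n_instances()`: their number.
#' @export
label_ids <- function(x) {
  stopifnot(inherits(x, "label_volume"))
  ids <- sort(unique(as.vector(x$labels)))
  ids[ids > 0L]
}

#' @rdname label_ids
#' @export
n_instances <- function(x) length(label_ids(x))

# voxel counts per positive id, as named integer vector
label_voxel_counts <- function(x) {
  tab <- tabulate(x$labels[x$labels > 0L])
  ids <- which(tab > 0L)
  stats::setNames(tab[ids], ids)
}

## ---- TIFF I/O -------------------------------------------------------------
## Multi-page TIFF layout: pages are grouped channel-major, i.e. all z-planes
## of channel 1, then all z-planes of channel 2, ... Each page is a (y, x)
## matrix. Intensities are written as 16-bit unsigned integers (values are
## rounded and must lie in [0, 65535]); labels likewise (max 65535 ids).

#' Read a multi-channel volumetric TIFF
#'
#' @param path Path to a multi-page TIFF whose pages are grouped
#'   channel-major (all z-planes of channel 1, then channel 2, ...).
#' @param channel_map Named integer vector mapping channel names to 1-based
#'   channel indices, e.g. `c(nuclei = 1, ki67 = 2)`.
#' @param spacing A [voxel_spacing()]; microscope TIFF metadata is unreliable
#'   so spacing always comes from the caller/config.
#' @param n_channels Number of channels stored in the file (defaults to the
#'   largest requested index); requesting an index beyond it is an error.
#' @return A [multichannel_volume()].
#' @export
load_volume <- function(path, channel_map, spacing,
                        n_channels = max(channel_map)) {
  assert_that(file.exists(path), "file not found: ", path)
  assert_that(length(channel_map) > 0 && !is.null(names(channel_map)),
              "channel_map must be a named vector of channel indices")
  assert_that(max(channel_map) <= n_channels,
              "channel index ", max(channel_map), " out of range: file has ",
              n_channels, " channel(s)")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  n_ch <- n_channels
  assert_that(length(pages) %% n_ch == 0L,
              "page count ", length(pages), " is not divisible by the ",
              "channel count ", n_ch)
  nz <- length(pages) %/% n_ch
  chans <- lapply(channel_map, function(ci) {
    assert_that(ci >= 1L && ci <= n_ch, "channel index out of range: ", ci)
    block <- pages[((ci - 1L) * nz + 1L):(ci * nz)]
    pages_to_array(block)
  })
  multichannel_volume(chans, spacing, metadata = list(source = path))
}

#' Read a nuclei instance mask from TIFF
#'
#' @param path Path to a single-channel multi-page integer TIFF.
#' @param spacing A [voxel_spacing()].
#' @return A [label_volume()]; the number of distinct instances is reported
#'   via a message.
#' @export
load_label_volume <- function(path, spacing) {
  assert_that(file.exists(path), "file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  arr <- pages_to_array(pages)
  assert_that(all(arr == round(arr)),
              "label TIFF contains non-integer values")
  assert_that(all(arr >= 0), "label TIFF contains negative values")
  lv <- label_volume(arr, spacing)
  message("loaded label volume with ", n_instances(lv), " instance(s)")
  lv
}

pages_to_array <- function(pages) {
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p  # drop trailing sample dim
  })
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(length(pages), ny, nx))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

array_to_pages <- function(arr) {
  lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ])
}

#' Write volumetric data to multi-page TIFF
#'
#' `write_volume_tiff()` writes a [multichannel_volume()] (channel-major
#' pages, 16-bit); `write_label_tiff()` writes a [label_volume()].
#'
#' @param vol A [multichannel_volume()].
#' @param x A [label_volume()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "multichannel_volume"))
  pages <- list()
  for (nm in names(vol$channels)) {
    ch <- round(vol$channels[[nm]])
    assert_that(max(ch) <= 65535, "channel '", nm, "' exceeds 16-bit range")
    pages <- c(pages, array_to_pages(ch / 65535))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
write_label_tiff <- function(x, path) {
  stopifnot(inherits(x, "label_volume"))
  assert_that(max(x$labels) <= 65535, "label ids exceed 16-bit TIFF range")
  tiff::writeTIFF(array_to_pages(x$labels / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

## ---- isotropic rescaling --------------------------------------------------

# resample a 3D array along one axis from spacing `old` to `new`;
# method "linear" for intensities, "nearest" for labels
resample_axis <- function(arr, axis, old, new, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  n <- d[axis]
  m <- floor((n - 1) * old / new + 1e-9) + 1L
  p <- (seq_len(m) - 1L) * new / old          # positions in source index units
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  if (method == "linear") {
    lo <- pmin(floor(p), n - 1)
    w <- p - lo
    lo1 <- as.integer(lo) + 1L
    hi1 <- pmin(lo1 + 1L, n)
    out <- a[lo1, , , drop = FALSE] * (1 - w) + a[hi1, , , drop = FALSE] * w
  } else {
    i <- pmin(pmax(as.integer(round(p)) + 1L, 1L), n)
    out <- a[i, , , drop = FALSE]
  }
  aperm(out, order(perm))
}

#' Rescale a volume to isotropic resolution
#'
#' Confocal stacks are acquired with a z-step (here typically 1 µm) coarser
#' than the lateral pixel size; all downstream geometry (volumes, distances,
#' morphology, shell erosion) assumes an isotropic grid. The target spacing
#' is the finer of (dy, dx), so the z-axis is upsampled and lateral detail is
#' never degraded. Intensity channels are resampled with linear
#' interpolation; label masks with nearest-neighbour so no new ids can
#' appear. Already-isotropic inputs are returned unchanged.
#'
#' @param x A [multichannel_volume()] or [label_volume()].
#' @return The same kind of object on an isotropic grid.
#' @export
rescale_to_isotropic <- function(x) UseMethod("rescale_to_isotropic")

#' @export
rescale_to_isotropic.multichannel_volume <- function(x) {
  if (is_isotropic(x$spacing)) return(x)
  target <- min(x$spacing$dy, x$spacing$dx)
  chans <- lapply(x$channels, function(ch) {
    for (axis in 1:3) {
      old <- c(x$spacing$dz, x$spacing$dy, x$spacing$dx)[axis]
      if (abs(old - target) > 1e-9 * target)
        ch <- resample_axis(ch, axis, old, target, "linear")
    }
    ch
  })
  multichannel_volume(chans, voxel_spacing(target, target, target),
                      metadata = x$metadata)
}

#' @export
rescale_to_isotropic.label_volume <- function(x) {
  if (is_isotropic(x$spacing)) return(x)
  target <- min(x$spacing$dy, x$spacing$dx)
  lab <- x$labels
  for (axis in 1:3) {
    old <- c(x$spacing$dz, x$spacing$dy, x$spacing$dx)[axis]
    if (abs(old - target) > 1e-9 * target)
      lab <- resample_axis(lab, axis, old, target, "nearest")
  }
  label_volume(lab, voxel_spacing(target, target, target))
}
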