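## Thin R wrappers around the compiled 3D binary morphology. All operations
## use the 6-connected (connectivity-1) structuring element throughout the
## package: one dilation grows a region by one voxel along each axis.

#' 3D binary morphology with a 6-connected structuring element
#'
#' Binary dilation, erosion, connected-component labeling and hole filling
#' on (z, y, x) logical arrays, all using connectivity 1 (6-neighbourhood).
#' These primitives underlie the outer-region construction (4 dilations),
#' the spheroid mask closure (40 dilations + 40 erosions) and the
#' equi-volumetric shell erosion.
#'
#' @param mask 3D logical array (z, y, x).
#' @param iter Number of iterations.
#' @return `binary_dilate()`/`binary_erode()`/`fill_holes()`: a logical array
#'   of the same shape; `label_connected()`: an integer array with components
#'   labeled 1..k.
#' @export
binary_dilate <- function(mask, iter = 1L) {
  d <- dim3(mask, "mask")
  if (iter <= 0L) return(mask)
  cpp_binary_dilate(mask, as.integer(d), as.integer(iter))
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, iter = 1L) {
  d <- dim3(mask, "mask")
  if (iter <= 0L) return(mask)
  cpp_binary_erode(mask, as.integer(d), as.integer(iter))
}

#' @rdname binary_dilate
#' @export
label_connected <- function(mask) {
  d <- dim3(mask, "mask")
  cpp_label_components(mask, as.integer(d))
}

#' @rdname binary_dilate
#' @export
fill_holes <- function(mask) {
  d <- dim3(mask, "mask")
  cpp_fill_holes(mask, as.integer(d))
}

# erode until the voxel count first drops to <= target; attribute
# "iterations" records the erosion depth used
erode_to_count <- function(mask, target) {
  d <- dim3(mask, "mask")
  cpp_erode_to_count(mask, as.integer(d), as.numeric(target))
}

# keep only the largest 6-connected component of a mask
largest_component <- function(mask) {
  lab <- label_connected(mask)
  if (max(lab) <= 1L) return(mask)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  out <- lab == keep
  dim(out) <- dim(mask)
  out
}

# pad a 3D array by `pad` voxels of `value` on every face
pad_array <- function(a, pad, value = FALSE) {
  d <- dim(a)
  out <- array(value, dim = d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- a
  out
}

unpad_array <- function(a, pad, d) {
  a[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), drop = FALSE]
}
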