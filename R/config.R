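#' Analysis configuration
#'
#' Collects every tunable of the quantification pipeline with the published
#' defaults: the 300--3000 \eqn{\mu m^3} nuclear volume filter, 4 binary
#' dilations (connectivity 1) for the outer region, 40 dilation + 40 erosion
#' iterations for the spheroid mask closure, 3 equi-volumetric shells, and
#' Gaussian smoothing with \eqn{\sigma = 1} voxel.
#'
#' @param channels Named integer vector mapping channel names to 1-based
#'   TIFF channel indices (e.g. `c(nuclei = 1, ki67 = 2)`). The `nuclei`
#'   channel is mandatory for gating features.
#' @param spacing A [voxel_spacing()] for the input stacks (µm/voxel). The
#'   lateral pixel size is not recoverable from typical microscope TIFFs, so
#'   it must be supplied here.
#' @param volume_min_um3,volume_max_um3 Nuclear volume filter bounds in
#'   \eqn{\mu m^3}; nuclei strictly smaller/larger are excluded as debris or
#'   segmentation errors (values exactly at a bound are retained).
#' @param outer_dilations Dilations defining the proximate outer region.
#' @param closure_iterations Dilation/erosion iterations for the spheroid
#'   mask closure.
#' @param n_shells Number of equi-volumetric shells.
#' @param smooth_sigma Gaussian sigma (voxels) for masked smoothing.
#' @param fg_threshold Named list of per-channel foreground thresholds;
#'   channels not listed use a volume-wide Otsu threshold.
#' @param use_smoothed_features Use masked-smoothed intensities for
#'   classifier features (raw intensities are always reported as well).
#' @param seed Integer seed for every stochastic step.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(channels = c(nuclei = 1),
                            spacing = voxel_spacing(1, 1, 1),
                            volume_min_um3 = 300,
                            volume_max_um3 = 3000,
                            outer_dilations = 4L,
                            closure_iterations = 40L,
                            n_shells = 3L,
                            smooth_sigma = 1,
                            fg_threshold = list(),
                            use_smoothed_features = TRUE,
                            seed = 1L) {
  assert_that(volume_min_um3 < volume_max_um3,
              "volume filter bounds must satisfy min < max (got ",
              volume_min_um3, " >= ", volume_max_um3, ")")
  assert_that(n_shells >= 1L, "n_shells must be >= 1")
  assert_that(outer_dilations >= 1L, "outer_dilations must be >= 1")
  assert_that(smooth_sigma > 0, "smooth_sigma must be > 0")
  assert_that(is.numeric(seed) && length(seed) == 1L && seed == round(seed),
              "seed must be a single integer")
  structure(list(channels = channels, spacing = spacing,
                 volume_min_um3 = volume_min_um3,
                 volume_max_um3 = volume_max_um3,
                 outer_dilations = as.integer(outer_dilations),
                 closure_iterations = as.integer(closure_iterations),
                 n_shells = as.integer(n_shells),
                 smooth_sigma = smooth_sigma,
                 fg_threshold = fg_threshold,
                 use_smoothed_features = isTRUE(use_smoothed_features),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read/write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @param config An [analysis_config()].
#' @return `read_analysis_config()`: an [analysis_config()];
#'   `write_analysis_config()`: the path, invisibly.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- y$spacing %||% list(dz = 1, dy = 1, dx = 1)
  analysis_config(
    channels = unlist(y$channels %||% list(nuclei = 1)),
    spacing = voxel_spacing(sp$dz, sp$dy, sp$dx),
    volume_min_um3 = y$volume_min_um3 %||% 300,
    volume_max_um3 = y$volume_max_um3 %||% 3000,
    outer_dilations = y$outer_dilations %||% 4L,
    closure_iterations = y$closure_iterations %||% 40L,
    n_shells = y$n_shells %||% 3L,
    smooth_sigma = y$smooth_sigma %||% 1,
    fg_threshold = y$fg_threshold %||% list(),
    use_smoothed_features = y$use_smoothed_features %||% TRUE,
    seed = y$seed %||% 1L
  )
}

#' @rdname read_analysis_config
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  y <- unclass(config)
  y$spacing <- list(dz = config$spacing$dz, dy = config$spacing$dy,
                    dx = config$spacing$dx)
  y$channels <- as.list(config$channels)
  yaml::write_yaml(y, path)
  invisible(path)
}

# resolve the foreground threshold for one channel (config override or Otsu)
resolve_fg_threshold <- function(config, name, channel) {
  th <- config$fg_threshold[[name]]
  if (is.null(th)) otsu_threshold(channel) else th
}
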