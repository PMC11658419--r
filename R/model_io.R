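#' Serialize classification models to a YAML sidecar
#'
#' Writes a `marker_model` or `celltype_model` as a versioned, plain-text
#' YAML file carrying the ordered feature names, standardization
#' parameters and the linear decision function (weights, offset, side
#' convention). `read_model()` reconstructs an equivalent model whose
#' predictions match the original exactly.
#'
#' @param model A `marker_model` or `celltype_model`.
#' @param path Output YAML path.
#' @return `write_model()`: the path, invisibly; `read_model()`: the model.
#' @export
write_model <- function(model, path) {
  assert_that(inherits(model, "marker_model") ||
                inherits(model, "celltype_model"),
              "model must be a marker_model or celltype_model")
  y <- list(
    format_version = 1L,
    class = class(model)[1],
    marker = model$marker %||% NULL,
    mode = model$mode %||% NULL,
    feature_names = as.list(model$feature_names %||% character()),
    center = as.numeric(model$core$center),
    scale = as.numeric(model$core$scale),
    weights = as.numeric(model$core$w),
    rho = model$core$rho,
    pos_side_is_true = model$core$pos_side_is_true,
    n_support_vectors = model$core$n_sv,
    seed = model$seed,
    use_smoothed = model$use_smoothed,
    sigma = model$sigma %||% NULL
  )
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  y <- yaml::read_yaml(path)
  assert_that(identical(y$format_version, 1L) || identical(y$format_version, 1),
              "unsupported model format version")
  core <- list(center = as.numeric(y$center), scale = as.numeric(y$scale),
               w = as.numeric(y$weights), rho = y$rho,
               pos_side_is_true = isTRUE(y$pos_side_is_true),
               n_sv = y$n_support_vectors, train_pred = NULL)
  names(core$center) <- names(core$scale) <- names(core$w) <-
    unlist(y$feature_names)
  m <- list(core = core, seed = y$seed,
            feature_names = unlist(y$feature_names),
            use_smoothed = isTRUE(y$use_smoothed))
  if (identical(y$class, "celltype_model")) {
    m$mode <- y$mode
    class(m) <- "celltype_model"
  } else {
    m$marker <- y$marker
    m$sigma <- y$sigma
    class(m) <- "marker_model"
  }
  m
}
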