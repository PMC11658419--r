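## SVM marker gating: linear-kernel support vector classifiers (C = 1) on
## standardized per-nucleus intensity features decide Ki-67 and Live-or-Dye
## positivity; a one-feature linear SVM on the sigma = 1 smoothed
## CellTracker signal expands manual annotations into cell-type labels.

# canonical feature matrices per marker, from the cell table
marker_feature_names <- function(marker, use_smoothed = TRUE) {
  form <- if (use_smoothed) "smooth" else "raw"
  switch(marker,
    ki67 = c(paste0("nuclei_nuc_", form, "_mean"),
             paste0("ki67_nuc_", form, "_mean"),
             paste0("ki67_out_", form, "_mean")),
    lod = c(paste0("nuclei_nuc_", form, "_mean"),
            paste0("lod_nuc_", form, "_mean")),
    celltracker = paste0("celltracker_nuc_", form, "_mean"),
    abort_sq("unknown marker: ", marker))
}

#' Feature matrix for a named marker gate
#'
#' Generic accessor behind [ki67_features()] / [lod_features()] and the
#' CellTracker gate: returns the ordered feature columns for `marker` from
#' a cell table.
#'
#' @param records Cell table from [build_cell_table()].
#' @param marker One of `"ki67"`, `"lod"`, `"celltracker"`.
#' @param use_smoothed Use masked-smoothed intensities (default) or raw.
#' @return Numeric matrix, one row per record.
#' @export
marker_features <- function(records, marker, use_smoothed = TRUE) {
  nms <- marker_feature_names(marker, use_smoothed)
  missing <- setdiff(nms, names(records))
  assert_that(length(missing) == 0,
              "cell table lacks feature column(s) for marker '", marker,
              "': ", paste(missing, collapse = ", "),
              " (is the channel present?)")
  m <- as.matrix(records[, nms, drop = FALSE])
  # empty outer regions contribute a 0 feature (flagged in the cell table)
  out_cols <- grepl("_out_", nms)
  if (any(out_cols) && "outer_empty" %in% names(records))
    m[records$outer_empty, out_cols] <- 0
  m
}

#' Marker-gating feature vectors
#'
#' `ki67_features()`: ordered columns (mean nuclear-stain intensity in the
#' nucleus, mean Ki-67 intensity in the nucleus, mean Ki-67 intensity in
#' the proximate outer region). `lod_features()`: (mean nuclear-stain
#' intensity in the nucleus, mean Live-or-Dye intensity in the nucleus).
#' Nuclei with an empty outer region get a 0 outer feature (they remain
#' flagged via `outer_empty` in the cell table).
#'
#' @param records Cell table from [build_cell_table()].
#' @param use_smoothed Use masked-smoothed intensities (default) or raw.
#' @return Numeric matrix, one row per record, fixed column order.
#' @export
ki67_features <- function(records, use_smoothed = TRUE)
  marker_features(records, "ki67", use_smoothed)

#' @rdname ki67_features
#' @export
lod_features <- function(records, use_smoothed = TRUE)
  marker_features(records, "lod", use_smoothed)

# shared standardize + linear-SVM core. The fitted decision function is
# stored explicitly (weights w, offset rho, side convention) so models
# serialize to plain YAML and prediction is exact linear algebra.
svm_core_fit <- function(features, labels, seed) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  assert_that(!anyNA(labels) && length(unique(labels)) == 2L,
              "training labels must contain both classes")
  assert_that(nrow(features) == length(labels),
              "feature/label length mismatch")
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0] <- 1
  std <- scale(features, center = ctr, scale = scl)
  set.seed(seed)
  fit <- e1071::svm(x = std, y = factor(labels, levels = c(FALSE, TRUE)),
                    kernel = "linear", cost = 1, scale = FALSE)
  pr <- predict(fit, std, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  pred <- as.logical(as.character(pr))
  pos_side_is_true <- mean(pred == (dv > 0)) >= 0.5
  w <- drop(crossprod(fit$coefs, fit$SV))
  core <- list(center = ctr, scale = scl, w = w, rho = fit$rho,
               pos_side_is_true = pos_side_is_true,
               n_sv = nrow(fit$SV), train_pred = NULL)
  core$train_pred <- svm_core_predict(core, features)
  # contract: the stored decision function reproduces libsvm's predictions
  assert_that(all(core$train_pred == pred),
              "internal error: decision function does not reproduce fit")
  core
}

svm_core_predict <- function(core, features) {
  std <- scale(as.matrix(features), center = core$center, scale = core$scale)
  dv <- drop(std %*% core$w) - core$rho
  if (core$pos_side_is_true) dv > 0 else dv <= 0
}

#' Train a marker-positivity SVM
#'
#' Fits a linear-kernel support vector classifier (C = 1) on standardized
#' features (train-set mean/SD). Deterministic for a fixed seed; applying
#' the model to its own training set reproduces the stored training
#' predictions exactly.
#'
#' @param features Numeric matrix (n x d), e.g. from [ki67_features()].
#' @param labels Logical vector of length n; both classes must be present.
#' @param seed Integer seed.
#' @param marker Marker name carried by the model.
#' @param use_smoothed Whether the features came from smoothed intensities.
#' @return An object of class `marker_model`.
#' @export
train_marker_svm <- function(features, labels, seed = 1L, marker = "marker",
                             use_smoothed = TRUE) {
  core <- svm_core_fit(features, labels, seed)
  structure(list(marker = marker,
                 feature_names = colnames(as.matrix(features)),
                 core = core, seed = as.integer(seed),
                 use_smoothed = isTRUE(use_smoothed)),
            class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf("<marker_model> %s: linear SVM on %d feature(s), %d SV\n",
              x$marker, length(x$core$center), x$core$n_sv))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.marker_model <- function(x, ...) {
  tibble::tibble(feature = x$feature_names %||%
                   paste0("f", seq_along(x$core$center)),
                 center = unname(x$core$center),
                 scale = unname(x$core$scale),
                 weight = unname(x$core$w))
}

#' @exportS3Method generics::glance
glance.marker_model <- function(x, ...) {
  tibble::tibble(marker = x$marker,
                 n_features = length(x$core$center),
                 n_support_vectors = x$core$n_sv,
                 seed = x$seed)
}

#' Apply a marker gate to a cell table
#'
#' Predicts per-nucleus positivity and the positive fraction. The fraction
#' denominator is the total number of (surviving) nuclei, not a gated
#' subset.
#'
#' @param model A `marker_model`.
#' @param records Cell table from [build_cell_table()], or a feature matrix
#'   with the model's columns.
#' @return An object of class `gate_result`: tibble (id, positive) with the
#'   positive fraction as attribute `fraction`.
#' @export
predict_marker <- function(model, records) {
  stopifnot(inherits(model, "marker_model"))
  if (is.data.frame(records) &&
      model$marker %in% c("ki67", "lod", "celltracker")) {
    feats <- marker_features(records, model$marker, model$use_smoothed)
    ids <- records$id %||% seq_len(nrow(records))
  } else {
    feats <- as.matrix(records)
    assert_that(ncol(feats) == length(model$core$center),
                "feature matrix has ", ncol(feats), " column(s), model ",
                "expects ", length(model$core$center))
    ids <- seq_len(nrow(feats))
  }
  pos <- svm_core_predict(model$core, feats)
  res <- tibble::tibble(id = ids, positive = pos)
  structure(res, fraction = mean(pos), marker = model$marker,
            class = c("gate_result", class(res)))
}

#' Positive fraction of a gate result
#'
#' @param x A `gate_result`.
#' @return Positives divided by total nuclei, in `[0, 1]`.
#' @export
gate_fraction <- function(x) {
  stopifnot(inherits(x, "gate_result"))
  attr(x, "fraction")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("<gate_result> %s: %d/%d positive (%.1f%%)\n",
              attr(x, "marker"), sum(x$positive), nrow(x),
              100 * attr(x, "fraction")))
  invisible(as.data.frame(x))
}

#' CellTracker label-expansion SVM
#'
#' One-feature linear SVM on the mean CellTracker intensity within the
#' nucleus, computed from the Gaussian-smoothed (sigma = 1 voxel)
#' CellTracker channel. Trained on a small manual annotation and used only
#' to expand cell-type training labels for the tumor/fibroblast classifier.
#'
#' @param records Cell table including `celltracker` channel statistics.
#' @param annotations Tibble or data.frame with columns `id` and
#'   `celltracker_positive` (logical), covering both classes.
#' @param sigma Smoothing sigma that produced the features; must be 1 (the
#'   cell table's `smooth_sigma`) unless deliberately overridden.
#' @param seed Integer seed.
#' @return A `marker_model` with marker `"celltracker"`.
#' @export
celltracker_svm <- function(records, annotations, sigma = 1, seed = 1L) {
  assert_that(all(c("id", "celltracker_positive") %in% names(annotations)),
              "annotations need columns id, celltracker_positive")
  ann <- dplyr::inner_join(records, tibble::as_tibble(annotations), by = "id")
  assert_that(nrow(ann) > 0, "no annotated ids found in the cell table")
  feats <- marker_features(ann, "celltracker", use_smoothed = TRUE)
  model <- train_marker_svm(feats, ann$celltracker_positive, seed = seed,
                            marker = "celltracker", use_smoothed = TRUE)
  model$sigma <- sigma
  model
}

#' Aggregate cleaved caspase-3 index
#'
#' Late-apoptotic cells cluster too densely to attribute Cas3 signal to
#' individual nuclei, so the above-threshold Cas3 intensity is aggregated
#' over the whole image and normalized by the total nucleus count:
#' \deqn{\mathrm{index} = \sum_x I(x)\,1[I(x) > t] \; / \; n_{nuclei}.}
#'
#' @param cas3_channel 3D Cas3 intensity array.
#' @param threshold Foreground threshold (same convention as the masked
#'   smoothing: values \eqn{\le} threshold are background).
#' @param n_nuclei Total number of nuclei (>= 1).
#' @return Intensity per cell (a.u.).
#' @export
cas3_index <- function(cas3_channel, threshold, n_nuclei) {
  assert_that(n_nuclei >= 1, "n_nuclei must be >= 1")
  sum(cas3_channel[cas3_channel > threshold]) / n_nuclei
}
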