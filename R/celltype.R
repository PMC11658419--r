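## Tumor/fibroblast discrimination in co-cultures. Fibroblast nuclei are
## smaller (mode ~500 um^3) and elongated; tumor nuclei larger (~1200 um^3)
## and rounder — but small round late-mitotic tumor nuclei confound a
## volume-only rule, so the classifier also uses the collagen-1 context
## (fibroblasts secrete collagen-1; tumor mono-cultures do not). The default
## classifier is a linear SVM on these features; a CNN-crop builder is
## provided for deep-learning backends.

#' Expand CellTracker annotations into cell-type labels
#'
#' Applies a trained CellTracker gate ([celltracker_svm()]) to a cell
#' table: CellTracker-positive nuclei are labeled fibroblast, the rest
#' tumor. Used to generate training labels for the cell-type classifier
#' from a small manual annotation.
#'
#' @param records Cell table with CellTracker channel statistics.
#' @param model A `marker_model` with marker `"celltracker"`.
#' @return Character vector (`"fibroblast"`/`"tumor"`), one per record.
#' @export
expand_labels_with_celltracker <- function(records, model) {
  stopifnot(inherits(model, "marker_model"))
  assert_that(identical(model$marker, "celltracker"),
              "model must be a CellTracker gate")
  gate <- predict_marker(model, records)
  ifelse(gate$positive, "fibroblast", "tumor")
}

#' Cell-type discrimination features
#'
#' Ordered columns: nuclear volume (\eqn{\mu m^3}), elongation
#' (major/minor axis ratio), mean collagen-1 intensity in the proximate
#' outer region, mean collagen-1 intensity in the nucleus. Empty outer
#' regions contribute a 0 collagen-outer feature.
#'
#' @param records Cell table from [build_cell_table()] including a
#'   `collagen1` channel.
#' @param use_smoothed Use masked-smoothed intensities (default) or raw.
#' @return Numeric matrix, one row per record, fixed column order.
#' @export
celltype_features <- function(records, use_smoothed = TRUE) {
  form <- if (use_smoothed) "smooth" else "raw"
  nms <- c("volume_um3", "elongation",
           paste0("collagen1_out_", form, "_mean"),
           paste0("collagen1_nuc_", form, "_mean"))
  missing <- setdiff(nms, names(records))
  assert_that(length(missing) == 0, "cell table lacks column(s): ",
              paste(missing, collapse = ", "))
  m <- as.matrix(records[, nms, drop = FALSE])
  if ("outer_empty" %in% names(records))
    m[records$outer_empty, 3] <- 0
  m[is.na(m[, 2]), 2] <- 1   # degenerate elongation -> round
  m
}

#' Train the tumor/fibroblast SVM
#'
#' Standardized linear-kernel SVM (C = 1) on [celltype_features()].
#' Deterministic under the seed.
#'
#' @param features Matrix from [celltype_features()].
#' @param type_labels Character vector, `"tumor"`/`"fibroblast"`.
#' @param seed Integer seed.
#' @param use_smoothed Whether features came from smoothed intensities.
#' @return An object of class `celltype_model`.
#' @export
train_celltype_svm <- function(features, type_labels, seed = 1L,
                               use_smoothed = TRUE) {
  assert_that(all(type_labels %in% c("tumor", "fibroblast")),
              "type labels must be 'tumor' or 'fibroblast'")
  core <- svm_core_fit(features, type_labels == "fibroblast", seed)
  structure(list(mode = "feature-svm",
                 feature_names = colnames(as.matrix(features)),
                 core = core, seed = as.integer(seed),
                 use_smoothed = isTRUE(use_smoothed)),
            class = "celltype_model")
}

#' @export
print.celltype_model <- function(x, ...) {
  cat(sprintf("<celltype_model> %s on [%s]\n", x$mode,
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.celltype_model <- function(x, ...) {
  tibble::tibble(feature = x$feature_names, center = unname(x$core$center),
                 scale = unname(x$core$scale), weight = unname(x$core$w))
}

#' @exportS3Method generics::glance
glance.celltype_model <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_features = length(x$core$center),
                 n_support_vectors = x$core$n_sv, seed = x$seed)
}

#' Predict cell types
#'
#' @param model A `celltype_model`.
#' @param records Cell table (features are rebuilt with the model's
#'   settings) or a feature matrix.
#' @return Character vector `"tumor"`/`"fibroblast"`, one per record.
#' @export
predict_celltype <- function(model, records) {
  stopifnot(inherits(model, "celltype_model"))
  feats <- if (is.data.frame(records))
    celltype_features(records, model$use_smoothed)
  else as.matrix(records)
  fib <- svm_core_predict(model$core, feats)
  ifelse(fib, "fibroblast", "tumor")
}

#' Three-channel crop for a CNN cell-type classifier
#'
#' Crop of shape (48, 64, 64) in (z, y, x), centered on the nucleus
#' centroid, channels in fixed order: nuclei intensity, collagen-1
#' intensity, binary mask of the focal nucleus only. Out-of-bounds regions
#' are zero-padded. Built on the isotropic grid so the window has a fixed
#' physical meaning.
#'
#' @param volume A [multichannel_volume()] with `nuclei` and `collagen1`.
#' @param labels A [label_volume()].
#' @param id Instance id.
#' @param crop_dim Crop shape, default `c(48, 64, 64)`.
#' @return 4D numeric array (channel, z, y, x) with the mask channel in
#'   `{0, 1}`.
#' @export
crop_for_cnn <- function(volume, labels, id, crop_dim = c(48L, 64L, 64L)) {
  stopifnot(inherits(volume, "multichannel_volume"),
            inherits(labels, "label_volume"))
  assert_that(all(c("nuclei", "collagen1") %in% names(volume$channels)),
              "volume needs 'nuclei' and 'collagen1' channels")
  lab <- labels$labels
  w <- which(lab == id)
  assert_that(length(w) > 0, "id ", id, " not present in labels")
  d <- dim(lab)
  ctr <- round(colMeans(arrayInd(w, d)))
  lo <- as.integer(ctr - crop_dim %/% 2L + 1L)
  hi <- lo + as.integer(crop_dim) - 1L
  src_lo <- pmax(lo, 1L); src_hi <- pmin(hi, d)
  dst_lo <- src_lo - lo + 1L; dst_hi <- dst_lo + (src_hi - src_lo)
  take <- function(a) {
    out <- array(0, dim = crop_dim)
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      a[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
    out
  }
  crop <- array(0, dim = c(3L, crop_dim))
  crop[1, , , ] <- take(volume$channels$nuclei)
  crop[2, , , ] <- take(volume$channels$collagen1)
  crop[3, , , ] <- take(array(as.numeric(lab == id), dim = d))
  crop
}

#' Corrected per-cell-type counts
#'
#' Decomposes a co-culture's total nucleus count into cell types: the
#' corrected tumor count is the total minus the predicted fibroblast
#' count, so the two always sum to the total.
#'
#' @param records Cell table (one row per nucleus).
#' @param type_predictions Character vector from [predict_celltype()],
#'   one per record.
#' @return An object of class `corrected_counts`: one-row tibble with
#'   total, n_fibroblast, n_tumor, fibroblast_fraction, tumor_fraction.
#' @export
corrected_counts <- function(records, type_predictions) {
  assert_that(length(type_predictions) == nrow(records),
              "predictions (", length(type_predictions),
              ") do not match records (", nrow(records), ")")
  assert_that(all(type_predictions %in% c("tumor", "fibroblast")),
              "predictions must be 'tumor' or 'fibroblast'")
  total <- nrow(records)
  n_fib <- sum(type_predictions == "fibroblast")
  res <- tibble::tibble(total = total, n_fibroblast = n_fib,
                        n_tumor = total - n_fib,
                        fibroblast_fraction = n_fib / total,
                        tumor_fraction = (total - n_fib) / total)
  structure(res, class = c("corrected_counts", class(res)))
}

#' Aggregate corrected counts over replicate spheroids
#'
#' @param counts_list List of `corrected_counts` (one per spheroid).
#' @return Tibble of mean and SD per count column.
#' @export
aggregate_corrected_counts <- function(counts_list) {
  df <- dplyr::bind_rows(lapply(counts_list, tibble::as_tibble))
  tidyr::pivot_longer(df, dplyr::everything(),
                      names_to = "metric", values_to = "value") %>%
    dplyr::group_by(.data$metric) %>%
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}
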