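#' Write / read the per-nucleus cell table
#'
#' CSV (RFC 4180, UTF-8, '.' decimal) with one row per nucleus and a fixed,
#' documented column order (id, morphology, per-channel statistics, flags,
#' any gating/typing columns appended). Missing values (e.g. an unset shell
#' index) are written as empty cells, not 0. Writing then reading
#' reproduces values to better than 1e-9.
#'
#' @param records Cell table tibble (non-empty).
#' @param path Output CSV path.
#' @return `write_cell_table()`: the path, invisibly;
#'   `read_cell_table()`: a tibble.
#' @export
write_cell_table <- function(records, path) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "cell table is empty; nothing to write")
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "")
}

#' Run the full spheroid quantification pipeline
#'
#' Orchestrates the in-scope stages end to end: load (or accept) the
#' multi-channel stack and nuclei instance mask, rescale both to isotropic
#' resolution, apply the 300--3000 \eqn{\mu m^3} volume filter, extract
#' per-nucleus morphology and intensity features (raw and masked-smoothed,
#' nucleus and outer region), apply any supplied marker gates, compute the
#' aggregate Cas3 index, build the spheroid mask and morphometry, the
#' per-nucleus center/hull distances, and the equi-volumetric shell
#' partition with per-shell statistics. Deterministic for a fixed config
#' seed; results are returned and, if `out_dir` is given, written as CSVs
#' plus a run log.
#'
#' @param config An [analysis_config()].
#' @param image A [multichannel_volume()] or path to a multi-channel TIFF.
#' @param labels A [label_volume()] or path to a label TIFF.
#' @param out_dir Optional output directory (created if needed).
#' @param marker_models Optional named list of `marker_model`s (e.g.
#'   `list(ki67 = ..., lod = ...)`); predictions are appended to the cell
#'   table as `<marker>_positive` and fractions to the metrics.
#' @param celltype_model Optional `celltype_model`; predictions appended as
#'   `cell_type` with corrected counts in the bundle.
#' @return An object of class `pipeline_result`: list with `cell_table`,
#'   `excluded`, `spheroid` (a `spheroid_metrics`), `shells`,
#'   `shell_table`, `metrics` (one-row tibble incl. cas3 index and marker
#'   fractions), and `corrected` (if a cell-type model was supplied).
#' @export
run_pipeline <- function(config, image, labels, out_dir = NULL,
                         marker_models = list(), celltype_model = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  set.seed(config$seed)
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort_sq("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  vol <- stage("load_volume",
    if (inherits(image, "multichannel_volume")) image
    else load_volume(image, config$channels, config$spacing))
  lab <- stage("load_labels",
    if (inherits(labels, "label_volume")) labels
    else suppressMessages(load_label_volume(labels, config$spacing)))
  say("loaded ", length(vol$channels), " channel(s), ",
      n_instances(lab), " nuclei")

  vol <- stage("rescale", rescale_to_isotropic(vol))
  lab <- stage("rescale", rescale_to_isotropic(lab))

  filt <- stage("volume_filter",
    filter_nuclei_by_volume(lab, config$volume_min_um3,
                            config$volume_max_um3))
  say("volume filter: ", nrow(filt$excluded), " excluded, ",
      n_instances(filt$labels), " retained")

  cells <- stage("cell_table", build_cell_table(vol, filt$labels, config))

  for (mk in names(marker_models)) {
    gate <- stage(paste0("gate_", mk),
                  predict_marker(marker_models[[mk]], cells))
    cells[[paste0(mk, "_positive")]] <- gate$positive
    say(mk, " gate: ", round(100 * gate_fraction(gate), 2), "% positive")
  }
  if (!is.null(celltype_model)) {
    cells$cell_type <- stage("celltype",
                             predict_celltype(celltype_model, cells))
  }

  sph <- stage("spheroid_morphometry",
               spheroid_morphometry(filt$labels, config))
  dists <- stage("distances", dplyr::bind_rows(lapply(
    seq_len(nrow(cells)), function(i)
      nucleus_distances(sph$mask,
                        c(cells$centroid_z_um[i], cells$centroid_y_um[i],
                          cells$centroid_x_um[i]), filt$labels$spacing))))
  cells <- dplyr::bind_cols(cells, dists)

  shells <- stage("shells",
                  partition_shells(sph$mask, config$n_shells,
                                   filt$labels$spacing))
  cells$shell_index <- vapply(seq_len(nrow(cells)), function(i) {
    k <- shell_index_at(shells, c(cells$centroid_z_um[i],
                                  cells$centroid_y_um[i],
                                  cells$centroid_x_um[i]))
    if (k == 0L) NA_integer_ else as.integer(k)
  }, integer(1))
  marker_cols <- paste0(names(marker_models), "_positive")
  shell_tab <- stage("shell_statistics",
                     shell_statistics(shells, cells,
                                      markers = intersect(marker_cols,
                                                          names(cells))))

  metrics <- sph$metrics
  if ("cas3" %in% names(vol$channels)) {
    th <- resolve_fg_threshold(config, "cas3", vol$channels$cas3)
    metrics$cas3_index <- cas3_index(vol$channels$cas3, th, nrow(cells))
  }
  for (mk in names(marker_models))
    metrics[[paste0(mk, "_fraction")]] <-
      mean(cells[[paste0(mk, "_positive")]])

  corrected <- NULL
  if (!is.null(celltype_model))
    corrected <- corrected_counts(cells, cells$cell_type)

  res <- structure(list(cell_table = cells, excluded = filt$excluded,
                        spheroid = sph, shells = shells,
                        shell_table = shell_tab, metrics = metrics,
                        corrected = corrected, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cell_table(cells, file.path(out_dir, "cell_table.csv"))
    readr::write_csv(metrics, file.path(out_dir, "spheroid_metrics.csv"))
    readr::write_csv(shell_tab, file.path(out_dir, "shell_table.csv"))
    if (nrow(filt$excluded) > 0)
      readr::write_csv(filt$excluded, file.path(out_dir, "excluded.csv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
    say("results written to ", out_dir)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d nuclei, %d excluded\n",
              nrow(x$cell_table), nrow(x$excluded)))
  print(as.data.frame(x$metrics))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pipeline_result <- function(x, ...) x$metrics

#' @exportS3Method generics::tidy
tidy.pipeline_result <- function(x, ...) x$cell_table
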