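#' Z-score normalize table columns
#'
#' Per column: \eqn{(x - \bar x)/s} with the sample SD (ddof 1), the
#' convention of spreadsheet/statistics-package heatmap normalization.
#' Output columns have mean 0 and SD 1.
#'
#' @param table Data frame of condition-by-metric values.
#' @param cols Columns to normalize (default: all numeric columns).
#' @return Tibble of the same shape with normalized columns.
#' @export
z_score_normalize <- function(table, cols = NULL) {
  tb <- tibble::as_tibble(table)
  if (is.null(cols))
    cols <- names(tb)[vapply(tb, is.numeric, logical(1))]
  for (cl in cols) {
    x <- tb[[cl]]
    assert_that(is.numeric(x), "column '", cl, "' is not numeric")
    s <- stats::sd(x)
    assert_that(is.finite(s) && s > 0,
                "column '", cl, "' has zero/undefined SD; cannot z-score")
    tb[[cl]] <- (x - mean(x)) / s
  }
  tb
}

# overlap bookkeeping shared by SEG and DET: for each GT object, the pred
# object covering > 50% of its voxels (at most one can exist)
seg_det_matches <- function(gt, pred) {
  glab <- if (inherits(gt, "label_volume")) gt$labels else gt
  plab <- if (inherits(pred, "label_volume")) pred$labels else pred
  assert_that(all(dim(glab) == dim(plab)), "gt and pred shapes differ")
  gt_ids <- sort(unique(glab[glab > 0L]))
  pred_ids <- sort(unique(plab[plab > 0L]))
  sel <- glab > 0L | plab > 0L
  ov <- tibble::tibble(gt = as.integer(glab[sel]),
                       pred = as.integer(plab[sel])) %>%
    dplyr::count(.data$gt, .data$pred, name = "n")
  gt_sizes <- ov %>% dplyr::filter(.data$gt > 0L) %>%
    dplyr::group_by(.data$gt) %>%
    dplyr::summarise(size = sum(.data$n), .groups = "drop")
  pred_sizes <- ov %>% dplyr::filter(.data$pred > 0L) %>%
    dplyr::group_by(.data$pred) %>%
    dplyr::summarise(size = sum(.data$n), .groups = "drop")
  pairs <- ov %>% dplyr::filter(.data$gt > 0L, .data$pred > 0L) %>%
    dplyr::left_join(gt_sizes, by = "gt") %>%
    dplyr::rename(gt_size = "size") %>%
    dplyr::left_join(pred_sizes, by = "pred") %>%
    dplyr::rename(pred_size = "size") %>%
    dplyr::mutate(coverage = .data$n / .data$gt_size,
                  jaccard = .data$n /
                    (.data$gt_size + .data$pred_size - .data$n))
  matches <- pairs %>% dplyr::filter(.data$coverage > 0.5)
  list(gt_ids = gt_ids, pred_ids = pred_ids, pairs = pairs,
       matches = matches)
}

#' SEG segmentation score
#'
#' Cell-tracking-challenge segmentation measure: each ground-truth object
#' is matched to the predicted object covering more than half of its
#' voxels (at most one can exist); SEG is the mean Jaccard index over all
#' ground-truth objects, counting unmatched objects as 0.
#'
#' @param gt,pred [label_volume()]s or integer arrays of the same shape.
#' @return SEG in `[0, 1]`, with the per-object match table as attribute
#'   `matches` (gt id, matched pred id, Jaccard).
#' @export
seg_score <- function(gt, pred) {
  m <- seg_det_matches(gt, pred)
  assert_that(length(m$gt_ids) > 0, "ground truth contains no objects")
  tab <- tibble::tibble(gt = m$gt_ids) %>%
    dplyr::left_join(dplyr::select(m$matches, "gt", "pred", "jaccard"),
                     by = "gt") %>%
    dplyr::mutate(jaccard = ifelse(is.na(.data$jaccard), 0, .data$jaccard))
  structure(mean(tab$jaccard), matches = tab)
}

#' DET detection score
#'
#' Cell-tracking-challenge detection measure, computed from the >50%
#' ground-truth coverage matching as a normalized detection graph edit
#' cost: \eqn{AOGM_D = 10\,FN + 1\,FP + 5\,NS} (FN = unmatched ground-truth
#' objects, FP = predicted objects that are no object's majority cover,
#' NS = ground-truth objects claimed by two or more matched predicted
#' objects), and \eqn{DET = 1 - \min(AOGM_D, AOGM_{D0})/AOGM_{D0}} with
#' \eqn{AOGM_{D0} = 10\, n_{GT}} (the cost of building the detection from
#' scratch).
#'
#' @param gt,pred [label_volume()]s or integer arrays of the same shape.
#' @return DET in `[0, 1]` with attribute `counts` (FN, FP, NS).
#' @export
det_score <- function(gt, pred) {
  m <- seg_det_matches(gt, pred)
  n_gt <- length(m$gt_ids)
  assert_that(n_gt > 0, "ground truth contains no objects")
  matched_gt <- m$matches$gt
  matched_pred <- unique(m$matches$pred)
  fn <- sum(!(m$gt_ids %in% matched_gt))
  fp <- sum(!(m$pred_ids %in% matched_pred))
  # GT objects overlapped by >= 2 matched predicted objects
  ns <- m$pairs %>%
    dplyr::filter(.data$pred %in% matched_pred) %>%
    dplyr::group_by(.data$gt) %>%
    dplyr::summarise(k = dplyr::n_distinct(.data$pred), .groups = "drop") %>%
    dplyr::filter(.data$k >= 2L) %>% nrow()
  aogm <- 10 * fn + 1 * fp + 5 * ns
  aogm0 <- 10 * n_gt
  structure(1 - min(aogm, aogm0) / aogm0,
            counts = c(FN = fn, FP = fp, NS = ns))
}

#' Evaluate a segmentation against ground truth
#'
#' @param gt,pred [label_volume()]s or integer arrays of the same shape.
#' @return An object of class `seg_eval`: list with `SEG`, `DET` and the
#'   per-object `matches` table.
#' @export
evaluate_segmentation <- function(gt, pred) {
  s <- seg_score(gt, pred)
  d <- det_score(gt, pred)
  structure(list(SEG = as.numeric(s), DET = as.numeric(d),
                 matches = attr(s, "matches"),
                 det_counts = attr(d, "counts")),
            class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("<seg_eval> SEG = %.3f, DET = %.3f (FN %d, FP %d, NS %d)\n",
              x$SEG, x$DET, x$det_counts["FN"], x$det_counts["FP"],
              x$det_counts["NS"]))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.seg_eval <- function(x, ...) {
  tibble::tibble(SEG = x$SEG, DET = x$DET,
                 FN = unname(x$det_counts["FN"]),
                 FP = unname(x$det_counts["FP"]),
                 NS = unname(x$det_counts["NS"]))
}

#' Build a condition-by-metric table from replicate runs
#'
#' Aggregates per-spheroid metric tibbles into replicate means and SDs per
#' condition, recording a reference condition (e.g. untreated tumor
#' mono-culture) for downstream normalization. A z-scored view of the
#' means is available via [z_score_normalize()].
#'
#' @param runs Tibble with a `condition` column and numeric metric columns
#'   (one row per replicate spheroid).
#' @param reference Name of the reference condition; must be present.
#' @return An object of class `condition_table`: list with `means`, `sds`
#'   (tibbles, one row per condition) and `reference`.
#' @export
build_condition_table <- function(runs, reference) {
  tb <- tibble::as_tibble(runs)
  assert_that("condition" %in% names(tb), "runs need a 'condition' column")
  assert_that(reference %in% tb$condition,
              "reference condition '", reference, "' not found")
  num <- names(tb)[vapply(tb, is.numeric, logical(1))]
  means <- tb %>% dplyr::group_by(.data$condition) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(num), mean), .groups = "drop")
  sds <- tb %>% dplyr::group_by(.data$condition) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(num), stats::sd),
                     .groups = "drop")
  structure(list(means = means, sds = sds, reference = reference),
            class = "condition_table")
}

#' @export
print.condition_table <- function(x, ...) {
  cat("<condition_table> reference:", x$reference, "\nmeans:\n")
  print(as.data.frame(x$means))
  invisible(x)
}

#' Z-scored view of a condition table
#'
#' @param x A `condition_table`.
#' @param subtract_reference Subtract the reference condition's mean from
#'   each column before z-scoring (default `FALSE`: z-score over all
#'   conditions per metric; the reference is bookkeeping either way).
#' @return Tibble of z-scored condition means.
#' @export
condition_zscores <- function(x, subtract_reference = FALSE) {
  stopifnot(inherits(x, "condition_table"))
  tb <- x$means
  assert_that(x$reference %in% tb$condition,
              "reference condition '", x$reference,
              "' missing from the table")
  num <- setdiff(names(tb)[vapply(tb, is.numeric, logical(1))], "condition")
  if (subtract_reference) {
    ref <- tb[tb$condition == x$reference, num]
    for (cl in num) tb[[cl]] <- tb[[cl]] - ref[[cl]]
  }
  z_score_normalize(tb, num)
}
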