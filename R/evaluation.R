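#' Registration error over ground-truth pairs (point RMSE)
#'
#' Root-mean-square Euclidean distance between each scene point and its
#' aligned ground-truth partner: sqrt(mean over the J truth pairs of
#' ||x_j - y_j||^2), where y_j is the aligned model point matched to scene
#' point x_j.
#'
#' @param aligned Aligned (transformed) model points.
#' @param scene Scene points.
#' @param truth Data frame of ground-truth pairs with columns `scene` and
#'   `model` (1-based row indices into `scene` and `aligned`).
#' @return Scalar RMSE in the coordinate units of the inputs.
#' @examples
#' rmse_points(tibble::tibble(x = 3, y = 4), tibble::tibble(x = 0, y = 0),
#'             tibble::tibble(scene = 1, model = 1))
#' @export
rmse_points <- function(aligned, scene, truth) {
  if (is.null(truth) || nrow(truth) == 0L) {
    abort("truth pairs must be non-empty", class = "driftreg_invalid_input")
  }
  a <- as_point_matrix(aligned)
  x <- as_point_matrix(scene)
  d <- x[truth$scene, , drop = FALSE] - a[truth$model, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Intensity RMSE between two images
#'
#' Root-mean-square difference of two intensity grids of identical size.
#'
#' @param img_a,img_b Numeric matrices (U x V intensity grids).
#' @return Scalar RMSE in intensity units.
#' @export
rmse_images <- function(img_a, img_b) {
  if (!all(dim(img_a) == dim(img_b))) {
    abort("images must have identical dimensions",
          class = "driftreg_invalid_input")
  }
  sqrt(mean((img_a - img_b)^2))
}

#' Score predicted correspondences against ground truth
#'
#' A ground-truth pair counts as a true positive when the aligned model point
#' lies within `threshold` of its scene partner, and as a false negative
#' otherwise. False positives are predicted pairs absent from the truth set
#' (a reporting convention for the registration setting; pairs predicted as
#' outliers, i.e. with `model` NA, are not counted).
#'
#' @param predicted Data frame of predicted pairs (`scene`, `model`), e.g.
#'   `tidy(fit)`; may be `NULL` or empty, in which case fp = 0.
#' @param truth Data frame of ground-truth pairs (`scene`, `model`).
#' @param aligned,scene Point sets used for the distance test.
#' @param threshold Positive distance threshold.
#' @return A tibble with columns `tp`, `fp`, `fn`.
#' @export
score_correspondences <- function(predicted, truth, aligned, scene,
                                  threshold) {
  stopifnot(threshold > 0)
  a <- as_point_matrix(aligned)
  x <- as_point_matrix(scene)
  d <- sqrt(rowSums((x[truth$scene, , drop = FALSE] -
                       a[truth$model, , drop = FALSE])^2))
  tp <- sum(d <= threshold)
  fn <- nrow(truth) - tp
  fp <- 0L
  if (!is.null(predicted) && nrow(predicted) > 0L) {
    pred <- predicted[!is.na(predicted$model), c("scene", "model")]
    if (nrow(pred) > 0L) {
      key <- function(df) paste(df$scene, df$model)
      fp <- sum(!(key(pred) %in% key(truth)))
    }
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn)
}

#' Recall, precision and F1 from correspondence counts
#'
#' recall = tp / (tp + fn), precision = tp / (tp + fp),
#' f1 = 2 tp / (2 tp + fp + fn). Empty denominators yield 0 with a warning.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return A tibble with columns `recall`, `precision`, `f1`.
#' @examples
#' precision_recall_f1(3, 1, 2)
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  guarded <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warn(sprintf("%s undefined (zero denominator); reported as 0", what))
    }
    out
  }
  tibble::tibble(
    recall = guarded(tp, tp + fn, "recall"),
    precision = guarded(tp, tp + fp, "precision"),
    f1 = guarded(2 * tp, 2 * tp + fp + fn, "F1")
  )
}

#' Recall-accuracy curve
#'
#' Recall of ground-truth correspondences recovered within each of a series
#' of ascending distance thresholds (the ground-truth pairing is used for the
#' distance test; set `pairing = "predicted"` to restrict to pairs the fit
#' actually predicted). The curve is non-decreasing in the threshold.
#'
#' @inheritParams score_correspondences
#' @param thresholds Ascending positive thresholds (e.g. pixel radii 1:5).
#' @param pairing `"truth"` (default) or `"predicted"`.
#' @param predicted Predicted pairs, required for `pairing = "predicted"`.
#' @return A tibble with columns `threshold`, `recall`.
#' @export
recall_accuracy_curve <- function(aligned, scene, truth, thresholds,
                                  pairing = c("truth", "predicted"),
                                  predicted = NULL) {
  pairing <- match.arg(pairing)
  stopifnot(all(diff(thresholds) >= 0), all(thresholds > 0))
  pairs <- truth
  if (pairing == "predicted") {
    if (is.null(predicted)) abort("predicted pairs required")
    pred <- predicted[!is.na(predicted$model), c("scene", "model")]
    key <- function(df) paste(df$scene, df$model)
    pairs <- truth[key(truth) %in% key(pred), , drop = FALSE]
  }
  a <- as_point_matrix(aligned)
  x <- as_point_matrix(scene)
  j <- nrow(truth)
  d <- if (nrow(pairs) > 0L) {
    sqrt(rowSums((x[pairs$scene, , drop = FALSE] -
                    a[pairs$model, , drop = FALSE])^2))
  } else {
    numeric(0)
  }
  tibble::tibble(
    threshold = thresholds,
    recall = vapply(thresholds, function(th) sum(d <= th) / j, numeric(1))
  )
}

#' Full metrics report for a registration fit
#'
#' Convenience wrapper computing point RMSE, correspondence counts at a
#' threshold, the derived rates, and a recall-accuracy curve for a
#' [cpd_register()] fit evaluated against a ground truth.
#'
#' @param fit A `cpd_fit`.
#' @param truth Ground-truth pairs (`scene`, `model`).
#' @param threshold Distance threshold for the TP test (scene units).
#' @param thresholds Thresholds for the recall-accuracy curve.
#' @return A one-row tibble: `rmse`, `tp`, `fp`, `fn`, `recall`, `precision`,
#'   `f1`, and a list-column `recall_accuracy`.
#' @export
evaluate_fit <- function(fit, truth, threshold = 0.05,
                         thresholds = seq(0.01, 0.05, by = 0.01)) {
  stopifnot(inherits(fit, "cpd_fit"))
  counts <- score_correspondences(fit$correspondence, truth,
                                  fit$aligned, fit$scene, threshold)
  rates <- precision_recall_f1(counts$tp, counts$fp, counts$fn)
  curve <- recall_accuracy_curve(fit$aligned, fit$scene, truth, thresholds)
  dplyr::bind_cols(
    tibble::tibble(rmse = rmse_points(fit$aligned, fit$scene, truth)),
    counts, rates,
    tibble::tibble(recall_accuracy = list(curve))
  )
}
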