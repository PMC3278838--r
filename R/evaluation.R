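#' Confusion counts for binary predictions
#'
#' @param truth Binary reference labels (0/1; 1 = amyloidogenic).
#' @param predicted Binary predicted labels, same length.
#' @return One-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (!all(c(truth, predicted) %in% c(0L, 1L))) {
    abort("Labels must be binary 0/1.")
  }
  tibble(tp = sum(truth == 1L & predicted == 1L),
         fp = sum(truth == 0L & predicted == 1L),
         tn = sum(truth == 0L & predicted == 0L),
         fn = sum(truth == 1L & predicted == 0L))
}

#' Confusion-based performance metrics
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, balanced
#' accuracy `BACC = (Sn+Sp)/2`, and Matthews correlation
#' \deqn{MCC = \frac{TP\cdot TN - FP\cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' An empty class makes Sn or Sp (and BACC) `NA`, never a silent 0; a zero
#' factor in the MCC denominator yields `MCC = 0` by the standard
#' convention.
#'
#' @param counts One-row tibble from [confusion_counts()] (columns `tp`,
#'   `fp`, `tn`, `fn`).
#' @return One-row tibble with columns `sensitivity`, `specificity`,
#'   `bacc`, `mcc`.
#' @examples
#' classification_metrics(tibble::tibble(tp = 8, fn = 2, tn = 8, fp = 2))
#' @export
classification_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fp + tn + fn == 0) abort("Empty confusion table.")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2)
  tibble(sensitivity = sn, specificity = sp,
         bacc = (sn + sp) / 2, mcc = mcc)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the distinct score values (plus a
#' sentinel above the maximum), calling a sample positive when its score is
#' greater than or equal to the threshold. Tied scores collapse to a single
#' operating point, so the curve runs from (0, 0) to (1, 1) with at most
#' one point per distinct score plus one.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param truth Binary labels (both classes required).
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_points <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth))
  if (length(unique(truth)) < 2L) {
    abort("ROC requires both classes in `truth`.")
  }
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- map(thresholds, function(t) {
    pred_pos <- scores >= t
    tibble(threshold = t,
           fpr = sum(pred_pos & truth == 0L) / n_neg,
           tpr = sum(pred_pos & truth == 1L) / n_pos)
  })
  bind_rows(pts)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_points()]; with the tie-collapsed curve this
#' equals the Mann-Whitney concordance probability (ties counted one half).
#'
#' @inheritParams roc_points
#' @param curve Optionally, a precomputed [roc_points()] tibble instead of
#'   `scores`/`truth`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores = NULL, truth = NULL, curve = NULL) {
  curve <- curve %||% roc_points(scores, truth)
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}

#' ROC-space quadrant of an operating point
#'
#' Splits the unit square at (FPR, TPR) = (0.5, 0.5). Quadrant II
#' (`tpr > 0.5`, `fpr < 0.5`, i.e. both sensitivity and specificity above
#' one half) marks predictors that balance the two error types; quadrant I
#' is sensitive but unspecific, III specific but insensitive (the
#' predict-everything-negative regime), IV inferior in both. Boundary
#' points (`tpr = 0.5` or `fpr = 0.5`) are assigned to the lower quadrant:
#' a method on the split lines does not get credit for the better half.
#'
#' @param fpr,tpr Coordinates of the operating point in `[0, 1]`
#'   (`fpr = 1 - specificity`, `tpr =` sensitivity).
#' @return A quadrant label: `"I"`, `"II"`, `"III"` or `"IV"`.
#' @examples
#' roc_quadrant(fpr = 0.198, tpr = 0.823) # "II"
#' roc_quadrant(fpr = 0.11, tpr = 0.32)   # "III"
#' @export
roc_quadrant <- function(fpr, tpr) {
  if (fpr < 0 || fpr > 1 || tpr < 0 || tpr > 1) {
    abort("`fpr` and `tpr` must lie in [0, 1].")
  }
  if (tpr > 0.5) {
    if (fpr < 0.5) "II" else "I"
  } else {
    if (fpr < 0.5) "III" else "IV"
  }
}

#' Evaluate scored predictions against reference labels
#'
#' Bundles the confusion table at the given threshold, the derived metrics,
#' the full ROC curve with its AUC, and the ROC-space quadrant of the
#' operating point into a single report.
#'
#' @param data Tibble with (at least) the score and truth columns; the
#'   prediction-output convention is columns `label` (truth) and `score`.
#' @param truth,score Column names (strings) holding labels and scores.
#' @param threshold Decision threshold (default 0.5; score >= threshold is
#'   called positive).
#' @return An `amyhex_eval` object; see [tidy.amyhex_eval()] and
#'   [glance.amyhex_eval()].
#' @export
evaluate_predictions <- function(data, truth = "label", score = "score",
                                 threshold = 0.5) {
  stopifnot(all(c(truth, score) %in% names(data)))
  y <- as.integer(data[[truth]])
  s <- data[[score]]
  counts <- confusion_counts(y, classify_scores(s, threshold))
  metrics <- classification_metrics(counts)
  curve <- roc_points(s, y)
  point <- c(fpr = 1 - metrics$specificity, tpr = metrics$sensitivity)
  structure(
    list(counts = counts, metrics = metrics, roc = curve,
         auc = roc_auc(curve = curve), threshold = threshold,
         quadrant = roc_quadrant(point[["fpr"]], point[["tpr"]])),
    class = "amyhex_eval")
}

#' @export
print.amyhex_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    paste0("<amyhex_eval> n = %d | Sn %.3f  Sp %.3f  BACC %.3f  MCC %.3f",
           " | AUC %.3f | quadrant %s (threshold %.2f)\n"),
    sum(unlist(x$counts)), m$sensitivity, m$specificity, m$bacc, m$mcc,
    x$auc, x$quadrant, x$threshold))
  invisible(x)
}

#' Tidiers for evaluation reports
#'
#' `tidy()` returns the ROC curve points; `glance()` the one-row metric
#' summary (confusion counts, Sn/Sp/BACC/MCC, AUC, quadrant).
#'
#' @param x An `amyhex_eval` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy amyhex_eval
#' @export
tidy.amyhex_eval <- function(x, ...) {
  x$roc
}

#' @rdname tidy.amyhex_eval
#' @method glance amyhex_eval
#' @export
glance.amyhex_eval <- function(x, ...) {
  bind_cols(x$counts, x$metrics,
            tibble(auc = x$auc, threshold = x$threshold,
                   quadrant = x$quadrant))
}

#' @rdname tidy.amyhex_eval
#' @param object An `amyhex_eval`.
#' @method autoplot amyhex_eval
#' @export
autoplot.amyhex_eval <- function(object, ...) {
  point <- tibble(fpr = 1 - object$metrics$specificity,
                  tpr = object$metrics$sensitivity)
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = point, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - Sp)",
                  y = "True positive rate (Sn)",
                  title = sprintf("AUC = %.3f, quadrant %s",
                                  object$auc, object$quadrant)) +
    ggplot2::theme_minimal()
}

#' Fig.-2-style quadrant scatter of operating points
#'
#' Plots one or more (FPR, TPR) operating points in ROC space with the
#' quadrant split lines at 0.5, the view used to compare predictors that
#' expose no tunable threshold.
#'
#' @param points Tibble with columns `fpr`, `tpr` and optionally `method`.
#' @return A ggplot.
#' @export
plot_quadrants <- function(points) {
  stopifnot(all(c("fpr", "tpr") %in% names(points)))
  if (!"method" %in% names(points)) {
    points$method <- paste0("point ", seq_len(nrow(points)))
  }
  points$quadrant <- map2_dbl(points$fpr, points$tpr, function(f, t) {
    match(roc_quadrant(f, t), c("I", "II", "III", "IV"))
  })
  points$quadrant <- c("I", "II", "III", "IV")[points$quadrant]
  ggplot2::ggplot(points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$method), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$quadrant),
                       nudge_y = 0.035, size = 3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate (1 - Sp)",
                  y = "True positive rate (Sn)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to JSON / ROC points to CSV
#'
#' @param report An `amyhex_eval`.
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_evaluation <- function(report, file) {
  jsonlite::write_json(
    list(counts = as.list(report$counts),
         metrics = as.list(report$metrics),
         auc = report$auc, threshold = report$threshold,
         quadrant = report$quadrant,
         roc = as.data.frame(report$roc)),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_evaluation
#' @export
write_roc_csv <- function(report, file) {
  write.table(report$roc, file, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
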