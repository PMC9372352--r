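# Voxel- and lesion-level segmentation evaluation metrics.
#
# Conventions for degenerate inputs: when both masks are empty the score is
# perfect (1, or 0 mm / 0 % for distances and volume difference); when a
# metric's denominator set is empty on one side only, the value is NaN and
# the report carries a flag, rather than a manufactured sentinel.

#' Voxel-level Dice, recall and precision
#'
#' Dice = 2TP / (2TP + FP + FN); recall = TP / (TP + FN);
#' precision = TP / (TP + FP).
#'
#' @param pred,truth logical (or 0/1) volumes of identical geometry.
#' @return list with `dice`, `recall`, `precision` and the raw counts
#'   `tp`, `fp`, `fn`.
#' @export
voxel_metrics <- function(pred, truth) {
  assert_same_geometry(pred, truth, "prediction and truth")
  p <- as.logical(pred); g <- as.logical(truth)
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  if (tp + fp + fn == 0L)
    return(list(dice = 1, recall = 1, precision = 1, tp = tp, fp = fp,
                fn = fn))
  list(dice = 2 * tp / (2 * tp + fp + fn),
       recall = if (tp + fn > 0) tp / (tp + fn) else NaN,
       precision = if (tp + fp > 0) tp / (tp + fp) else NaN,
       tp = tp, fp = fp, fn = fn)
}

#' Recall restricted to the definite WMH region
#'
#' Fraction of definite-WMH voxels (labeled by both raters) recovered by
#' the prediction.
#'
#' @param pred logical prediction volume.
#' @param definite logical definite-WMH volume.
#' @return a single number, or NaN when the definite mask is empty.
#' @export
definite_recall <- function(pred, definite) {
  assert_same_geometry(pred, definite, "prediction and definite mask")
  n <- sum(definite)
  if (n == 0L) return(NaN)
  sum(as.logical(pred) & as.logical(definite)) / n
}

#' Lesion-level recall and F1
#'
#' Lesions are 3D connected components (26-connectivity).  A truth lesion is
#' detected if at least one predicted voxel overlaps it; a predicted
#' component is correct if it overlaps at least one truth voxel.  Lesion
#' recall is the detected fraction of truth lesions, lesion precision the
#' correct fraction of predicted components, and lesion F1 their harmonic
#' mean.
#'
#' @param pred,truth logical volumes.
#' @return list with `lesion_recall`, `lesion_precision`, `lesion_f1`,
#'   `n_truth_lesions`, `n_pred_components`.
#' @export
lesion_metrics <- function(pred, truth) {
  assert_same_geometry(pred, truth, "prediction and truth")
  p <- as.logical(pred); g <- as.logical(truth)
  if (!any(p) && !any(g))
    return(list(lesion_recall = 1, lesion_precision = 1, lesion_f1 = 1,
                n_truth_lesions = 0L, n_pred_components = 0L))
  lt <- label_components(array(g, dim(truth)))
  lp <- label_components(array(p, dim(pred)))
  nt <- max(lt); np <- max(lp)
  detected <- if (nt > 0) length(unique(lt[g & p])) else 0L
  correct <- if (np > 0) length(unique(lp[p & g])) else 0L
  recall <- if (nt > 0) detected / nt else NaN
  precision <- if (np > 0) correct / np else NaN
  f1 <- if (is.finite(recall) && is.finite(precision) &&
            recall + precision > 0) 2 * recall * precision /
    (recall + precision) else if (isTRUE(recall == 0) ||
                                  isTRUE(precision == 0)) 0 else NaN
  list(lesion_recall = recall, lesion_precision = precision, lesion_f1 = f1,
       n_truth_lesions = nt, n_pred_components = np)
}

#' Average volume difference in percent
#'
#' `|A - B| / B * 100` with A the predicted and B the reference volume.
#'
#' @param pred,truth logical volumes.
#' @return percentage; 0 when both are empty, NaN when only the truth is
#'   empty.
#' @export
avd <- function(pred, truth) {
  assert_same_geometry(pred, truth, "prediction and truth")
  a <- sum(as.logical(pred)); b <- sum(as.logical(truth))
  if (b == 0L) return(if (a == 0L) 0 else NaN)
  abs(a - b) / b * 100
}

#' 95th-percentile Hausdorff distance in mm
#'
#' For each voxel of one set, the Euclidean distance (in mm, anisotropic
#' spacing respected) to the nearest voxel of the other set is computed; the
#' 95th percentile (nearest-rank) of these distances is taken in each
#' direction and the larger of the two directed values is returned.
#'
#' @param pred,truth logical volumes.
#' @param spacing voxel spacing `c(x, y, z)` in mm.
#' @return distance in mm; 0 when both masks are empty, NaN when exactly one
#'   is empty.
#' @export
hausdorff95 <- function(pred, truth, spacing) {
  assert_same_geometry(pred, truth, "prediction and truth")
  p <- as.logical(pred); g <- as.logical(truth)
  if (!any(p) && !any(g)) return(0)
  if (!any(p) || !any(g)) return(NaN)
  dist_to_g <- edt_mm(array(g, dim(truth)), spacing)
  dist_to_p <- edt_mm(array(p, dim(pred)), spacing)
  directed <- function(dists) {
    s <- sort(dists)
    nearest_rank(s, 0.95)
  }
  max(directed(dist_to_g[p]), directed(dist_to_p[g]))
}

#' Full per-class metrics report for one subject
#'
#' Evaluates one predicted label volume against the reference for classes 1
#' (WMH) and 2 (other intracranial lesions): Dice, recall, precision,
#' lesion recall, lesion F1, average volume difference and Hausdorff95, plus
#' definite-WMH recall when a definite mask is available.
#'
#' @param pred,truth integer label volumes (0/1/2).
#' @param spacing voxel spacing in mm.
#' @param definite optional logical definite-WMH mask (class 1 only).
#' @param classes which label codes to evaluate.
#' @return data frame, one row per class.
#' @export
metrics_report <- function(pred, truth, spacing, definite = NULL,
                           classes = c(1L, 2L)) {
  rows <- lapply(classes, function(cl) {
    pm <- pred == cl; tm <- truth == cl
    vm <- voxel_metrics(pm, tm)
    lm <- lesion_metrics(pm, tm)
    data.frame(class = cl, dice = vm$dice, recall = vm$recall,
               precision = vm$precision,
               definite_recall = if (cl == 1L && !is.null(definite))
                 definite_recall(pm, definite) else NA_real_,
               lesion_recall = lm$lesion_recall,
               lesion_f1 = lm$lesion_f1,
               avd_percent = avd(pm, tm),
               hausdorff95_mm = hausdorff95(pm, tm, spacing))
  })
  do.call(rbind, rows)
}

#' Cohort-aggregate metrics (per-subject mean and SD)
#'
#' @param reports list of [metrics_report()] data frames.
#' @return data frame with per-class mean and SD of every metric; NaN
#'   entries (undefined per-subject values) are dropped from the aggregation.
#' @export
cohort_metrics <- function(reports) {
  all <- do.call(rbind, reports)
  metrics <- setdiff(names(all), "class")
  out <- lapply(split(all, all$class), function(df) {
    means <- vapply(metrics, function(m) mean(df[[m]][is.finite(df[[m]])]),
                    numeric(1))
    sds <- vapply(metrics, function(m) sd(df[[m]][is.finite(df[[m]])]),
                  numeric(1))
    data.frame(class = df$class[1], metric = metrics, mean = means, sd = sds,
               row.names = NULL)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
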