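#' Classify scored images by a threshold
#'
#' Applies the decision rule `score >= cutoff` implies AWM, else NODAL,
#' preserving input order.
#'
#' @param scores numeric I15 scores, or a [score_set()] data frame.
#' @param cutoff a finite numeric threshold or an `i15_cutoff` object.
#' @return Character vector of predicted labels.
#' @export
classify_by_threshold <- function(scores, cutoff) {
  if (inherits(cutoff, "i15_cutoff")) cutoff <- cutoff$threshold
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff))
    stop("'cutoff' must be a single finite number")
  if (is.data.frame(scores)) scores <- scores$i15
  ifelse(scores >= cutoff, "AWM", "NODAL")
}

#' Confusion matrix under the AWM-positive convention
#'
#' Tabulates predictions against truth with AWM as the positive class and
#' NODAL as the negative class: a true positive is an AWM image classified
#' as AWM, a true negative a nodal image classified as nodal.
#'
#' @param pred,truth equal-length character vectors of `"AWM"` / `"NODAL"`.
#' @return An object of class `confusion_matrix` with integer counts `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("'pred' and 'truth' must have the same length (",
         length(pred), " vs ", length(truth), ")")
  bad <- which(!pred %in% c("AWM", "NODAL") | !truth %in% c("AWM", "NODAL"))
  if (length(bad))
    stop("invalid label at position ", bad[1],
         "; labels must be 'AWM' or 'NODAL'")
  structure(list(tp = sum(pred == "AWM" & truth == "AWM"),
                 fp = sum(pred == "AWM" & truth == "NODAL"),
                 tn = sum(pred == "NODAL" & truth == "NODAL"),
                 fn = sum(pred == "NODAL" & truth == "AWM")),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("AWM", "NODAL"),
                              predicted = c("AWM", "NODAL")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity of a classification
#'
#' Sensitivity is the proportion of AWM images correctly identified as AWM
#' (true-positive rate, `100 * tp / (tp + fn)`); specificity the proportion
#' of nodal images correctly identified as nodal (true-negative rate,
#' `100 * tn / (tn + fp)`). Both are returned as unrounded percentages;
#' report formatting rounds half-up to one decimal (see
#' [round_half_up()]).
#'
#' @param cm a [confusion()] matrix.
#' @return Percentage in `[0, 100]`.
#' @examples
#' sensitivity(confusion_counts(tp = 79, fp = 0, tn = 0, fn = 2)) # 97.53...
#' @export
sensitivity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0)
    stop("sensitivity undefined: no AWM images in truth")
  100 * cm$tp / (cm$tp + cm$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tn + cm$fp == 0)
    stop("specificity undefined: no NODAL images in truth")
  100 * cm$tn / (cm$tn + cm$fp)
}

#' Round half away from zero
#'
#' Decimal rounding with halves rounded up, the convention used for
#' reported percentages (base `round()` rounds halves to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise an examiner panel
#'
#' Aggregates per-examiner sensitivity and specificity percentages to the
#' panel mean and standard error, SE = sample standard deviation
#' (n - 1 denominator) / sqrt(n raters); a single rater reports SE 0.
#'
#' @param per_rater data frame (or matrix) with columns `sensitivity` and
#'   `specificity`, one row per rater, values in percent.
#' @return An object of class `panel_summary` with fields `per_rater`,
#'   `n_raters`, `mean_sen`, `se_sen`, `mean_spe`, `se_spe` (unrounded
#'   percentages).
#' @examples
#' panel_summary(data.frame(sensitivity = c(90, 95, 100),
#'                          specificity = c(88, 92, 96)))
#' @export
panel_summary <- function(per_rater) {
  per_rater <- as.data.frame(per_rater)
  if (nrow(per_rater) == 0L) stop("panel requires at least one rater")
  stopifnot(all(c("sensitivity", "specificity") %in% names(per_rater)))
  n <- nrow(per_rater)
  se <- function(v) if (n == 1L) 0 else sd(v) / sqrt(n)
  structure(list(per_rater = per_rater, n_raters = n,
                 mean_sen = mean(per_rater$sensitivity),
                 se_sen = se(per_rater$sensitivity),
                 mean_spe = mean(per_rater$specificity),
                 se_spe = se(per_rater$specificity)),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("<panel_summary> %d examiners\n", x$n_raters))
  cat(sprintf("  sensitivity %.1f%% +/- %.1f (SE)\n",
              round_half_up(x$mean_sen), round_half_up(x$se_sen)))
  cat(sprintf("  specificity %.1f%% +/- %.1f (SE)\n",
              round_half_up(x$mean_spe), round_half_up(x$se_spe)))
  invisible(x)
}

#' Per-examiner performance from a rater table
#'
#' Computes each examiner's sensitivity and specificity against the truth
#' labels and aggregates them with [panel_summary()]. The rater table is
#' the long format written by examiner studies: one row per
#' (rater, image) with the rater's predicted label.
#'
#' @param raters data frame with columns `rater_id`, `source_id`,
#'   `predicted_label`.
#' @param truth data frame with columns `source_id`, `label`.
#' @return A `panel_summary`.
#' @export
panel_from_raters <- function(raters, truth) {
  stopifnot(all(c("rater_id", "source_id", "predicted_label") %in% names(raters)),
            all(c("source_id", "label") %in% names(truth)))
  truth_map <- setNames(truth$label, truth$source_id)
  missing <- setdiff(raters$source_id, names(truth_map))
  if (length(missing))
    stop("rater table references unknown source_id '", missing[1], "'")
  per <- lapply(split(raters, raters$rater_id), function(r) {
    cm <- confusion(r$predicted_label, unname(truth_map[r$source_id]))
    c(sensitivity = sensitivity(cm), specificity = specificity(cm))
  })
  panel_summary(do.call(rbind, per))
}
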